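# Image-derived shape features and per-event quality control.
#
# Contours are ordered closed polygons in pixel coordinates (n x 2 matrices;
# the closing edge from the last to the first vertex is implicit). Area comes
# from the shoelace formula, perimeter from the Euclidean arc length of the
# vertex chain -- the usual cytometry conventions.

#' Deformation of an imaged shape
#'
#' The circularity deficit
#' \deqn{D = 1 - \frac{2\sqrt{\pi A}}{P},}
#' where \eqn{A} is the projected area and \eqn{P} the perimeter of the
#' two-dimensional image of the shape. \eqn{D = 0} for a circle and, by the
#' isoperimetric inequality, \eqn{D > 0} for any other simple shape
#' (\eqn{D < 1} always).
#'
#' @param area projected area (um^2 or any unit, consistent with perimeter
#'   squared).
#' @param perimeter perimeter in the matching length unit.
#' @return dimensionless deformation in `[0, 1)`.
#' @examples
#' deformation(pi * 5^2, 2 * pi * 5)   # circle: 0
#' deformation(1, 4)                   # unit square: 1 - sqrt(pi)/2
#' @export
deformation <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0))
    guv_stop("guvmech_input_error",
             "deformation() needs strictly positive area and perimeter")
  1 - 2 * sqrt(pi * area) / perimeter
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

polygon_perimeter <- function(v) {
  dx <- diff(c(v[, 1], v[1, 1]))
  dy <- diff(c(v[, 2], v[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

check_contour <- function(contour) {
  if (!is.matrix(contour) || ncol(contour) != 2 || nrow(contour) < 3 ||
      any(!is.finite(contour)))
    guv_stop("guvmech_contour_error",
             "contour must be a finite n x 2 matrix with n >= 3")
  if (polygon_area(contour) <= 0)
    guv_stop("guvmech_contour_error", "degenerate contour: zero enclosed area")
  invisible(contour)
}

#' Porosity (convexity defect) of a contour
#'
#' Ratio of the area of the convex hull of the contour vertices to the area
#' enclosed by the contour itself. Exactly 1 for convex contours; values
#' clearly above 1 indicate geometric flaws such as indentations from
#' overlapping vesicles (doublets) or jagged, missegmented contour lines.
#'
#' @param contour n x 2 matrix of vertices in pixel coordinates.
#' @return dimensionless ratio >= 1.
#' @export
porosity <- function(contour) {
  check_contour(contour)
  hull <- contour[chull(contour[, 1], contour[, 2]), , drop = FALSE]
  # polygon arithmetic can undershoot 1 by rounding on exactly convex input
  max(1, polygon_area(hull) / polygon_area(contour))
}

#' Shape features of a contour
#'
#' Computes the event features from a pixel-coordinate contour: area (shoelace
#' formula, scaled by the squared pixel size), perimeter (polygon arc length),
#' deformation via [deformation()], and porosity via [porosity()].
#'
#' @param contour n x 2 matrix of vertices in pixel coordinates; an attribute
#'   `pixel_um` is honoured if present.
#' @param pixel_um pixel size in micrometres per pixel (default 0.34).
#' @return one-row data.frame with `area_um`, `perim_um`, `deform`,
#'   `porosity`, `area_px`.
#' @export
contour_features <- function(contour, pixel_um = attr(contour, "pixel_um")) {
  check_contour(contour)
  if (is.null(pixel_um)) pixel_um <- 0.34
  a_px <- polygon_area(contour)
  p_px <- polygon_perimeter(contour)
  data.frame(area_um = a_px * pixel_um^2,
             perim_um = p_px * pixel_um,
             deform = deformation(a_px, p_px),
             porosity = porosity(contour),
             area_px = a_px)
}

#' Pixelation correction coefficients
#'
#' Representing a contour on a pixel grid inflates the measured perimeter, so
#' even a perfect circle appears slightly deformed; the offset shrinks as the
#' object grows. The correction subtracts a size-dependent offset
#' \deqn{\Delta D(A_{px}) = c_1 A_{px}^{-c_2}}
#' from the measured deformation. The default coefficients are
#' self-calibrated against this package's contour rasterizer
#' ([rasterize_contour()]) on synthetic circles of 10--80 px radius; they are
#' a synthetic stand-in appropriate for contours produced by that rasterizer.
#' For instrument data, supply the coefficient set established for the
#' camera/segmentation pipeline in use.
#'
#' @param c1,c2 coefficients of the power-law offset.
#' @return list of class `guv_pixcorr`.
#' @export
pixel_correction <- function(c1 = 2.085, c2 = 0.884) {
  stopifnot(c1 >= 0, c2 > 0)
  structure(list(c1 = c1, c2 = c2), class = "guv_pixcorr")
}

#' Correct deformation for pixelation
#'
#' Subtracts the size-dependent pixelation offset of [pixel_correction()]
#' from a measured deformation; the result is clamped at 0 (a correction must
#' not produce negative deformation) and tends to the raw value in the
#' large-object limit. With `coef = NULL` the identity is returned with a
#' warning, so uncorrected analyses are explicit, never silent.
#'
#' @param D measured deformation (vectorized, >= 0).
#' @param area_px object area in squared pixels (vectorized, > 0).
#' @param coef a [pixel_correction()] coefficient set, or `NULL` for the
#'   identity.
#' @return corrected deformation, elementwise `<= D`.
#' @export
pixelation_correct <- function(D, area_px, coef = pixel_correction()) {
  stopifnot(all(D >= 0), all(area_px > 0))
  if (is.null(coef)) {
    guv_warn("no pixelation-correction coefficients configured; returning D unchanged")
    return(D)
  }
  pmax(0, D - coef$c1 * area_px^(-coef$c2))
}

#' Quality gate configuration
#'
#' The default gates retain events with area in `[60, 225]` um^2 (the range
#' covered by the calibration simulations), deformation at most 0.1, and --
#' when the porosity feature is available -- porosity at most 1.03, a robust
#' threshold that removes most missegmented contours.
#'
#' @param area_um length-2 numeric, area window in um^2.
#' @param deform_max maximum deformation.
#' @param porosity_max maximum porosity.
#' @return list of class `guv_gates`.
#' @export
gate_config <- function(area_um = c(60, 225), deform_max = 0.1,
                        porosity_max = 1.03) {
  stopifnot(length(area_um) == 2, diff(area_um) > 0,
            deform_max > 0, porosity_max >= 1)
  structure(list(area_um = area_um, deform_max = deform_max,
                 porosity_max = porosity_max), class = "guv_gates")
}

#' Apply quality gates to an event table
#'
#' Splits events into those passing all gates and those failing at least one;
#' rejected events are annotated with every failing gate
#' (`"area_range"`, `"deform_max"`, `"porosity"`) in a `qc_flags` column.
#' Filtering is idempotent. An empty survivor set triggers a warning rather
#' than failing silently.
#'
#' @param events data.frame with `area_um`, `deform` and optionally
#'   `porosity` (`NA` porosity is tolerated and not gated).
#' @param gates a [gate_config()].
#' @return list with data.frames `kept` and `rejected` (the latter with a
#'   `qc_flags` character column) and a named integer vector `counts`.
#' @export
apply_gates <- function(events, gates = gate_config()) {
  check_events(events)
  flags <- character(nrow(events))
  bad_area <- events$area_um < gates$area_um[1] |
    events$area_um > gates$area_um[2]
  bad_def <- events$deform > gates$deform_max
  bad_por <- if ("porosity" %in% names(events))
    !is.na(events$porosity) & events$porosity > gates$porosity_max
  else rep(FALSE, nrow(events))
  add <- function(flags, bad, label)
    ifelse(bad, ifelse(nzchar(flags), paste(flags, label, sep = ","), label),
           flags)
  flags <- add(flags, bad_area, "area_range")
  flags <- add(flags, bad_def, "deform_max")
  flags <- add(flags, bad_por, "porosity")
  rej <- nzchar(flags)
  kept <- events[!rej, , drop = FALSE]
  rejected <- events[rej, , drop = FALSE]
  rejected$qc_flags <- flags[rej]
  if (nrow(kept) == 0)
    guv_warn("no events survive the quality gates")
  list(kept = kept, rejected = rejected,
       counts = c(kept = nrow(kept), area_range = sum(bad_area),
                  deform_max = sum(bad_def), porosity = sum(bad_por)))
}
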