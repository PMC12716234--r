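# Synthetic RT-DC event populations with the statistical structure the
# estimators assume: areas drawn from a configurable size distribution,
# deformations from the forward response surface, multiplicative lognormal
# measurement noise, and a configurable fraction of outlier events whose
# deformation is inflated (mimicking vesicle doublets and misplaced contour
# lines). All randomness flows from the spec seed; the global RNG state is
# left untouched.

#' Specify a synthetic vesicle population
#'
#' @param n number of events.
#' @param K true area expansion modulus (N/m).
#' @param area distribution of projected areas: `"uniform"` on `area_range`
#'   (default) or `"lognormal"` truncated to `area_range`.
#' @param area_range area window in um^2 (default the calibration range
#'   `[60, 225]`).
#' @param area_meanlog,area_sdlog parameters of the lognormal size option.
#' @param sigma_D log-SD of the multiplicative lognormal deformation noise,
#'   `D_obs = D_true * exp(eps)`, `eps ~ N(0, sigma_D^2)` (default 0.15).
#'   The noise has zero log-mean, so the median observed deformation equals
#'   the true one.
#' @param outlier_fraction expected fraction of outlier events (default
#'   0.05).
#' @param outlier_factor range of the deformation inflation factor for
#'   outliers, drawn uniformly (default `c(1.5, 3)`).
#' @param seed integer seed; identical specs give bitwise-identical output.
#' @return list of class `guv_popspec`.
#' @export
population_spec <- function(n, K, area = c("uniform", "lognormal"),
                            area_range = c(60, 225),
                            area_meanlog = log(120), area_sdlog = 0.3,
                            sigma_D = 0.15, outlier_fraction = 0.05,
                            outlier_factor = c(1.5, 3), seed = 1) {
  area <- match.arg(area)
  stopifnot(n > 0, K > 0, diff(area_range) > 0, sigma_D >= 0,
            outlier_fraction >= 0, outlier_fraction <= 1,
            length(outlier_factor) == 2, all(outlier_factor >= 1))
  structure(list(n = as.integer(n), K = K, area = area,
                 area_range = area_range, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog, sigma_D = sigma_D,
                 outlier_fraction = outlier_fraction,
                 outlier_factor = outlier_factor, seed = as.integer(seed)),
            class = "guv_popspec")
}

draw_areas <- function(spec) {
  if (spec$area == "uniform") {
    runif(spec$n, spec$area_range[1], spec$area_range[2])
  } else {
    # rejection-sample the truncated lognormal
    out <- numeric(0)
    while (length(out) < spec$n) {
      cand <- exp(rnorm(2 * spec$n, spec$area_meanlog, spec$area_sdlog))
      out <- c(out, cand[cand >= spec$area_range[1] &
                           cand <= spec$area_range[2]])
    }
    out[seq_len(spec$n)]
  }
}

#' Generate a synthetic event population
#'
#' Areas are sampled from the spec's size distribution; true deformations
#' follow the forward response surface [forward_D()] at the spec's modulus;
#' observed deformations add multiplicative lognormal noise; a random subset
#' of events becomes outliers by inflating the deformation with a factor
#' drawn from `outlier_factor`. The returned truth table records the
#' noise-free deformation and the outlier labels, so estimator recovery can
#' be scored exactly.
#'
#' @param spec a [population_spec()].
#' @param setup a [channel_setup()].
#' @param calib a [guv_calibration()].
#' @param population integer label stored in the truth table (default 1).
#' @return list with `events` (data.frame `area_um`, `deform`) and `truth`
#'   (data.frame `population`, `K_true`, `D_true`, `is_outlier`).
#' @examples
#' ev <- generate_events(population_spec(100, K = 0.2, seed = 7),
#'                       reference_setup())
#' head(ev$events)
#' @export
generate_events <- function(spec, setup, calib = default_calibration(),
                            population = 1L) {
  stopifnot(inherits(spec, "guv_popspec"))
  with_seed(spec$seed, {
    A <- draw_areas(spec)
    D_true <- forward_D(spec$K, A, setup, calib)
    D <- D_true * exp(rnorm(spec$n, 0, spec$sigma_D))
    is_out <- runif(spec$n) < spec$outlier_fraction
    if (any(is_out))
      D[is_out] <- D[is_out] *
        runif(sum(is_out), spec$outlier_factor[1], spec$outlier_factor[2])
    list(events = data.frame(area_um = A, deform = D),
         truth = data.frame(population = as.integer(population),
                            K_true = spec$K, D_true = D_true,
                            is_outlier = is_out))
  })
}

#' Specify and generate a mixed-population data set
#'
#' `mixture_spec()` bundles several [population_spec()]s;
#' `generate_mixture()` draws each population (sub-seeds derived from the
#' mixture seed), merges them and applies a seeded shuffle. Truth labels are
#' kept alongside, never inside, the event table.
#'
#' @param ... two or more [population_spec()] objects.
#' @param seed seed for sub-seed derivation and the final shuffle.
#' @return `mixture_spec()`: list of class `guv_mixspec`;
#'   `generate_mixture()`: list with `events` and `truth` as in
#'   [generate_events()], rows shuffled consistently.
#' @export
mixture_spec <- function(..., seed = 1) {
  pops <- list(...)
  stopifnot(length(pops) >= 1,
            all(vapply(pops, inherits, logical(1), "guv_popspec")))
  structure(list(populations = pops, seed = as.integer(seed)),
            class = "guv_mixspec")
}

#' @rdname mixture_spec
#' @param spec a `guv_mixspec`.
#' @inheritParams generate_events
#' @export
generate_mixture <- function(spec, setup, calib = default_calibration()) {
  stopifnot(inherits(spec, "guv_mixspec"))
  draws <- lapply(seq_along(spec$populations), function(i) {
    p <- spec$populations[[i]]
    p$seed <- (spec$seed %% 1000003L) * 1000L + i  # deterministic sub-seeds, < 2^31
    generate_events(p, setup, calib, population = i)
  })
  events <- do.call(rbind, lapply(draws, `[[`, "events"))
  truth <- do.call(rbind, lapply(draws, `[[`, "truth"))
  with_seed(spec$seed, {
    perm <- sample.int(nrow(events))
    list(events = events[perm, , drop = FALSE],
         truth = truth[perm, , drop = FALSE])
  })
}

# perimeter of an ellipse with semi-axes (q, 1) by quadrature
ellipse_perimeter_unit <- function(q) {
  integrate(function(t) sqrt(q^2 * sin(t)^2 + cos(t)^2), 0, 2 * pi,
            rel.tol = 1e-10)$value
}

ellipse_deformation <- function(q) {
  1 - 2 * sqrt(pi * pi * q) / ellipse_perimeter_unit(q)
}

smooth_closed <- function(v, win) {
  n <- nrow(v)
  if (win <= 1 || n <= win) return(v)
  idx <- outer(seq_len(n), seq_len(win) - (win + 1) %/% 2, "+")
  idx <- ((idx - 1) %% n) + 1
  cbind(rowMeans(matrix(v[idx, 1], n)), rowMeans(matrix(v[idx, 2], n)))
}

raster_chain <- function(x, y, smooth_scale) {
  xi <- round(x); yi <- round(y)
  keep <- c(TRUE, diff(xi) != 0 | diff(yi) != 0)
  v <- cbind(xi[keep], yi[keep])
  # drop a duplicated closing vertex
  n <- nrow(v)
  if (n > 1 && v[n, 1] == v[1, 1] && v[n, 2] == v[1, 2]) v <- v[-n, , drop = FALSE]
  smooth_closed(v, max(3L, as.integer(round(smooth_scale / 3))))
}

#' Rasterize a synthetic vesicle contour
#'
#' Emits a pixel-quantized closed polygon whose measured features
#' ([contour_features()]) match a requested (area, deformation) pair within
#' a documented tolerance. Shapes come from an elongated (elliptical) family
#' whose aspect ratio is solved so that the ideal contour has the requested
#' deformation; the ideal outline is sampled densely, snapped to the pixel
#' grid, and lightly smoothed with a window proportional to the object size,
#' emulating the subpixel contour refinement of RT-DC segmentation. The
#' residual pixelation offset of the deformation decays with object area and
#' is what [pixelation_correct()] removes. A `"doublet"` variant overlays
#' two offset circles of the requested total area, producing the non-convex
#' outline (porosity > 1.03) typical of coincident vesicles.
#'
#' Tolerances (measured on the calibration domain): measured area within 2%
#' of the request; corrected deformation within 0.01 absolute.
#'
#' @param area_um2 requested projected area (um^2).
#' @param deform requested deformation; the elliptical family covers
#'   `[0, 0.3]` -- larger values raise an error naming the family limit.
#'   Ignored for doublets.
#' @param pixel_um pixel size (um/px, default 0.34).
#' @param shape `"ellipse"` (default) or `"doublet"`.
#' @param n_samples boundary samples before pixel snapping.
#' @return n x 2 matrix of vertices in pixel coordinates with attribute
#'   `pixel_um`, class `guv_contour`.
#' @export
rasterize_contour <- function(area_um2, deform = 0, pixel_um = 0.34,
                              shape = c("ellipse", "doublet"),
                              n_samples = 8000) {
  shape <- match.arg(shape)
  stopifnot(area_um2 > 0, deform >= 0)
  area_px <- area_um2 / pixel_um^2
  t <- seq(0, 2 * pi, length.out = n_samples + 1)[-(n_samples + 1)]
  if (shape == "ellipse") {
    if (deform > 0.3)
      guv_stop("guvmech_shape_error",
               "requested deformation %.3g exceeds the elliptical shape-family limit (0.3)",
               deform)
    q <- if (deform == 0) 1
         else uniroot(function(q) ellipse_deformation(q) - deform,
                      c(1 + 1e-9, 60), tol = 1e-10)$root
    b <- sqrt(area_px / (pi * q)); a <- q * b
    v <- raster_chain(a * cos(t), b * sin(t), smooth_scale = b)
  } else {
    # two equal circles, centre distance 1.4 R: union area = 2*pi*R^2 - lens
    R <- sqrt(area_px / (2 * pi)) * 1.06   # rough lens-overlap compensation
    d <- 1.4 * R
    x1 <- R * cos(t) - d / 2; y1 <- R * sin(t)
    x2 <- R * cos(t) + d / 2; y2 <- R * sin(t)
    k1 <- (x1 - d / 2)^2 + y1^2 > R^2   # parts of circle 1 outside circle 2
    k2 <- (x2 + d / 2)^2 + y2^2 > R^2
    xs <- c(x1[k1], x2[k2]); ys <- c(y1[k1], y2[k2])
    o <- order(atan2(ys, xs))
    v <- raster_chain(xs[o], ys[o], smooth_scale = R)
  }
  structure(v, pixel_um = pixel_um, class = c("guv_contour", class(v)))
}
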