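# Nondimensionalization of the RT-DC stress scale and derived diagnostics.
# Internal units are SI throughout; micrometres and microlitres appear only at
# the constructor/I-O boundary.

#' Describe an RT-DC channel setup
#'
#' Bundles the experimental context that defines the stress scale
#' \eqn{\eta Q / L^3} and the modulus scale \eqn{\eta Q / L^2}: channel side
#' length, flow rate and effective buffer viscosity, plus the camera pixel
#' size. All arguments are given in the units customary at the instrument
#' (micrometres, microlitres per second, millipascal seconds); they are stored
#' in SI internally.
#'
#' @param channel_um side length \eqn{L} of the square channel cross-section
#'   in micrometres (reference setup: 20).
#' @param flow_ul_s flow rate \eqn{Q} in microlitres per second (reference:
#'   0.04).
#' @param viscosity_mpa_s effective buffer viscosity \eqn{\eta} in mPa s.
#'   Either this or `medium` must be given; see [viscosity_lookup()].
#' @param medium optional buffer label understood by [viscosity_lookup()],
#'   e.g. `"CellCarrierB"`; used when `viscosity_mpa_s` is missing.
#' @param pixel_um camera pixel size in micrometres per pixel (default 0.34).
#'
#' @return An object of class `guv_setup` with SI fields `L`, `Q`, `eta`,
#'   `px` (m, m^3/s, Pa s, m) and the derived equivalent cylindrical channel
#'   radius `R` (see [equivalent_radius()]).
#' @examples
#' setup <- channel_setup(20, 0.04, viscosity_mpa_s = 15)
#' modulus_scale(setup)   # eta*Q/L^2 in N/m
#' @export
channel_setup <- function(channel_um = 20, flow_ul_s = 0.04,
                          viscosity_mpa_s = NULL, medium = NULL,
                          pixel_um = 0.34) {
  if (is.null(viscosity_mpa_s)) {
    if (is.null(medium))
      guv_stop("guvmech_config_error",
               "supply either viscosity_mpa_s or a known medium label")
    viscosity_mpa_s <- viscosity_lookup(flow_ul_s, medium) * 1e3
  }
  stopifnot(channel_um > 0, flow_ul_s > 0, viscosity_mpa_s > 0, pixel_um > 0)
  L <- channel_um * 1e-6
  out <- structure(list(
    L = L,
    Q = flow_ul_s * 1e-9,          # 1 uL = 1e-9 m^3
    eta = viscosity_mpa_s * 1e-3,
    px = pixel_um * 1e-6,
    R = equivalent_radius(L),
    medium = medium
  ), class = "guv_setup")
  out
}

#' Reference channel setup
#'
#' The setup used for the response-surface calibration: \eqn{L' = 20} um,
#' \eqn{Q' = 0.04} uL/s, \eqn{\eta' = 15} mPa s.
#' @return A `guv_setup`.
#' @export
reference_setup <- function() {
  channel_setup(channel_um = 20, flow_ul_s = 0.04, viscosity_mpa_s = 15)
}

#' @export
print.guv_setup <- function(x, ...) {
  cat(sprintf("RT-DC channel setup: L = %g um, Q = %g uL/s, eta = %g mPa s\n",
              x$L * 1e6, x$Q * 1e9, x$eta * 1e3))
  cat(sprintf("  pixel %g um, equivalent radius %.4g um, modulus scale %.4g N/m\n",
              x$px * 1e6, x$R * 1e6, modulus_scale(x)))
  invisible(x)
}

#' Modulus scale of a setup
#'
#' \eqn{\eta Q / L^2} in N/m; multiplying the dimensionless \eqn{\hat K} by
#' this scale gives the physical area expansion modulus.
#' @param setup a [channel_setup()].
#' @return scalar, N/m.
#' @export
modulus_scale <- function(setup) setup$eta * setup$Q / setup$L^2

#' Nondimensionalize / redimensionalize the area expansion modulus
#'
#' \eqn{\hat K = K L^2/(\eta Q)}; `dim_K()` is the exact inverse.
#'
#' @param K area expansion modulus in N/m (positive).
#' @param K_hat dimensionless modulus.
#' @param setup a [channel_setup()].
#' @return `nondim_K`: dimensionless \eqn{\hat K}; `dim_K`: N/m.
#' @examples
#' s <- channel_setup(20, 0.04, 6.3)
#' nondim_K(0.186, s)   # ~295.2
#' @export
nondim_K <- function(K, setup) {
  stopifnot(all(K > 0))
  K / modulus_scale(setup)
}

#' @rdname nondim_K
#' @export
dim_K <- function(K_hat, setup) K_hat * modulus_scale(setup)

#' Nondimensionalize an event area
#'
#' \eqn{\hat A = A / L^2} with \eqn{A} in square micrometres.
#' @param area_um2 projected area in um^2.
#' @param setup a [channel_setup()].
#' @return dimensionless relative area.
#' @export
nondim_A <- function(area_um2, setup) area_um2 * 1e-12 / setup$L^2

#' Rescale moduli and areas between setups
#'
#' A change of setup from `from` \eqn{(\eta_1, Q_1, L_1)} to `to`
#' \eqn{(\eta_2, Q_2, L_2)} leaves the dimensionless state invariant, so the
#' physical modulus rescales by \eqn{(\eta_2 Q_2 L_1^2)/(\eta_1 Q_1 L_2^2)}
#' and areas by \eqn{(L_2/L_1)^2}. The rescaling forms a group: composing
#' a->b and b->c equals a->c exactly.
#'
#' @param K modulus in N/m (vectorized).
#' @param area_um2 projected areas in um^2 (vectorized).
#' @param from,to [channel_setup()] objects.
#' @return rescaled modulus (N/m) or area (um^2).
#' @export
rescale_K <- function(K, from, to) K * rescale_factor(from, to)

#' @rdname rescale_K
#' @export
rescale_factor <- function(from, to) {
  (to$eta * to$Q * from$L^2) / (from$eta * from$Q * to$L^2)
}

#' @rdname rescale_K
#' @export
rescale_A <- function(area_um2, from, to) area_um2 * (to$L / from$L)^2

#' Capillary-number diagnostics
#'
#' \eqn{Ca = \eta \dot\gamma r / K} compares the external viscous stress with
#' the membrane's resistance to area expansion; \eqn{Ca_\kappa = \eta
#' \dot\gamma r^3 / \kappa} is the analogue based on the bending rigidity
#' \eqn{\kappa}. Values of \eqn{Ca_\kappa \gg 1} indicate that bending
#' contributions to the stationary shape are negligible and the deformation is
#' governed by area dilation alone.
#'
#' @param r vesicle radius in m (vectorized).
#' @param K area expansion modulus in N/m.
#' @param setup a [channel_setup()]; supplies \eqn{\eta}.
#' @param shear_rate approximate shear rate in 1/s; defaults to
#'   [shear_rate()] of the setup.
#' @param kappa bending rigidity in N m (default 1e-19, typical for GUVs).
#' @return list with numeric vectors `Ca` and `Ca_kappa`.
#' @examples
#' capillary_numbers(6.5e-6, K = 0.4, setup = reference_setup())
#' @export
capillary_numbers <- function(r, K, setup, shear_rate = NULL,
                              kappa = 1e-19) {
  stopifnot(all(r > 0), all(K > 0), kappa > 0)
  if (is.null(shear_rate)) shear_rate <- guvmech::shear_rate(setup)
  list(Ca = setup$eta * shear_rate * r / K,
       Ca_kappa = setup$eta * shear_rate * r^3 / kappa)
}

#' Approximate wall shear rate of a setup
#'
#' A diagnostic, not a fitted quantity: ~35 000 1/s at the reference setup,
#' scaled as \eqn{Q/L^3} for other setups.
#' @param setup a [channel_setup()].
#' @return shear rate in 1/s.
#' @export
shear_rate <- function(setup) {
  ref <- list(Q = 0.04e-9, L = 20e-6)
  35000 * (setup$Q / ref$Q) * (ref$L / setup$L)^3
}

#' Equivalent cylindrical channel radius
#'
#' Radius of the cylinder that maps the square cross-section onto an
#' axisymmetric model; the ratio R/L = 10.94/20 = 0.547 is fixed. Used for
#' diagnostics such as the centerline velocity, not for the estimators.
#' @param L channel side length in m.
#' @return radius in m.
#' @export
equivalent_radius <- function(L) {
  stopifnot(all(L > 0))
  0.547 * L
}

#' Centerline velocity of Poiseuille flow in the equivalent cylinder
#'
#' \eqn{v_{max} = 2Q/(\pi R^2)}; ~0.21 m/s at the reference setup.
#' @param setup a [channel_setup()].
#' @return velocity in m/s.
#' @export
centerline_velocity <- function(setup) 2 * setup$Q / (pi * setup$R^2)

# effective viscosities of shear-thinning measurement buffers, tabulated per
# (medium, flow rate); no rheology model is implemented
.viscosity_table <- list(
  CellCarrierB = c("0.04" = 6.3e-3, "0.08" = 4.7e-3)
)

#' Tabulated effective buffer viscosity
#'
#' Effective viscosity of a shear-thinning measurement buffer at a given flow
#' rate in a 20 um channel. Only tabulated (medium, flow rate) pairs are
#' available -- e.g. 0.59% MC-PBS ("CellCarrierB") at 0.04 uL/s (6.3 mPa s)
#' and 0.08 uL/s (4.7 mPa s). For anything else, pass the viscosity to
#' [channel_setup()] explicitly.
#'
#' @param flow_ul_s flow rate in uL/s.
#' @param medium buffer label.
#' @return viscosity in Pa s.
#' @export
viscosity_lookup <- function(flow_ul_s, medium) {
  tab <- .viscosity_table[[medium]]
  if (is.null(tab))
    guv_stop("guvmech_config_error",
             "no viscosity table for medium '%s'; supply viscosity_mpa_s", medium)
  hit <- which(abs(as.numeric(names(tab)) - flow_ul_s) < 1e-9)
  if (!length(hit))
    guv_stop("guvmech_config_error",
             "no tabulated viscosity for %s at Q = %g uL/s; supply viscosity_mpa_s",
             medium, flow_ul_s)
  unname(tab[hit])
}
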