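# The calibrated response surface and slope law, and their recreation from a
# simulation table.
#
# Direct surface:  K^ = gamma * D^(-beta * A^^alpha) * A^^(-delta)
# Slope law:       K^ = a * (dD/dA^)^(-b)
# with K^ = K*L^2/(eta*Q) and A^ = A/L^2. Both laws are dimensionless, so one
# calibration serves every flow rate, viscosity and channel size.

#' Calibration constants of the deformation response
#'
#' Container for the fitted constants of the direct response surface
#' \eqn{\hat K = \gamma D^{-\beta \hat A^\alpha} \hat A^{-\delta}} and of the
#' collective slope law \eqn{\hat K = a\,s^{-b}} (with \eqn{s = dD/d\hat A}
#' the slope of the deformation--area relation), together with their validity
#' ranges. The built-in values were obtained from axisymmetric phase-field
#' simulations of fluid vesicles in a square RT-DC channel; they are stated
#' for the SI nondimensionalization \eqn{\hat K = K L^2/(\eta Q)} (quoting
#' the same surface under a different unit convention rescales \eqn{\gamma}
#' and \eqn{a} by a common factor and leaves all estimates unchanged).
#'
#' @param alpha,beta,gamma,delta constants of the direct surface (defaults
#'   0.5, 2.16, 0.34, 1).
#' @param a,b constants of the slope law (defaults 1.5, 1.75).
#' @param valid_D deformation range over which the surface was calibrated.
#' @param valid_Ahat relative-area range \eqn{\hat A} of the calibration.
#' @param provenance `"built-in"` or `"refit"`.
#' @return object of class `guv_calibration`.
#' @seealso [fit_direct_surface()], [fit_slope_law()] to recreate the
#'   constants from a simulation table.
#' @export
guv_calibration <- function(alpha = 0.5, beta = 2.16, gamma = 0.34,
                            delta = 1, a = 1.5, b = 1.75,
                            valid_D = c(0, 0.06),
                            valid_Ahat = c(0.12, 0.56),
                            provenance = "built-in") {
  stopifnot(alpha > 0, beta > 0, gamma > 0, delta > 0, a > 0, b > 0,
            diff(valid_D) > 0, diff(valid_Ahat) > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 a = a, b = b, valid_D = valid_D, valid_Ahat = valid_Ahat,
                 provenance = provenance),
            class = "guv_calibration")
}

#' @rdname guv_calibration
#' @export
default_calibration <- function() guv_calibration()

#' @export
print.guv_calibration <- function(x, ...) {
  cat(sprintf("GUV deformation calibration (%s)\n", x$provenance))
  cat(sprintf("  surface: alpha=%g beta=%g gamma=%g delta=%g\n",
              x$alpha, x$beta, x$gamma, x$delta))
  cat(sprintf("  slope law: a=%g b=%g\n", x$a, x$b))
  cat(sprintf("  validity: D in [%g, %g], A/L^2 in [%g, %g]\n",
              x$valid_D[1], x$valid_D[2], x$valid_Ahat[1], x$valid_Ahat[2]))
  invisible(x)
}

# surface evaluated on dimensionless coordinates
khat_surface <- function(D, Ahat, calib) {
  calib$gamma * D^(-calib$beta * Ahat^calib$alpha) * Ahat^(-calib$delta)
}

#' Ordinary least-squares line fit
#'
#' Thin wrapper around [stats::lm()] returning slope, free intercept and
#' \eqn{R^2}; the slope of the deformation--area relation is the sufficient
#' statistic of the collective estimator.
#'
#' @param x,y numeric vectors of equal length; at least two distinct `x`.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2 || length(unique(x)) < 2)
    guv_stop("guvmech_fit_error", "need >= 2 distinct x values for a line fit")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n = length(x))
}

#' Read a simulation table
#'
#' CSV with columns `K_N_per_m`, `area_um2`, `deform` (optional `radius_um`):
#' one row per simulated stationary vesicle shape.
#' @param path file path.
#' @return data.frame.
#' @export
read_sim_table <- function(path) {
  sim <- utils::read.csv(path, comment.char = "#")
  need <- c("K_N_per_m", "area_um2", "deform")
  miss <- setdiff(need, names(sim))
  if (length(miss))
    guv_stop("guvmech_schema_error", "simulation table lacks column(s): %s",
             paste(miss, collapse = ", "))
  stopifnot(all(sim$K_N_per_m > 0), all(sim$area_um2 > 0),
            all(sim$deform > 0 & sim$deform < 1))
  sim
}

#' Refit the direct response surface from a simulation table
#'
#' Two-step Levenberg--Marquardt least squares on the \eqn{\hat K} residuals:
#' the squared difference between the surface prediction and the
#' nondimensionalized simulation moduli is minimized. In the default
#' two-step form, \eqn{\alpha = 0.5} and \eqn{\delta = 1} are held fixed and
#' only \eqn{(\beta, \gamma)} are solved for, which conditions the problem
#' well; `fix_alpha_delta = FALSE` solves for all four constants.
#'
#' @param sim data.frame as from [read_sim_table()].
#' @param setup the [channel_setup()] the simulations were run at.
#' @param fix_alpha_delta fix \eqn{\alpha} and \eqn{\delta} (default TRUE).
#' @param start starting constants (a `guv_calibration`); defaults to the
#'   built-in calibration.
#' @return list with elements `calibration` (provenance `"refit"`; slope-law
#'   constants carried over from `start`) and `report` (estimates,
#'   \eqn{R^2}, SSR, n, convergence flag).
#' @export
fit_direct_surface <- function(sim, setup, fix_alpha_delta = TRUE,
                               start = default_calibration()) {
  if (nrow(sim) < 4 || length(unique(sim$K_N_per_m)) < 2 ||
      length(unique(sim$area_um2)) < 2)
    guv_stop("guvmech_fit_error",
             "need >= 4 simulation records spanning multiple K and A")
  Ahat <- nondim_A(sim$area_um2, setup)
  Khat <- nondim_K(sim$K_N_per_m, setup)
  D <- sim$deform

  resid_fn <- function(par) {
    cal <- if (fix_alpha_delta)
      list(alpha = start$alpha, beta = par[["beta"]],
           gamma = par[["gamma"]], delta = start$delta)
    else as.list(par)
    khat_surface(D, Ahat, cal) - Khat
  }
  par0 <- if (fix_alpha_delta) c(beta = start$beta, gamma = start$gamma)
          else c(alpha = start$alpha, beta = start$beta,
                 gamma = start$gamma, delta = start$delta)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  converged <- fit$info %in% 1:4
  if (!converged)
    guv_warn("surface refit did not converge (nls.lm info %d): %s",
             fit$info, fit$message)
  par <- as.list(coef(fit))
  if (fix_alpha_delta) {
    par$alpha <- start$alpha; par$delta <- start$delta
  }
  ssr <- sum(resid_fn(coef(fit))^2)
  r2 <- 1 - ssr / sum((Khat - mean(Khat))^2)
  cal <- guv_calibration(alpha = par$alpha, beta = par$beta,
                         gamma = par$gamma, delta = par$delta,
                         a = start$a, b = start$b,
                         valid_D = range(D), valid_Ahat = range(Ahat),
                         provenance = "refit")
  list(calibration = cal,
       report = list(estimates = unlist(par[c("alpha", "beta", "gamma",
                                              "delta")]),
                     r_squared = r2, ssr = ssr, n = nrow(sim),
                     converged = converged))
}

#' Refit the collective slope law from a simulation table
#'
#' For each simulated modulus, the slope of the deformation--area relation is
#' obtained by ordinary least squares (free intercept); the power law
#' \eqn{\hat K = a s^{-b}} is then fitted as a line in log--log space, which
#' is well conditioned and exact for noise-free power-law data.
#'
#' @inheritParams fit_direct_surface
#' @return list with `calibration` (updated `a`, `b`; surface constants from
#'   `start`) and `report` (`a`, `b`, \eqn{R^2} of the log--log line, number
#'   of K groups used and dropped).
#' @export
fit_slope_law <- function(sim, setup, start = default_calibration()) {
  groups <- split(sim, sim$K_N_per_m)
  usable <- vapply(groups, function(g)
    length(unique(g$area_um2)) >= 2, logical(1))
  if (any(!usable))
    guv_warn("%d K group(s) with < 2 distinct areas excluded from slope-law fit",
             sum(!usable))
  groups <- groups[usable]
  if (length(groups) < 2)
    guv_stop("guvmech_fit_error", "need >= 2 K groups with >= 2 areas each")
  slopes <- vapply(groups, function(g) {
    linear_fit(nondim_A(g$area_um2, setup), g$deform)$slope
  }, numeric(1))
  if (any(slopes <= 0))
    guv_stop("guvmech_fit_error", "non-positive deformation-area slope in simulation group")
  Khat <- nondim_K(as.numeric(names(groups)), setup)
  ll <- linear_fit(log(slopes), log(Khat))
  cal <- guv_calibration(alpha = start$alpha, beta = start$beta,
                         gamma = start$gamma, delta = start$delta,
                         a = exp(ll$intercept), b = -ll$slope,
                         valid_D = start$valid_D,
                         valid_Ahat = start$valid_Ahat,
                         provenance = "refit")
  list(calibration = cal,
       report = list(a = exp(ll$intercept), b = -ll$slope,
                     r_squared = ll$r_squared,
                     n_groups = length(groups),
                     n_dropped = sum(!usable)))
}

#' Serialize / restore a calibration
#'
#' JSON round trip including provenance and validity ranges.
#' @param calib a `guv_calibration`.
#' @param path file path.
#' @return `read_calibration` returns a `guv_calibration`.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::fromJSON(path)
  guv_calibration(alpha = x$alpha, beta = x$beta, gamma = x$gamma,
                  delta = x$delta, a = x$a, b = x$b,
                  valid_D = x$valid_D, valid_Ahat = x$valid_Ahat,
                  provenance = x$provenance)
}
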