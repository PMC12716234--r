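# The three K-extraction strategies: direct (per event), collective
# (population slope), and combined (mixture-filtered collective), plus the
# Gaussian mixture machinery on ln K.
#
# Events are data frames with columns `area_um` (projected area, um^2) and
# `deform` (dimensionless), the de-facto RT-DC feature names.

check_events <- function(events) {
  if (!is.data.frame(events) ||
      !all(c("area_um", "deform") %in% names(events)))
    guv_stop("guvmech_schema_error",
             "events must be a data.frame with columns area_um and deform")
  invisible(events)
}

validity_flags <- function(D, Ahat, calib) {
  (D < calib$valid_D[1] | D > calib$valid_D[2] |
     Ahat < calib$valid_Ahat[1] | Ahat > calib$valid_Ahat[2])
}

#' Per-event (direct) extraction of the area expansion modulus
#'
#' Evaluates the calibrated response surface at each event's
#' \eqn{(D, \hat A)} and converts to physical units:
#' \deqn{K = \frac{\eta Q}{L^2}\,\gamma\,D^{-\beta \hat A^{\alpha}}\,
#'       \hat A^{-\delta}.}
#' \eqn{K} is strictly decreasing in \eqn{D} at fixed area: softer vesicles
#' are more deformed. Events outside the calibration validity ranges are
#' still evaluated but flagged (attribute `"outside_validity"`); events with
#' \eqn{D \le 0} have no defined modulus and yield `NA` with a warning.
#'
#' @param events data.frame with `area_um`, `deform`, or a numeric vector of
#'   deformations if `area_um` is supplied separately.
#' @param setup a [channel_setup()].
#' @param calib a [guv_calibration()]; defaults to the built-in constants.
#' @param area_um areas in um^2 when `events` is a bare deformation vector.
#' @return numeric vector of moduli (N/m), one per event, with attribute
#'   `outside_validity` (logical vector).
#' @examples
#' s <- reference_setup()
#' direct_K(data.frame(area_um = 130, deform = 0.03), s)
#' @export
direct_K <- function(events, setup, calib = default_calibration(),
                     area_um = NULL) {
  if (is.numeric(events) && !is.null(area_um))
    events <- data.frame(area_um = area_um, deform = events)
  check_events(events)
  stopifnot(all(events$area_um > 0, na.rm = TRUE))
  D <- events$deform
  Ahat <- nondim_A(events$area_um, setup)
  bad <- !is.finite(D) | D <= 0
  if (any(bad))
    guv_warn("%d event(s) with D <= 0: modulus undefined, returning NA",
             sum(bad))
  K <- rep(NA_real_, length(D))
  K[!bad] <- dim_K(khat_surface(D[!bad], Ahat[!bad], calib), setup)
  attr(K, "outside_validity") <- validity_flags(D, Ahat, calib)
  K
}

#' Forward model: stationary deformation of a vesicle with known modulus
#'
#' Unique inverse of the direct response surface: the deformation \eqn{D > 0}
#' that a vesicle of modulus \eqn{K} and projected area \eqn{A} assumes in a
#' given setup,
#' \deqn{D = \left(\frac{\gamma}{\hat K \hat A^{\delta}}\right)^{1/(\beta
#'   \hat A^{\alpha})}.}
#' Monotone decreasing in \eqn{K} (rigid limit \eqn{D \to 0}) and increasing
#' in \eqn{A} over the calibration domain. Used by the synthetic generator
#' and for round-trip checks of [direct_K()].
#'
#' @param K modulus in N/m (vectorized).
#' @param area_um2 projected area in um^2 (vectorized).
#' @inheritParams direct_K
#' @return deformation (dimensionless).
#' @export
forward_D <- function(K, area_um2, setup, calib = default_calibration()) {
  stopifnot(all(K > 0), all(area_um2 > 0))
  Ahat <- nondim_A(area_um2, setup)
  Khat <- nondim_K(K, setup)
  exp(log(calib$gamma / (Khat * Ahat^calib$delta)) /
        (calib$beta * Ahat^calib$alpha))
}

#' Collective (slope-based) extraction of the area expansion modulus
#'
#' Fits a free-intercept least-squares line to the deformation--area diagram
#' and converts its slope through the calibrated power law
#' \deqn{K = \frac{\eta Q}{L^2}\, a \,(s\,L^2)^{-b},}
#' where \eqn{s = dD/dA}. Because measurement noise is averaged on the data
#' before the nonlinear map, this estimator is far less noise-sensitive than
#' averaging per-event moduli.
#'
#' @param events data.frame with `area_um`, `deform` (>= 2 distinct areas).
#' @inheritParams direct_K
#' @return a `guv_estimate`: list with `K` (N/m), `method = "collective"`,
#'   `slope` (1/um^2), `intercept`, `r_squared`, `n_used`.
#' @export
collective_K <- function(events, setup, calib = default_calibration()) {
  check_events(events)
  keep <- is.finite(events$area_um) & is.finite(events$deform)
  ev <- events[keep, ]
  if (nrow(ev) < 2 || length(unique(ev$area_um)) < 2)
    guv_stop("guvmech_fit_error",
             "collective fit needs >= 2 events with distinct areas")
  fit <- linear_fit(nondim_A(ev$area_um, setup), ev$deform)
  if (fit$slope <= 0)
    guv_stop("guvmech_slope_error",
             "non-positive deformation-area slope (%.3g): collective power law undefined",
             fit$slope)
  Khat <- calib$a * fit$slope^(-calib$b)
  new_estimate(K = dim_K(Khat, setup), method = "collective",
               n_used = nrow(ev), n_rejected = sum(!keep),
               slope = fit$slope / (setup$L * 1e6)^2,  # per um^2
               slope_nd = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared)
}

new_estimate <- function(...) structure(list(...), class = "guv_estimate")

#' @export
print.guv_estimate <- function(x, ...) {
  cat(sprintf("GUV population estimate (%s): K = %.4g N/m  [n = %d]\n",
              x$method, x$K, x$n_used))
  if (!is.null(x$slope_nd))
    cat(sprintf("  dD/dA^ = %.4g, intercept = %.4g, R^2 = %.3f\n",
                x$slope_nd, x$intercept, x$r_squared))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gaussian mixture on ln K (1-D EM)

#' Fit a Gaussian mixture model to log-moduli
#'
#' Maximum-likelihood Gaussian mixture on \eqn{\ln K} by
#' expectation--maximization. Multiplicative (lognormal) measurement noise on
#' the non-negative deformation makes per-event moduli lognormal, so genuine
#' vesicle populations appear as Gaussian components on the log scale while
#' missegmented events (doublets, misplaced contours) form a separate
#' low-modulus component.
#'
#' The EM uses quantile-based initialization plus seeded jittered restarts,
#' keeps the solution with the best log-likelihood, floors component
#' variances, and reports components in ascending order of their means. The
#' log-likelihood is non-decreasing over iterations (an invariant of EM that
#' is tested).
#'
#' @param K_values positive moduli (N/m); needs at least
#'   `10 * n_components` finite values.
#' @param n_components number of Gaussian components (2 for a homogeneous
#'   sample plus outliers, 3 for a suspected two-population mixture).
#' @param seed integer seed; all restarts derive from it.
#' @param n_restarts EM restarts (default 10).
#' @param max_iter,tol iteration cap (500) and log-likelihood convergence
#'   tolerance (1e-8).
#' @param var_floor lower bound on component variances (default 1e-6); a
#'   floored component is flagged.
#' @return object of class `guv_mixture`: `weights`, `means`, `sds` (on ln
#'   K), `loglik`, `loglik_trace`, `n`, `n_iter`, `converged`,
#'   `var_floored`, `seed`.
#' @export
fit_lnK_mixture <- function(K_values, n_components = 2, seed,
                            n_restarts = 10, max_iter = 500, tol = 1e-8,
                            var_floor = 1e-6) {
  x <- K_values[is.finite(K_values) & K_values > 0]
  if (length(x) < 10 * n_components)
    guv_stop("guvmech_fit_error",
             "need >= %d finite positive K values for %d components",
             10 * n_components, n_components)
  x <- log(x)
  n <- length(x)
  k <- n_components

  em_run <- function(mu0, sigma0, w0) {
    mu <- mu0; sigma <- sigma0; w <- w0
    trace <- numeric(0)
    ll_old <- -Inf
    floored <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k),
                     function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                     numeric(n))
      rs <- rowSums(dens)
      rs[rs == 0] <- .Machine$double.xmin
      ll <- sum(log(rs))
      trace <- c(trace, ll)
      resp <- dens / rs
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      v <- colSums(resp * (outer(x, mu, "-"))^2) / nk
      if (any(v < var_floor)) {
        v <- pmax(v, var_floor)
        floored <- TRUE
      }
      sigma <- sqrt(v)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(mu = mu, sigma = sigma, w = w, loglik = ll, trace = trace,
         n_iter = it, converged = it < max_iter, floored = floored)
  }

  best <- NULL
  with_seed(seed, {
    qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    spread <- sd(x)
    for (r in seq_len(n_restarts)) {
      mu0 <- if (r == 1) qs else qs + rnorm(k, sd = 0.5 * spread)
      run <- em_run(sort(mu0), rep(max(spread / k, sqrt(var_floor)), k),
                    rep(1 / k, k))
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  })
  ord <- order(best$mu)
  if (best$floored)
    guv_warn("EM variance floor hit (degenerate component); variances floored at %g",
             var_floor)
  structure(list(weights = best$w[ord], means = best$mu[ord],
                 sds = best$sigma[ord], n_components = k,
                 loglik = best$loglik, loglik_trace = best$trace,
                 n = n, n_iter = best$n_iter, converged = best$converged,
                 var_floored = best$floored, seed = seed),
            class = "guv_mixture")
}

#' @export
print.guv_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture on ln K (%d components, n = %d, loglik = %.2f)\n",
              x$n_components, x$n, x$loglik))
  for (j in seq_len(x$n_components))
    cat(sprintf("  comp %d: weight %.3f  K = exp(mu) = %.4g N/m  sd(lnK) = %.3f%s\n",
                j, x$weights[j], exp(x$means[j]), x$sds[j],
                if (j == 1 && x$n_components > 1) "  [outlier class]" else ""))
  invisible(x)
}

#' Classify events by mixture component
#'
#' Hard assignment of each modulus to the component with the highest
#' posterior probability. Components are indexed in ascending order of their
#' \eqn{\ln K} means; component 1 (lowest modulus, i.e. highest deformation)
#' is the outlier class whenever the model has more than one component.
#' Posterior ties break deterministically to the lower-index component.
#'
#' @param K_values moduli (N/m); non-positive or non-finite values get `NA`.
#' @param model a fitted [fit_lnK_mixture()] model.
#' @return integer vector of component indices (1 = outlier class).
#' @export
classify <- function(K_values, model) {
  out <- rep(NA_integer_, length(K_values))
  ok <- is.finite(K_values) & K_values > 0
  x <- log(K_values[ok])
  post <- vapply(seq_len(model$n_components), function(j)
    model$weights[j] * dnorm(x, model$means[j], model$sds[j]),
    numeric(length(x)))
  post <- matrix(post, ncol = model$n_components)
  # max.col with ties.method = "first" gives the documented lower-index tie rule
  out[ok] <- max.col(post, ties.method = "first")
  out
}

#' Geometric-mean modulus of the dominant mixture component
#'
#' Summarizes a fitted mixture by \eqn{\exp(\mu)} of the highest-weight
#' non-outlier component -- the geometric-mean convention natural for a
#' lognormal population.
#'
#' @param model a fitted [fit_lnK_mixture()] model.
#' @return modulus in N/m.
#' @export
direct_aggregate <- function(model) {
  idx <- if (model$n_components == 1) 1L
         else 1L + which.max(model$weights[-1])
  exp(model$means[idx])
}

#' Combined (mixture-filtered collective) extraction
#'
#' The full noise- and outlier-resistant pipeline: per-event [direct_K()],
#' Gaussian mixture on \eqn{\ln K}, hard classification, removal of the
#' outlier class (lowest modulus), then [collective_K()] on each retained
#' class. With `n_components = 2` a single population estimate is returned;
#' with `n_components = 3` one estimate per retained class (a suspected
#' two-population mixture).
#'
#' @inheritParams collective_K
#' @param n_components mixture components (default 2).
#' @param seed integer seed for the mixture fit.
#' @return a `guv_combined`: list with `estimates` (list of `guv_estimate`,
#'   one per retained class, ascending modulus), `mixture`, `assignment`
#'   (component index per input event, NA where the modulus was undefined),
#'   `class_sizes`, `n_outliers`, `n_undefined`.
#' @export
combined_K <- function(events, setup, calib = default_calibration(),
                       n_components = 2, seed) {
  check_events(events)
  if (n_components < 2)
    guv_stop("guvmech_config_error",
             "combined fitting needs n_components >= 2 (component 1 is the outlier class)")
  Kd <- withCallingHandlers(
    direct_K(events, setup, calib),
    warning = function(w) invokeRestart("muffleWarning"))
  n_undef <- sum(!is.finite(Kd))
  if (n_undef > 0)
    message(sprintf("combined_K: %d event(s) with undefined modulus (D <= 0) excluded",
                    n_undef))
  model <- tryCatch(
    fit_lnK_mixture(Kd, n_components = n_components, seed = seed),
    guvmech_error = function(e)
      guv_stop("guvmech_stage_error", "combined_K [mixture stage]: %s",
               conditionMessage(e)))
  cls <- classify(Kd, model)
  sizes <- tabulate(cls, nbins = n_components)
  ests <- lapply(seq.int(2L, n_components), function(j) {
    sub <- events[!is.na(cls) & cls == j, , drop = FALSE]
    est <- tryCatch(
      collective_K(sub, setup, calib),
      guvmech_error = function(e)
        guv_stop("guvmech_stage_error",
                 "combined_K [collective stage, class %d]: %s", j,
                 conditionMessage(e)))
    est$method <- "combined"
    est
  })
  structure(list(estimates = ests, mixture = model, assignment = cls,
                 class_sizes = sizes, n_outliers = sizes[1],
                 n_undefined = n_undef),
            class = "guv_combined")
}

#' @export
print.guv_combined <- function(x, ...) {
  cat(sprintf("Combined GUV estimate: %d class(es), %d outlier event(s) removed\n",
              length(x$estimates), x$n_outliers))
  for (e in x$estimates) print(e)
  invisible(x)
}
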