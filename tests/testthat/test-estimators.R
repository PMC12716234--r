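test_that("direct extraction inverts the forward model exactly", {
  grid <- expand.grid(K = c(0.1, 0.4, 1.0, 3.0), A = c(80, 140, 200))
  D <- forward_D(grid$K, grid$A, ref)
  Krec <- direct_K(data.frame(area_um = grid$A, deform = D), ref)
  expect_lt(max(abs(Krec / grid$K - 1)), 1e-9)
})

test_that("direct extraction matches an independent transcription of the surface", {
  # symbolic form written out by hand with literal constants
  L <- 20e-6; Q <- 0.04e-9; eta <- 0.015
  Ahat <- 130e-12 / L^2
  K_hand <- eta * Q / L^2 * 0.34 * 0.03^(-2.16 * sqrt(Ahat)) * Ahat^(-1)
  expect_equal(direct_K(data.frame(area_um = 130, deform = 0.03), ref)[1],
               K_hand, tolerance = 1e-12)
  expect_equal(K_hand, 0.117745, tolerance = 1e-5)  # frozen spot value
})

test_that("direct extraction scales with the stress scale and flags validity", {
  ev <- data.frame(area_um = 130, deform = 0.02)
  s2 <- channel_setup(20, 0.08, 30)  # eta*Q quadrupled
  expect_equal(direct_K(ev, s2)[1], 4 * direct_K(ev, ref)[1])
  # strictly decreasing in D at fixed area
  Ks <- direct_K(data.frame(area_um = 130, deform = c(0.01, 0.02, 0.05)), ref)
  expect_true(all(diff(Ks) < 0))
  expect_warning(out <- direct_K(data.frame(area_um = 130, deform = 0), ref),
                 "undefined")
  expect_true(is.na(out[1]))
  flagged <- direct_K(data.frame(area_um = c(130, 20), deform = c(0.02, 0.02)),
                      ref)
  expect_identical(attr(flagged, "outside_validity"), c(FALSE, TRUE))
})

test_that("forward deformation behaves physically", {
  expect_lt(forward_D(1e5, 130, ref), 1e-4)          # rigid limit
  A <- seq(60, 224, by = 8)
  for (K in c(0.15, 0.5, 2))
    expect_true(all(diff(forward_D(K, A, ref)) > 0))  # softer with size
  expect_true(all(diff(forward_D(c(0.1, 0.3, 1, 3), 130, ref)) < 0))
})

test_that("collective estimator needs a positive slope and distinct areas", {
  A <- seq(60, 225, length.out = 50)
  D <- forward_D(0.2, A, ref)
  est <- collective_K(data.frame(area_um = A, deform = D), ref)
  expect_s3_class(est, "guv_estimate")
  expect_identical(est$method, "collective")
  expect_identical(est$n_used, 50L)
  expect_error(collective_K(data.frame(area_um = A, deform = rev(D)), ref),
               class = "guvmech_slope_error")
  expect_error(collective_K(data.frame(area_um = c(100, 100),
                                       deform = c(0.01, 0.02)), ref),
               class = "guvmech_fit_error")
})

test_that("EM mixture recovers moments, weights, and is deterministic", {
  set.seed(7)
  x <- exp(rnorm(800, log(0.2), 0.1))
  m1 <- fit_lnK_mixture(x, 1, seed = 3)
  expect_equal(m1$means, mean(log(x)), tolerance = 1e-6)
  expect_equal(m1$sds, sd(log(x)) * sqrt(799 / 800), tolerance = 1e-3)

  # two well-separated populations (5 sigma), mixing 0.3/0.7
  set.seed(8)
  x2 <- c(exp(rnorm(600, log(0.2), 0.2)), exp(rnorm(1400, log(0.2) + 1, 0.2)))
  m2 <- fit_lnK_mixture(x2, 2, seed = 5)
  expect_equal(m2$weights, c(0.3, 0.7), tolerance = 0.02)
  expect_true(all(diff(m2$means) > 0))       # ascending-mean order
  expect_equal(sum(m2$weights), 1, tolerance = 1e-12)

  # determinism and private RNG stream
  before <- runif(1)
  m2b <- fit_lnK_mixture(x2, 2, seed = 5)
  expect_identical(m2$means, m2b$means)
  expect_identical(m2$loglik, m2b$loglik)

  # EM invariant: log-likelihood non-decreasing over iterations
  expect_true(all(diff(m2$loglik_trace) > -1e-8))

  expect_error(fit_lnK_mixture(x2[1:15], 2, seed = 1),
               class = "guvmech_fit_error")
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(9)
  x <- c(exp(rnorm(500, log(0.15), 0.25)), exp(rnorm(700, log(1.5), 0.3)))
  m <- fit_lnK_mixture(x, 2, seed = 2)
  mc <- mclust::Mclust(log(x), G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(m$loglik, mc$loglik, tolerance = 1e-4)
  expect_equal(sort(m$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1e-3)
})

test_that("classification assigns by posterior with a deterministic tie-break", {
  model <- structure(list(weights = c(0.5, 0.5), means = c(-1, 1),
                          sds = c(0.3, 0.3), n_components = 2L),
                     class = "guv_mixture")
  expect_identical(classify(exp(c(-1, 1)), model), c(1L, 2L))
  # exactly equidistant point: posterior tie resolved to the lower index
  expect_identical(classify(exp(0), model), 1L)
  expect_true(is.na(classify(-5, model)))
})

test_that("dominant-component aggregate uses the geometric-mean convention", {
  model <- structure(list(weights = 1, means = log(0.2), sds = 0.1,
                          n_components = 1L), class = "guv_mixture")
  expect_equal(direct_aggregate(model), 0.2)
  set.seed(11)
  x <- exp(rnorm(4000, log(0.3), 0.2))
  m <- fit_lnK_mixture(x, 1, seed = 1)
  expect_equal(direct_aggregate(m), exp(mean(log(x))), tolerance = 1e-6)
})

test_that("combined pipeline filters injected outliers at the expected rate", {
  gen <- generate_events(population_spec(2000, K = 0.2, seed = 21), ref)
  cmb <- suppressMessages(combined_K(gen$events, ref, seed = 21))
  out_frac <- cmb$n_outliers / nrow(gen$events)
  expect_lt(abs(out_frac - 0.05), 0.02)
  expect_length(cmb$estimates, 1)
  expect_identical(cmb$estimates[[1]]$method, "combined")
  # stage failures carry the stage label
  ev_const <- data.frame(area_um = rep(130, 60),
                         deform = exp(rnorm(60, log(0.02), 0.1)))
  expect_error(suppressMessages(combined_K(ev_const, ref, seed = 1)),
               "collective stage")
})

test_that("noise biases mean per-event modulus upward but not the collective fit", {
  # Jensen: K(D) is convex, so multiplicative D-noise with unit median
  # inflates the arithmetic mean of direct estimates above the truth, while
  # the slope-based collective estimate (noise averaged on the data) is
  # nearly unchanged relative to its noise-free value.
  spec <- population_spec(5000, K = 0.2, sigma_D = 0.15,
                          outlier_fraction = 0, seed = 31)
  gen <- generate_events(spec, ref)
  Kd <- direct_K(gen$events, ref)
  expect_gt(mean(Kd), 0.2)
  expect_equal(exp(mean(log(Kd))), 0.2, tolerance = 0.02)  # geometric mean ~ truth
  clean <- data.frame(area_um = gen$events$area_um, deform = gen$truth$D_true)
  K_noisy <- collective_K(gen$events, ref)$K
  K_clean <- collective_K(clean, ref)$K
  expect_lt(abs(K_noisy / K_clean - 1), 0.03)
})
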