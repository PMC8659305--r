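test_that("sensitivity ratio handles its edge cases", {
  expect_equal(compute_S(2, 2, 3), 0)         # kept estimate
  expect_equal(compute_S(2, 3, 3), 1)         # adopted the social mean
  expect_equal(compute_S(5, 5.1, 5.001), 100) # near-degenerate denominator
  expect_true(is.na(compute_S(2, 2.5, 2)))    # undefined when M = X_p
  expect_equal(compute_S(c(1, 2), c(2, 2), c(3, 4)), c(0.5, 0))
})

test_that("clipping reports the removed fraction exactly", {
  S <- c(runif(95, 0, 1), rep(100, 3), rep(-7, 2))
  cl <- clip_S(S)
  expect_equal(cl$removed_fraction, 5 / 100)
  expect_true(all(cl$values >= -1.05 & cl$values <= 2.05))
  expect_equal(clip_S(runif(50))$removed_fraction, 0)
  # NA (undefined) values are excluded from the denominator
  expect_equal(clip_S(c(NA, 1, 100))$removed_fraction, 0.5)
})

test_that("the mixture fit recovers spike weight and Gaussian moments", {
  set.seed(14)
  S <- c(rep(0, 2000), rnorm(3000, 0.55, 0.3))
  fit <- fit_S_mixture(S)
  expect_s3_class(fit, "mixture_fit")
  expect_lt(abs(fit$P0 - 0.4), 0.03)
  expect_lt(abs(fit$m_g - 0.55), 0.03)
  expect_lt(abs(fit$sigma_g - 0.3), 0.03)
  # the mean relation holds by construction
  expect_equal(fit$mean_S, fit$Pg * fit$m_g)

  all0 <- fit_S_mixture(rep(0, 100))
  expect_equal(all0$P0, 1)
  expect_true(is.na(all0$m_g))
})

test_that("moving bins average the records inside each window", {
  # constant S: every non-empty bin mean equals it
  set.seed(4)
  D <- runif(500, -2, 2)
  curve <- moving_bin_curve(D, rep(0.3, 500))
  expect_true(all(abs(curve$mean_S[curve$n > 0] - 0.3) < 1e-12))

  # a single record appears in all windows containing it
  c1 <- moving_bin_curve(0, 1)
  expect_equal(c1$n > 0, abs(c1$center) <= 0.5 + 1e-12)

  # piecewise-linear mean function is recovered up to bin smoothing
  set.seed(6)
  D <- runif(2e4, -2.5, 2.5)
  S <- 0.25 + 0.1 * abs(D) + rnorm(2e4, 0, 0.05)
  curve <- moving_bin_curve(D, S)
  flat <- curve$center >= 1 & curve$center <= 2  # away from the kink
  expect_lt(max(abs(curve$mean_S[flat] -
                      (0.25 + 0.1 * abs(curve$center[flat])))), 0.02)

  # step = bin size degenerates to disjoint binning
  dj <- moving_bin_curve(D, S, bin_size = 1, step = 1, centers_range = c(-2, 2))
  ref <- vapply(dj$center, function(ctr) mean(S[abs(D - ctr) <= 0.5]), numeric(1))
  expect_equal(dj$mean_S, ref)
})

test_that("the cusp bottom is recovered from a V-shaped curve", {
  centers <- seq(-2, 2, by = 0.1)
  curve <- data.frame(center = centers,
                      mean_S = 0.3 + 0.2 * abs(centers + 0.4),
                      n = 50L)
  expect_lt(abs(fit_D0(curve) - (-0.4)), 0.02)

  sym <- data.frame(center = centers, mean_S = 0.1 + 0.5 * abs(centers), n = 10L)
  expect_lt(abs(as.numeric(fit_D0(sym))), 0.005)

  expect_error(fit_D0(curve[curve$center > 1, ]), "at least 3")
})

test_that("condition-specific fitting intervals follow the documented exceptions", {
  expect_equal(d0_search_interval("random", 3L), c(-1.2, 0.6))
  expect_equal(d0_search_interval("random", 5L), c(-1.2, 0.6))
  expect_equal(d0_search_interval("median", 3L), c(-1.2, 0.6))
  expect_equal(d0_search_interval("median", 5L), c(-1.2, 0.2))
  expect_equal(d0_search_interval("shifted_median", 3L), c(-1.2, 0.2))
  expect_equal(cusp_fit_interval("random", 1L), c(-1.65, 2.5))
  expect_equal(cusp_fit_interval("median", 7L), c(-1.9, 2.5))
  expect_equal(cusp_fit_interval("shifted_median", 9L), c(-1.2, 1.5))
  expect_equal(cusp_fit_interval("median", 3L), c(-2.5, 2.5))
})

test_that("closed-form cusp least squares is exact on noiseless data", {
  set.seed(9)
  D <- runif(500, -2.4, 2.4)
  sig <- runif(500, 0, 0.6)
  S <- 0.3 + ifelse(D < -0.3, 0.07, 0.12) * abs(D + 0.3) - 0.2 * sig
  fit <- fit_cusp(D, S, sig, D0 = -0.3, tau = 3)
  expect_equal(fit$alpha, 0.3, tolerance = 1e-8)
  expect_equal(fit$beta_minus, 0.07, tolerance = 1e-8)
  expect_equal(fit$beta_plus, 0.12, tolerance = 1e-8)
  expect_equal(fit$beta_prime, -0.2, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)

  # symmetric generator gives equal slopes
  S2 <- 0.3 + 0.1 * abs(D + 0.3)
  fit2 <- fit_cusp(D, S2, D0 = -0.3, tau = 1)
  expect_equal(fit2$beta_minus, fit2$beta_plus, tolerance = 1e-8)
  expect_true(is.na(fit2$beta_prime))
})

test_that("normal equations agree with a numeric minimizer", {
  set.seed(10)
  D <- runif(200, -2.4, 2.4)
  sig <- runif(200, 0, 0.6)
  S <- 0.3 + 0.1 * abs(D + 0.2) - 0.2 * sig + rnorm(200, 0, 0.3)
  fit <- fit_cusp(D, S, sig, D0 = -0.2, tau = 5)
  qfun <- function(p)
    sum((S - p[1] - ifelse(D < -0.2, p[2], p[3]) * abs(D + 0.2) - p[4] * sig)^2)
  op <- optim(c(0, 0, 0, 0), qfun, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 2000))
  expect_lt(max(abs(c(fit$alpha, fit$beta_minus, fit$beta_plus, fit$beta_prime) -
                      op$par)), 1e-6)
  expect_equal(fit$rss, op$value, tolerance = 1e-10)
})

test_that("cusp fit names collinear regressors", {
  D <- rep(1, 50)  # all on one branch and constant: |D - D0| collinear with 1
  expect_error(fit_cusp(D, rnorm(50), D0 = 0, tau = 1), "collinear")
})

test_that("profiled D0 is unbiased where the curve-level V-fit is not", {
  set.seed(15)
  n <- 4e4
  D <- rlaplace_trunc(n, 0, 0.7)
  sig <- runif(n, 0.1, 0.5)
  S <- 0.35 + ifelse(D < -0.25, 0.05, 0.12) * abs(D + 0.25) - 0.25 * sig +
    rnorm(n, 0, 0.35)
  d0 <- fit_D0_profile(D, S, sig, tau = 3)
  expect_lt(abs(as.numeric(d0) - (-0.25)), 0.05)
})

test_that("dispersion regressions recover linear parameter laws", {
  # two exact points define the line exactly
  two <- data.frame(mean_sigma = c(0.1, 0.5), Pg = c(0.6, 0.5),
                    m_g = c(0.6, 0.5), sigma_g = c(0.3, 0.4))
  law <- regress_params_vs_sigma(two)
  expect_equal(unname(law$Pg), c(0.625, -0.25))
  expect_equal(unname(law$sigma_g), c(0.275, 0.25))

  set.seed(18)
  sig <- seq(0.05, 0.5, length.out = 12)
  noisy <- data.frame(mean_sigma = sig,
                      Pg = 0.65 - 0.3 * sig + rnorm(12, 0, 0.01),
                      m_g = 0.6 - 0.2 * sig + rnorm(12, 0, 0.01),
                      sigma_g = 0.3 + 0.2 * sig + rnorm(12, 0, 0.01))
  law <- regress_params_vs_sigma(noisy)
  expect_lt(abs(law$m_g["slope"] + 0.2), 0.05)
  expect_lt(abs(law$Pg["slope"] + 0.3), 0.05)

  expect_error(regress_params_vs_sigma(two[1, ]), "at least 2")
})

test_that("the product-law cross term is negligible at realistic slopes", {
  expect_equal(quadratic_cross_term(0.2, 0.2, 0.5), 0.01)
  expect_equal(quadratic_cross_term(0, 0.5, 1), 0)
})
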