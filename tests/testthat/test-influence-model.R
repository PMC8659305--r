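test_that("social summary is the mean and MAD of the shared logs", {
  s <- social_summary(c(2, 4), X_p = 1)
  expect_equal(s$M, 3)
  expect_equal(s$sigma, 1)
  expect_equal(s$D, 2)

  s1 <- social_summary(5.2, X_p = 4)
  expect_equal(s1$sigma, 0)
  expect_equal(s1$tau, 1L)

  expect_error(social_summary(numeric(0), 0), "non-empty")

  set.seed(2)
  for (rep in 1:20) {
    v <- rnorm(sample(2:11, 1))
    s <- social_summary(v, 0)
    expect_equal(s$M, sum(v) / length(v))
    expect_equal(s$sigma, sum(abs(v - mean(v))) / length(v))
  }
})

test_that("expected sensitivity evaluates the linear cusp", {
  p <- influence_params(
    tau1 = list(m_g = 0.5, sigma_g = 0.3, D0 = -0.2, alpha = 0.2,
                beta_minus = 0.05, beta_plus = 0.1),
    tau_gt1 = list(D0 = -0.2, alpha = 0.2, beta_minus = 0.05, beta_plus = 0.1,
                   beta_prime = -0.3, m_g_intercept = 0.7, m_g_slope = -0.4,
                   sigma_g_intercept = 0.3, sigma_g_slope = 0.2))
  # cusp bottom: <S> = alpha
  expect_equal(expected_S(-0.2, 0, 3, p), 0.2 - 0.3 * 0)
  expect_equal(expected_S(-0.2, 0, 1, p), 0.2)
  # hand evaluation: 0.2 + 0.1 * 1.0 - 0.3 * 0.5
  expect_equal(expected_S(0.8, 0.5, 3, p), 0.15)
  # left branch uses beta_minus
  expect_equal(expected_S(-1.2, 0, 3, p), 0.2 + 0.05 * 1)
  # no similarity term at tau = 1
  expect_equal(expected_S(0.8, 0.5, 1, p), 0.2 + 0.1 * 1)

  # no-asymmetry variant is an even function of D
  pna <- apply_variant(p, "no_asymmetry")
  expect_equal(pna$tau_gt1$D0, 0)
  expect_equal(expected_S(0.7, 0.1, 5, pna), expected_S(-0.7, 0.1, 5, pna))
})

test_that("Gaussian parameters interpolate linearly with floors", {
  p <- default_influence_params()
  g1 <- gaussian_params_at(0.9, 1, p)
  expect_equal(g1$m_g, p$tau1$m_g)      # constants at tau = 1
  expect_equal(g1$sigma_g, p$tau1$sigma_g)

  g <- gaussian_params_at(0.5, 3, p)
  expect_equal(g$m_g, 0.65 - 0.2 * 0.5)
  expect_equal(g$sigma_g, 0.30 + 0.2 * 0.5)

  # the floor engages where the law would cross zero
  steep <- influence_params(
    tau1 = p$tau1,
    tau_gt1 = modifyList(p$tau_gt1, list(m_g_intercept = 0.1, m_g_slope = -1)))
  gf <- gaussian_params_at(c(0.05, 0.5), 3, steep)
  expect_equal(gf$m_g, c(0.1 - 0.05, 1e-3))
  expect_equal(gf$n_floor_m, 1L)
})

test_that("spike-and-Gaussian draws close the mean relation <S> = Pg m_g", {
  p <- default_influence_params()
  # <S> = 0 forces S = 0 always
  p0 <- influence_params(
    tau1 = list(m_g = 0.5, sigma_g = 0.3, D0 = 0, alpha = 0,
                beta_minus = 0, beta_plus = 0),
    tau_gt1 = list(D0 = 0, alpha = 0, beta_minus = 0, beta_plus = 0,
                   beta_prime = 0, m_g_intercept = 0.5, m_g_slope = 0,
                   sigma_g_intercept = 0.3, sigma_g_slope = 0))
  set.seed(1)
  expect_true(all(draw_S(rep(0.5, 1000), 0.2, 3, p0) == 0))

  # Pg = 1: pure Gaussian at (m_g, sigma_g)
  set.seed(2)
  pg1 <- influence_params(
    tau1 = p$tau1,
    tau_gt1 = modifyList(p$tau_gt1,
                         list(alpha = 0.65, beta_minus = 0, beta_plus = 0,
                              beta_prime = 0, m_g_intercept = 0.65,
                              m_g_slope = 0, sigma_g_intercept = 0.3,
                              sigma_g_slope = 0)))
  s <- draw_S(rep(0, 1e5), 0, 3, pg1)
  expect_lt(abs(mean(s) - 0.65), 3 * 0.3 / sqrt(1e5))
  expect_equal(sum(attr(s, "kept")), 0)

  # interior Pg: zero fraction and mean match the mixture law
  set.seed(3)
  D <- 0.3; sig <- 0.4; n <- 1e5
  eS <- expected_S(D, sig, 3, p)
  gp <- gaussian_params_at(sig, 3, p)
  pg <- eS / gp$m_g
  s <- draw_S(rep(D, n), sig, 3, p)
  frac0 <- mean(attr(s, "kept"))
  expect_lt(abs(frac0 - (1 - pg)), 3 * sqrt(pg * (1 - pg) / n))
  se_mean <- sqrt((pg * gp$sigma_g^2 + pg * (1 - pg) * gp$m_g^2) / n)
  expect_lt(abs(mean(s) - eS), 3.5 * se_mean)
})

test_that("the update rule is the weighted mean with a floor", {
  expect_equal(update_estimate(1.2, 0, 3), 1.2)
  expect_equal(update_estimate(1.2, 1, 3), 3)
  expect_equal(update_estimate(1, 0.5, 3), 2)
  # extrapolation allowed, then floored at the raw-estimate bound
  expect_equal(update_estimate(1, -2, 3, lower_bound = -0.5), -0.5)
})

test_that("a null model leaves the estimates untouched", {
  null_p <- influence_params(
    tau1 = list(m_g = 0.5, sigma_g = 0.3, D0 = 0, alpha = 0,
                beta_minus = 0, beta_plus = 0),
    tau_gt1 = list(D0 = 0, alpha = 0, beta_minus = 0, beta_plus = 0,
                   beta_prime = 0, m_g_intercept = 0.5, m_g_slope = 0,
                   sigma_g_intercept = 0.3, sigma_g_slope = 0))
  rec <- simulate_experiment(full_questions(), full_design(), null_p,
                             n_runs = 2, seed = 5)
  expect_identical(rec$X_s, rec$X_p)
  expect_true(all(rec$kept))
})

test_that("simulations are bit-identical under the same seed", {
  a <- small_sim(n_runs = 3, seed = 99)
  b <- small_sim(n_runs = 3, seed = 99)
  expect_identical(a, b)
})

test_that("raw estimates never drop below 1", {
  rec <- small_sim(n_runs = 3, seed = 12)
  expect_true(all(rec$X_p > -rec$log_true))
  expect_true(all(rec$X_s >= -rec$log_true))
  expect_true(all(rec$E_p > 1))
  expect_true(all(rec$E_s >= 1))
})

test_that("herding narrows the estimate distribution in every condition", {
  rec <- simulate_experiment(full_questions(), full_design(), herding_params(),
                             n_runs = 20, seed = 8)
  eS <- expected_S(rec$D, rec$sigma, rec$tau, herding_params())
  expect_true(all(eS > 0 & eS < 0.5))
  for (trt in unique(rec$treatment)) {
    for (tv in unique(rec$tau)) {
      sel <- rec$treatment == trt & rec$tau == tv
      before <- mean(abs(rec$X_p[sel] - median(rec$X_p[sel])))
      after <- mean(abs(rec$X_s[sel] - median(rec$X_s[sel])))
      expect_lt(after, before)
    }
  }
})

test_that("asymmetry raises sensitivity to higher social information", {
  rec <- small_sim(n_runs = 10, seed = 21)
  gap <- mean(rec$S[rec$D > 0]) - mean(rec$S[rec$D < 0])
  expect_gt(gap, 0.02)
  # the symmetric variant shows no such gap
  rec_s <- simulate_experiment(full_questions(), full_design(),
                               apply_variant(default_influence_params(),
                                             "no_asymmetry"),
                               n_runs = 10, seed = 21)
  gap_s <- mean(rec_s$S[rec_s$D > 0]) - mean(rec_s$S[rec_s$D < 0])
  expect_lt(abs(gap_s), abs(gap) / 3)
})

test_that("sensitivity falls with shared-set dispersion only in the full model", {
  rec <- small_sim(n_runs = 10, seed = 33)
  rnd <- rec[rec$treatment == "random" & rec$tau > 1, ]
  lo <- rnd$sigma <= median(rnd$sigma)
  drop_full <- mean(rnd$S[lo]) - mean(rnd$S[!lo])
  expect_gt(drop_full, 0.03)

  rec_ns <- simulate_experiment(full_questions(), full_design(),
                                apply_variant(default_influence_params(),
                                              "no_similarity"),
                                n_runs = 10, seed = 33)
  rns <- rec_ns[rec_ns$treatment == "random" & rec_ns$tau > 1, ]
  lo <- rns$sigma <= median(rns$sigma)
  drop_ns <- mean(rns$S[lo]) - mean(rns$S[!lo])
  expect_lt(abs(drop_ns), drop_full / 3)
})
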