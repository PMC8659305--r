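#' Summary of the social information shown to a subject
#'
#' Subjects are assumed to perceive the central tendency and dispersion of
#' the estimates they receive: `M` is the arithmetic mean of the shared
#' log-estimates (the log of the geometric mean of the raw estimates),
#' `sigma` the mean absolute deviation about `M`, and `D = M - X_p` the
#' distance of the social information from the personal estimate.
#'
#' @param shared A `shared_set` from [select_shared()], or a bare numeric
#'   vector of shared log-estimates.
#' @param X_p The focal subject's personal log-estimate.
#' @return A list of class `"social_summary"` with `M`, `sigma`, `tau`
#'   and `D`.  `sigma` is 0 when a single estimate is shared.
#' @export
social_summary <- function(shared, X_p) {
  values <- if (inherits(shared, "shared_set")) shared$values else as.numeric(shared)
  if (length(values) == 0L) stop_domain("shared set must be non-empty")
  M <- mean(values)
  structure(list(M = M,
                 sigma = mean(abs(values - M)),
                 tau = length(values),
                 D = M - X_p),
            class = "social_summary")
}

# pick the tau = 1 or tau > 1 parameter block
param_block <- function(params, tau) if (tau == 1L) params$tau1 else params$tau_gt1

#' Mean sensitivity to social influence (linear cusp)
#'
#' Evaluates `<S>(D, sigma, tau) = alpha + beta_pm |D - D0| + beta' sigma`,
#' using `beta_minus` when `D < D0` and `beta_plus` when `D >= D0`.  The
#' similarity term `beta' sigma` only applies at `tau > 1` (a single
#' shared estimate has no dispersion).  The raw linear value is returned
#' unclamped; probabilities are clamped downstream in [draw_S()].
#'
#' @param D,sigma Distance and dispersion of the received estimates
#'   (vectors, recycled).
#' @param tau Number of shared estimates (vector, recycled).
#' @param params An [influence_params()] object.
#' @return Numeric vector of mean sensitivities.
#' @export
expected_S <- function(D, sigma, tau, params) {
  stopifnot(inherits(params, "influence_params"))
  n <- max(length(D), length(sigma), length(tau))
  D <- rep_len(D, n); sigma <- rep_len(sigma, n); tau <- rep_len(as.integer(tau), n)
  out <- numeric(n)
  for (one in c(TRUE, FALSE)) {
    sel <- if (one) tau == 1L else tau > 1L
    if (!any(sel)) next
    b <- if (one) params$tau1 else params$tau_gt1
    beta <- ifelse(D[sel] < b$D0, b$beta_minus, b$beta_plus)
    out[sel] <- b$alpha + beta * abs(D[sel] - b$D0) +
      if (one) 0 else b$beta_prime * sigma[sel]
  }
  out
}

#' Gaussian mixture parameters at a given dispersion
#'
#' `m_g` and `sigma_g` of the non-zero (Gaussian) part of the sensitivity
#' distribution: constants at `tau = 1`, linear in the dispersion `sigma`
#' at `tau > 1`.  Both are floored at a small positive constant where the
#' linear laws would cross zero at large dispersion, keeping the mixture
#' well defined; floor events are counted.
#'
#' @param sigma Dispersion of the received estimates (vector).
#' @param tau Number of shared estimates (vector, recycled).
#' @param params An [influence_params()] object.
#' @param floor Lower bound applied to `m_g` and `sigma_g`.
#' @return A list with numeric vectors `m_g` and `sigma_g` and integer
#'   floor-event counts `n_floor_m` and `n_floor_s`.
#' @export
gaussian_params_at <- function(sigma, tau, params, floor = 1e-3) {
  stopifnot(inherits(params, "influence_params"))
  n <- max(length(sigma), length(tau))
  sigma <- rep_len(sigma, n); tau <- rep_len(as.integer(tau), n)
  m_g <- s_g <- numeric(n)
  one <- tau == 1L
  if (any(one)) {
    m_g[one] <- params$tau1$m_g
    s_g[one] <- params$tau1$sigma_g
  }
  if (any(!one)) {
    b <- params$tau_gt1
    m_g[!one] <- b$m_g_intercept + b$m_g_slope * sigma[!one]
    s_g[!one] <- b$sigma_g_intercept + b$sigma_g_slope * sigma[!one]
  }
  n_floor_m <- sum(m_g < floor)
  n_floor_s <- sum(s_g < floor)
  list(m_g = pmax(m_g, floor), sigma_g = pmax(s_g, floor),
       n_floor_m = n_floor_m, n_floor_s = n_floor_s)
}

#' Draw sensitivities from the spike-and-Gaussian law
#'
#' With probability `P_g = clamp(<S> / m_g, 0, 1)` a Gaussian deviate
#' `N(m_g, sigma_g)` is returned, otherwise exactly 0 (the agent keeps its
#' personal estimate).  In the unclamped regime the expected drawn value
#' equals the linear-cusp mean `<S>`, closing the relation
#' `<S> = P_g m_g`.  Drawn values are not clipped to the analysis interval
#' `[-1.05, 2.05]`; that restriction is an analysis-side filter only.
#'
#' @inheritParams expected_S
#' @return Numeric vector of sensitivities with attributes `kept` (logical
#'   vector, `TRUE` where the spike fired) and `guards` (counts of P_g
#'   clamps and `m_g`/`sigma_g` floors).
#' @export
draw_S <- function(D, sigma, tau, params) {
  n <- max(length(D), length(sigma), length(tau))
  sigma <- rep_len(sigma, n); tau <- rep_len(tau, n)
  mean_S <- expected_S(D, sigma, tau, params)
  gp <- gaussian_params_at(sigma, tau, params)
  pg_raw <- mean_S / gp$m_g
  pg <- pmin(pmax(pg_raw, 0), 1)
  kept <- runif(n) >= pg
  S <- numeric(n)
  if (any(!kept))
    S[!kept] <- rnorm(sum(!kept), gp$m_g[!kept], gp$sigma_g[!kept])
  structure(S,
            kept = kept,
            guards = c(pg_clamped_low = sum(pg_raw < 0),
                       pg_clamped_high = sum(pg_raw > 1),
                       m_g_floored = gp$n_floor_m,
                       sigma_g_floored = gp$n_floor_s))
}

#' Update a personal estimate with social information
#'
#' `X_s = (1 - S) X_p + S M`, the weighted mean of the personal estimate
#' and the log geometric mean of the received estimates (extrapolation is
#' allowed when `S` falls outside `[0, 1]`).  The result is floored at
#' `lower_bound = -log10(T)` so that raw second estimates never drop below
#' 1.
#'
#' @param X_p Personal log-estimate.
#' @param S Sensitivity to social influence.
#' @param M Mean of the received log-estimates.
#' @param lower_bound Floor applied to the result.
#' @return The second log-estimate `X_s`.
#' @export
update_estimate <- function(X_p, S, M, lower_bound = -Inf) {
  pmax((1 - S) * X_p + S * M, lower_bound)
}
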