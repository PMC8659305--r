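#' Sensitivity to social influence from observed estimates
#'
#' `S = (X_s - X_p) / (M - X_p)`, the weight given to the mean of the
#' received log-estimates.  Undefined when `M = X_p` (the ratio has no
#' meaning there); such records return `NA` and are excluded from all S
#' analyses rather than raising an error.
#'
#' @param X_p,X_s,M Personal and second log-estimates and mean of the
#'   received log-estimates (vectors, recycled).
#' @return Numeric vector of sensitivities, `NA` where `M == X_p`.
#' @export
compute_S <- function(X_p, X_s, M) {
  n <- max(length(X_p), length(X_s), length(M))
  X_p <- rep_len(X_p, n); X_s <- rep_len(X_s, n); M <- rep_len(M, n)
  out <- ifelse(M == X_p, NA_real_, (X_s - X_p) / (M - X_p))
  out[X_s == X_p & !is.na(out)] <- 0  # exact ratio, avoids -0/x noise
  out
}

#' Restrict sensitivities to the analysis interval
#'
#' Large |S| values arise when `M` is very close to `X_p` and do not
#' reflect a large adjustment; they are removed before any S-based
#' statistic.  The default interval is `[-1.05, 2.05]`.
#'
#' @param S Numeric vector of defined sensitivities.
#' @param interval Length-2 numeric interval to keep.
#' @return A list with `values` (the kept sensitivities), `keep` (logical
#'   mask into the input) and `removed_fraction`.
#' @export
clip_S <- function(S, interval = c(-1.05, 2.05)) {
  keep <- !is.na(S) & S >= interval[1] & S <= interval[2]
  n <- sum(!is.na(S))
  list(values = S[keep], keep = keep,
       removed_fraction = if (n == 0L) 0 else sum(!keep & !is.na(S)) / n)
}

#' Fit the spike-and-Gaussian mixture to a sample of sensitivities
#'
#' The distribution of S is modelled as
#' `f(S) = (1 - P_g) delta(S) + P_g Gamma(S; m_g, sigma_g)` with the
#' constraint `<S> = P_g m_g`, i.e. `P_g = mean(S) / m_g`.  The non-zero
#' part of the empirical density (histogram of bin width `bin_width` on
#' `s_range`, normalized by the total count) is fitted against
#' `P_g Gamma` by nonlinear least squares with `m_g` and `sigma_g` as
#' the free parameters.  Exact zeros must be identified upstream by
#' provenance (second estimate equal to the personal estimate), not by a
#' numeric tolerance.
#'
#' @param S Numeric vector of clipped, defined sensitivities.
#' @param bin_width Histogram bin width.
#' @param s_range Histogram support (the clipping interval).
#' @return A list of class `"mixture_fit"`: `P0`, `Pg`, `m_g`, `sigma_g`,
#'   `mean_S`, `rss`, `n`.  `mean_S == Pg * m_g` by construction.  When
#'   all values are zero, `P0 = 1` and the Gaussian parameters are `NA`.
#' @export
fit_S_mixture <- function(S, bin_width = 0.1, s_range = c(-1.05, 2.05)) {
  S <- S[!is.na(S)]
  n <- length(S)
  if (n == 0L) stop_domain("no defined S values to fit")
  mean_S <- mean(S)
  nz <- S[S != 0]
  if (length(nz) == 0L)
    return(structure(list(P0 = 1, Pg = 0, m_g = NA_real_, sigma_g = NA_real_,
                          mean_S = mean_S, rss = 0, n = n),
                     class = "mixture_fit"))
  nz <- nz[nz >= s_range[1] & nz <= s_range[2]]
  breaks <- seq(s_range[1], s_range[2], by = bin_width)
  counts <- tabulate(findInterval(nz, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  dens <- counts / (n * bin_width)
  mids <- breaks[-length(breaks)] + bin_width / 2

  m0 <- mean(nz)
  s0 <- max(sd(nz), bin_width)
  rss_fun <- function(p) sum((dens - (mean_S / p[1]) * dnorm(mids, p[1], p[2]))^2)
  fit <- tryCatch({
    df <- data.frame(mids = mids, dens = dens)
    nl <- nls(dens ~ (mean_S / m) * dnorm(mids, m, s), data = df,
              start = list(m = m0, s = s0),
              control = nls.control(maxiter = 200, warnOnly = FALSE))
    unname(coef(nl))
  }, error = function(e) NULL)
  if (is.null(fit) || fit[2] <= 0 || abs(fit[1]) < 1e-8) {
    op <- optim(c(m0, s0), rss_fun, method = "L-BFGS-B",
                lower = c(-5, 1e-4), upper = c(5, 5))
    if (op$convergence != 0)
      stop_domain("mixture fit did not converge: ", op$message %||% op$convergence)
    fit <- op$par
  }
  m_g <- fit[1]; sigma_g <- abs(fit[2])
  Pg <- mean_S / m_g
  structure(list(P0 = 1 - Pg, Pg = Pg, m_g = m_g, sigma_g = sigma_g,
                 mean_S = mean_S, rss = rss_fun(fit), n = n),
            class = "mixture_fit")
}

#' Moving-bin curve of mean sensitivity against distance
#'
#' Overlapping bins of size `bin_size` whose centers advance in steps of
#' `step` over `centers_range`; each point is the mean S over records with
#' `|D - center| <= bin_size / 2`.  With `step < bin_size` the same data
#' are replicated across several bin placements, trading bin-count against
#' bin-size noise; with `step = bin_size` this degenerates to ordinary
#' disjoint binning.
#'
#' @param D,S Paired numeric vectors.
#' @param bin_size,step,centers_range Binning geometry.
#' @return A data frame with `center`, `mean_S` (`NA` for empty bins) and
#'   `n`.
#' @export
moving_bin_curve <- function(D, S, bin_size = 1, step = 0.1,
                             centers_range = c(-2, 2)) {
  keep <- !is.na(D) & !is.na(S)
  D <- D[keep]; S <- S[keep]
  centers <- seq(centers_range[1], centers_range[2], by = step)
  half <- bin_size / 2
  res <- vapply(centers, function(ctr) {
    inb <- abs(D - ctr) <= half
    k <- sum(inb)
    c(if (k == 0L) NA_real_ else mean(S[inb]), k)
  }, numeric(2))
  data.frame(center = centers, mean_S = res[1, ], n = as.integer(res[2, ]))
}

#' Search interval for the cusp bottom, per condition
#'
#' The cusp bottom `D0` is located within `[-1.2, 0.2]` by default; for
#' three conditions whose empirical curves have a shallow bottom (random
#' treatment at `tau` 3 and 5, median treatment at `tau` 3) the upper
#' bound is extended to 0.6.
#'
#' @param treatment,tau Condition.
#' @return Length-2 numeric interval.
#' @export
d0_search_interval <- function(treatment, tau) {
  wide <- (treatment == "random" && tau %in% c(3L, 5L)) ||
    (treatment == "median" && tau == 3L)
  c(-1.2, if (wide) 0.6 else 0.2)
}

#' Fitting interval for the cusp slopes, per condition
#'
#' The piecewise-linear fit uses records with `D` in `[-2.5, 2.5]` by
#' default; a few conditions use a slightly restricted interval where the
#' sparse extremes would otherwise dominate the fit.
#'
#' @param treatment,tau Condition.
#' @return Length-2 numeric interval.
#' @export
cusp_fit_interval <- function(treatment, tau) {
  if (treatment == "random" && tau %in% c(1L, 11L)) return(c(-1.65, 2.5))
  if (treatment == "median" && tau == 7L) return(c(-1.9, 2.5))
  if (treatment == "shifted_median" && tau == 3L) return(c(-2, 2.5))
  if (treatment == "shifted_median" && tau == 9L) return(c(-1.2, 1.5))
  c(-2.5, 2.5)
}

#' Locate the cusp bottom from a moving-bin curve
#'
#' For each candidate `D0` on a grid over `search_interval`, the curve
#' points inside the interval are fitted by least squares with the
#' V-shaped function `a + b |D - D0|`; the returned `D0` minimizes the
#' residual sum of squares (grid step 0.01, refined by a parabola through
#' the best point and its neighbours).
#'
#' @param curve A data frame from [moving_bin_curve()].
#' @param search_interval Interval searched for the bottom.
#' @param grid_step Grid resolution.
#' @return The estimated `D0`, with the minimal RSS as attribute `rss`.
#' @export
fit_D0 <- function(curve, search_interval = c(-1.2, 0.2), grid_step = 0.01) {
  pts <- curve[!is.na(curve$mean_S) &
                 curve$center >= search_interval[1] &
                 curve$center <= search_interval[2], , drop = FALSE]
  if (nrow(pts) < 3L)
    stop_domain("need at least 3 curve points inside the search interval")
  x <- pts$center; y <- pts$mean_S
  cand <- seq(search_interval[1], search_interval[2], by = grid_step)
  rss <- vapply(cand, function(d0) {
    r <- abs(x - d0)
    sum(stats::lm.fit(cbind(1, r), y)$residuals^2)
  }, numeric(1))
  i <- which.min(rss)
  d0 <- cand[i]
  if (i > 1L && i < length(cand)) {    # parabolic refinement on the grid
    denom <- rss[i - 1L] - 2 * rss[i] + rss[i + 1L]
    if (is.finite(denom) && denom > 0)
      d0 <- d0 + grid_step * (rss[i - 1L] - rss[i + 1L]) / (2 * denom)
  }
  structure(d0, rss = rss[i])
}

#' Locate the cusp bottom by profiling the record-level least squares
#'
#' For each candidate `D0` on a grid over `search_interval`, the full
#' cusp model is fitted to the individual records by [fit_cusp()] and the
#' candidate minimizing the residual sum of squares is returned (with
#' parabolic refinement on the grid).  Unlike the curve-level V-fit of
#' [fit_D0()], profiling the record-level fit is not affected by the
#' moving-bin smoothing, which rounds an asymmetric cusp and drags the
#' apparent bottom toward the shallow-slope side; it is therefore the
#' estimator used by [fit_influence_params()].
#'
#' @inheritParams fit_cusp
#' @param search_interval Interval searched for the bottom.
#' @param grid_step Grid resolution.
#' @return The estimated `D0`, with the minimal RSS as attribute `rss`.
#' @export
fit_D0_profile <- function(D, S, sigma = NULL, tau,
                           search_interval = c(-1.2, 0.2), grid_step = 0.02,
                           fit_interval = c(-2.5, 2.5)) {
  cand <- seq(search_interval[1], search_interval[2], by = grid_step)
  rss <- vapply(cand, function(d0)
    fit_cusp(D, S, sigma, D0 = d0, tau = tau, fit_interval = fit_interval)$rss,
    numeric(1))
  i <- which.min(rss)
  d0 <- cand[i]
  if (i > 1L && i < length(cand)) {
    denom <- rss[i - 1L] - 2 * rss[i] + rss[i + 1L]
    if (is.finite(denom) && denom > 0)
      d0 <- d0 + grid_step * (rss[i - 1L] - rss[i + 1L]) / (2 * denom)
  }
  structure(d0, rss = rss[i])
}

#' Fit the cusp response by closed-form least squares
#'
#' With `D0` fixed, the mean-sensitivity model
#' `S = alpha + beta_minus |D - D0| 1[D < D0] + beta_plus |D - D0|
#' 1[D >= D0] + beta' sigma` is linear in its coefficients; the fit
#' minimizes the unweighted sum of squares over individual records with
#' `D` inside `fit_interval` (every answer has the same weight) and is
#' solved in closed form from the design matrix.  The `beta' sigma` term
#' is omitted at `tau = 1`.
#'
#' @param D,S Individual-record distances and sensitivities.
#' @param sigma Individual-record dispersions (ignored at `tau = 1`).
#' @param D0 Cusp bottom, typically from [fit_D0()].
#' @param tau Number of shared estimates of the condition.
#' @param fit_interval Records with `D` outside it are excluded.
#' @return A list of class `"cusp_fit"`: `D0`, `alpha`, `beta_minus`,
#'   `beta_plus`, `beta_prime` (`NA` at `tau = 1`), `fit_interval`,
#'   `rss`, `n`.
#' @export
fit_cusp <- function(D, S, sigma = NULL, D0, tau, fit_interval = c(-2.5, 2.5)) {
  keep <- !is.na(D) & !is.na(S) & D >= fit_interval[1] & D <= fit_interval[2]
  D <- D[keep]; S <- S[keep]
  with_sigma <- tau > 1L
  if (with_sigma) {
    if (is.null(sigma)) stop_domain("sigma is required when tau > 1")
    sigma <- sigma[keep]
  }
  r <- abs(D - D0)
  X <- cbind(intercept = 1,
             beta_minus = r * (D < D0),
             beta_plus = r * (D >= D0))
  if (with_sigma) X <- cbind(X, beta_prime = sigma)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- colnames(X)[qr_X$pivot[(qr_X$rank + 1L):ncol(X)]]
    stop_domain("rank-deficient cusp design; collinear regressor(s): ",
                paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_X, S)
  res <- S - X %*% beta
  structure(list(D0 = as.numeric(D0),
                 alpha = unname(beta["intercept"]),
                 beta_minus = unname(beta["beta_minus"]),
                 beta_plus = unname(beta["beta_plus"]),
                 beta_prime = if (with_sigma) unname(beta["beta_prime"]) else NA_real_,
                 fit_interval = fit_interval,
                 rss = sum(res^2),
                 n = length(S)),
            class = "cusp_fit")
}

#' Linear laws of the mixture parameters in the dispersion
#'
#' Ordinary least-squares regressions of the per-condition `P_g`, `m_g`
#' and `sigma_g` on the per-condition mean dispersion of the received
#' estimates, plus the product law `P_g m_g` (the mean sensitivity)
#' against dispersion.
#'
#' @param fits A data frame with one row per condition (`tau > 1`) and
#'   columns `mean_sigma`, `Pg`, `m_g`, `sigma_g`.
#' @return A list with one `c(intercept, slope)` vector per parameter
#'   (`Pg`, `m_g`, `sigma_g`, `product`).
#' @export
regress_params_vs_sigma <- function(fits) {
  if (nrow(fits) < 2L) stop_domain("need at least 2 conditions to regress")
  reg <- function(y) {
    co <- coef(lm(y ~ fits$mean_sigma))
    c(intercept = unname(co[1]), slope = unname(co[2]))
  }
  list(Pg = reg(fits$Pg),
       m_g = reg(fits$m_g),
       sigma_g = reg(fits$sigma_g),
       product = reg(fits$Pg * fits$m_g))
}

#' Quadratic cross-term of the product law
#'
#' When `P_g` and `m_g` are both linear in the dispersion, their product
#' contains a quadratic term `b_Pg * b_mg * sigma^2`.  At slopes of 0.2
#' and a dispersion of 0.5 this evaluates to 0.01, small enough for the
#' product law to be treated as linear.
#'
#' @param slope_Pg,slope_mg Slopes of the two linear laws.
#' @param sigma Dispersion at which to evaluate the term.
#' @return The magnitude of the quadratic term.
#' @export
quadratic_cross_term <- function(slope_Pg, slope_mg, sigma) {
  abs(slope_Pg * slope_mg) * sigma^2
}
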