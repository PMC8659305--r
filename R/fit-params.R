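#' Recover the influence-model parameters from a record table
#'
#' The estimation pipeline applied per condition (treatment x tau):
#' sensitivities with `M = X_p` are excluded, the rest are clipped to the
#' analysis interval, the spike-and-Gaussian mixture is fitted
#' ([fit_S_mixture()]), the cusp bottom is located by profiling the
#' record-level least squares ([fit_D0_profile()], search interval from
#' [d0_search_interval()]) and the cusp slopes are fitted over individual
#' records ([fit_cusp()]).  Per
#' treatment, the `tau = 1` fits form the single-estimate block; the
#' `tau > 1` cusp parameters are averaged over tau and the mixture
#' parameters regressed on the mean dispersion to give the linear laws of
#' the multi-estimate block.
#'
#' @param records A simulation or experiment record table with columns
#'   `treatment`, `tau`, `X_p`, `X_s`, `M`, `sigma` (and optionally a
#'   provenance column `kept`; otherwise `X_s == X_p` marks kept records).
#' @param s_interval Clipping interval for S.
#' @param condition_intervals If `TRUE`, use the per-condition cusp
#'   fitting intervals of [cusp_fit_interval()]; otherwise the default
#'   `[-2.5, 2.5]` everywhere.
#' @return A list of class `"influence_fit"`: `params` (named list of
#'   [influence_params()] per treatment), `condition_fits` (one row per
#'   condition with the mixture and cusp estimates), `sigma_laws`
#'   (per-treatment output of [regress_params_vs_sigma()]),
#'   `clip_removed_fraction` and `n_s_undefined`.
#' @export
fit_influence_params <- function(records, s_interval = c(-1.05, 2.05),
                                 condition_intervals = FALSE) {
  need <- c("treatment", "tau", "X_p", "X_s", "M", "sigma")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop_domain("records lack column(s): ", paste(missing, collapse = ", "))

  S_raw <- compute_S(records$X_p, records$X_s, records$M)
  if (!is.null(records$kept)) S_raw[records$kept] <- 0
  n_undef <- sum(is.na(S_raw))
  clip <- clip_S(S_raw, s_interval)

  conds <- unique(records[, c("treatment", "tau")])
  conds <- conds[order(conds$treatment, conds$tau), , drop = FALSE]
  rows <- vector("list", nrow(conds))
  for (k in seq_len(nrow(conds))) {
    tr <- conds$treatment[k]; tv <- conds$tau[k]
    sel <- clip$keep & records$treatment == tr & records$tau == tv
    S <- S_raw[sel]; D <- records$D[sel]; sig <- records$sigma[sel]
    mix <- fit_S_mixture(S, s_range = s_interval)
    f_int <- if (condition_intervals) cusp_fit_interval(tr, tv) else c(-2.5, 2.5)
    D0 <- fit_D0_profile(D, S, sigma = sig, tau = tv,
                         search_interval = d0_search_interval(tr, tv),
                         fit_interval = f_int)
    cusp <- fit_cusp(D, S, sigma = sig, D0 = D0, tau = tv, fit_interval = f_int)
    rows[[k]] <- data.frame(
      treatment = tr, tau = tv, n = mix$n,
      mean_sigma = mean(sig), mean_S = mix$mean_S,
      P0 = mix$P0, Pg = mix$Pg, m_g = mix$m_g, sigma_g = mix$sigma_g,
      D0 = as.numeric(D0), alpha = cusp$alpha,
      beta_minus = cusp$beta_minus, beta_plus = cusp$beta_plus,
      beta_prime = cusp$beta_prime,
      stringsAsFactors = FALSE
    )
  }
  fits <- do.call(rbind, rows)

  params <- list(); laws <- list()
  for (tr in unique(fits$treatment)) {
    sub <- fits[fits$treatment == tr, , drop = FALSE]
    one <- sub[sub$tau == 1L, , drop = FALSE]
    multi <- sub[sub$tau > 1L, , drop = FALSE]
    if (nrow(one) != 1L || nrow(multi) < 2L) next  # blocks need both regimes
    law <- regress_params_vs_sigma(multi)
    laws[[tr]] <- law
    params[[tr]] <- influence_params(
      tau1 = list(m_g = one$m_g, sigma_g = one$sigma_g, D0 = one$D0,
                  alpha = one$alpha, beta_minus = one$beta_minus,
                  beta_plus = one$beta_plus),
      tau_gt1 = list(D0 = mean(multi$D0), alpha = mean(multi$alpha),
                     beta_minus = mean(multi$beta_minus),
                     beta_plus = mean(multi$beta_plus),
                     beta_prime = mean(multi$beta_prime),
                     m_g_intercept = law$m_g["intercept"],
                     m_g_slope = law$m_g["slope"],
                     sigma_g_intercept = max(law$sigma_g["intercept"], 0),
                     sigma_g_slope = law$sigma_g["slope"])
    )
  }
  structure(list(params = params,
                 condition_fits = fits,
                 sigma_laws = laws,
                 clip_removed_fraction = clip$removed_fraction,
                 n_s_undefined = n_undef),
            class = "influence_fit")
}
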