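#' Median of a group's log-estimates
#'
#' The reference value for the median-based sharing treatments: the sample
#' median of all group members' log-estimates (including the focal
#' subject's own), with the even-count convention of averaging the two
#' middle order statistics.
#'
#' @param group_logs Non-empty numeric vector of log-estimates.
#' @return The sample median.
#' @export
group_median_log <- function(group_logs) {
  if (length(group_logs) == 0L) stop_domain("group_logs must be non-empty")
  median(group_logs)
}

#' Bias-compensated shifted median
#'
#' `m' = m / gamma` approximates the log truth when the group's median log
#' estimate underestimates it with slope `gamma < 1`.  For `m > 0` and
#' `gamma < 1` the shifted value exceeds the median; the formula is applied
#' unchanged for `m <= 0`, where `m' <= m`.
#'
#' @param m Group median log-estimate.
#' @param gamma Positive bias slope (0.9 in the emulated experiments).
#' @return The shifted reference value `m / gamma`.
#' @export
shifted_median <- function(m, gamma) {
  if (!is.finite(gamma) || gamma <= 0) stop_domain("gamma must be positive")
  m / gamma
}

#' Select the estimates shared with a focal subject
#'
#' Implements the three sharing treatments.  `random` picks `tau` distinct
#' other group members uniformly without replacement.  `median` and
#' `shifted_median` pick the `tau` other members whose log-estimates are
#' closest to a reference value: the group median `m` (computed over all
#' members, including the focal subject) or the shifted median `m / gamma`.
#' The focal subject's own estimate is never shared back.  Ties in distance
#' are broken deterministically: smaller log-estimate first, then smaller
#' subject index; duplicate values are kept as distinct subject-attached
#' items.
#'
#' @param group_logs Numeric vector of the group's log-estimates, one per
#'   subject (optionally named with subject ids).
#' @param focal Index (or name) of the focal subject in `group_logs`.
#' @param treatment `"random"`, `"median"` or `"shifted_median"`.
#' @param tau Number of estimates to share; must be smaller than the group
#'   size.
#' @param gamma Bias slope used by the shifted-median treatment.
#' @return A list of class `"shared_set"` with elements `values` (the
#'   `tau` shared log-estimates), `source_subjects` (their indices),
#'   `focal`, `treatment`, `tau` and `ref` (the selection reference, `NA`
#'   for the random treatment).
#' @export
select_shared <- function(group_logs, focal, treatment, tau, gamma = 0.9) {
  n <- length(group_logs)
  treatment <- match.arg(treatment, c("random", "median", "shifted_median"))
  tau <- as.integer(tau)
  if (tau >= n) stop_domain("tau must be smaller than the group size")
  if (tau < 1L) stop_domain("tau must be at least 1")
  if (is.character(focal)) focal <- match(focal, names(group_logs))
  if (is.na(focal) || focal < 1L || focal > n) stop_domain("invalid focal subject")

  if (treatment == "random") {
    others <- seq_len(n)[-focal]
    sel <- others[sample.int(n - 1L, tau)]
    ref <- NA_real_
  } else {
    m <- group_median_log(group_logs)
    ref <- if (treatment == "shifted_median") shifted_median(m, gamma) else m
    ord <- order(abs(group_logs - ref), group_logs, seq_len(n))
    ord <- ord[ord != focal]
    sel <- ord[seq_len(tau)]
  }
  structure(list(focal = focal,
                 values = unname(group_logs[sel]),
                 source_subjects = sel,
                 treatment = treatment,
                 tau = tau,
                 ref = ref),
            class = "shared_set")
}
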