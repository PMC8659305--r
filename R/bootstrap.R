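#' Question-level bootstrap of a statistic
#'
#' The sampling unit is the question: each replicate draws `N_Q` question
#' labels with replacement from the `N_Q` questions present and recomputes
#' the statistic on all records of the drawn questions (records of a
#' question drawn twice enter twice).  Error bars are asymmetric: `b_plus`
#' is chosen so that a fraction `conf` of the replicates above the
#' full-data value `x0` lie within `[x0, x0 + b_plus]`, and `b_minus`
#' symmetrically below (`conf = 0.683` by analogy with one standard
#' deviation).
#'
#' @param data A data frame of records.
#' @param statistic Function of a data frame returning a numeric scalar.
#' @param questions Vector of question labels, one per row of `data`.
#' @param n_boot Number of bootstrap replicates.
#' @param conf Coverage used for the asymmetric bars.
#' @param seed Optional integer seed.
#' @return A list of class `"bootstrap_summary"`: `x0`, `b_minus`,
#'   `b_plus`, `samples`, `n_boot`, `conf`, `n_dropped` (replicates where
#'   the statistic was undefined).
#' @export
bootstrap_statistic <- function(data, statistic, questions = data$question,
                                n_boot = 1000L, conf = 0.683, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(questions) != nrow(data))
    stop_domain("questions must have one label per record")
  idx_by_q <- split(seq_len(nrow(data)), questions)
  nq <- length(idx_by_q)
  if (nq < 1L) stop_domain("need at least one question group")
  x0 <- statistic(data)
  samples <- vapply(seq_len(n_boot), function(i) {
    drawn <- sample.int(nq, nq, replace = TRUE)
    rows <- unlist(idx_by_q[drawn], use.names = FALSE)
    as.numeric(statistic(data[rows, , drop = FALSE]))
  }, numeric(1))
  n_dropped <- sum(is.na(samples))
  samples <- samples[!is.na(samples)]
  bars <- bootstrap_bars(samples, x0, conf)
  structure(list(x0 = x0, b_minus = bars["b_minus"], b_plus = bars["b_plus"],
                 samples = samples, n_boot = n_boot, conf = conf,
                 n_dropped = n_dropped),
            class = "bootstrap_summary")
}

# asymmetric error bars from a replicate sample
bootstrap_bars <- function(samples, x0, conf = 0.683) {
  up <- samples[samples > x0] - x0
  down <- x0 - samples[samples < x0]
  c(b_minus = if (length(down)) unname(quantile(down, conf)) else 0,
    b_plus = if (length(up)) unname(quantile(up, conf)) else 0)
}

#' Bootstrap significance of a claim
#'
#' The probability `p0` that the opposite of a claim holds, estimated as
#' the fraction of bootstrap replicates whose sign contradicts the claim.
#' When no contradicting replicate is observed the true probability is of
#' the order of `1 / n` or lower; the returned value is then 0 with the
#' bound `1 / n` attached as attribute `upper_bound`.
#'
#' @param samples Bootstrapped values of the quantity the claim is about
#'   (e.g. a difference claimed to be positive).
#' @param claim `"positive"` or `"negative"`: the claimed sign of the
#'   quantity.
#' @return `p0`, with attributes `n` and `upper_bound`.
#' @export
p0_significance <- function(samples, claim = c("positive", "negative")) {
  claim <- match.arg(claim)
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n == 0L) stop_domain("no replicates")
  opposite <- if (claim == "positive") sum(samples < 0) else sum(samples > 0)
  structure(opposite / n, n = n, upper_bound = max(opposite, 1L) / n)
}
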