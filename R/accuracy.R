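#' Collective and individual accuracy
#'
#' Both are distances from the truth on the log scale, so 0 is best.
#' Collective accuracy is the absolute value of the median of all
#' log-deviations, `|median(X)|`: how far the group's median estimate is
#' from the truth.  Individual accuracy is the median of the absolute
#' log-deviations, `median(|X|)`: how far a typical individual estimate
#' is from the truth.
#'
#' @param X Non-empty numeric vector of log-deviations `log10(E / T)`.
#' @return A non-negative scalar.
#' @export
collective_accuracy <- function(X) {
  if (length(X) == 0L) stop_domain("X must be non-empty")
  abs(median(X))
}

#' @rdname collective_accuracy
#' @export
individual_accuracy <- function(X) {
  if (length(X) == 0L) stop_domain("X must be non-empty")
  median(abs(X))
}

#' Goodness of fit standardized by bootstrap error bars
#'
#' Mean of squared model-data residuals divided by the squared half-width
#' of the (possibly asymmetric) error bars, `C = (b_plus + b_minus) / 2`.
#' Analogous to a reduced chi-squared: values of order 1 mean the model
#' deviates from the data by about the data's own fluctuations.
#'
#' @param observed,model Equal-length numeric vectors.
#' @param err_up,err_down Upper and lower error-bar half-widths.
#' @return Non-negative scalar.
#' @export
goodness_of_fit <- function(observed, model, err_up, err_down) {
  stopifnot(length(observed) == length(model),
            length(observed) == length(err_up),
            length(observed) == length(err_down))
  C <- (err_up + err_down) / 2
  if (any(C <= 0)) stop_domain("error-bar half-widths must be positive")
  mean(((observed - model) / C)^2)
}

#' Mean relative error between model and data
#'
#' @param observed,model Equal-length numeric vectors; `model` non-zero.
#' @return `mean(|observed - model| / |model|)`.
#' @export
relative_error <- function(observed, model) {
  stopifnot(length(observed) == length(model))
  if (any(model == 0)) stop_domain("model values must be non-zero")
  mean(abs(observed - model) / abs(model))
}

#' Recalibrate personal log-estimates for the known bias
#'
#' The recalibration baseline divides each log estimate by the bias slope:
#' `log10(E') = log10(E) / gamma`, which in deviation coordinates
#' `X = log10(E / T)` reads `X' = (X + log10(T)) / gamma - log10(T)`.
#' With `gamma = 1` estimates are unchanged.  This external correction
#' removes the median bias but stretches the dispersion by `1 / gamma`,
#' and serves as the comparison baseline for the shifted-median treatment.
#'
#' @param X_p Personal log-deviations.
#' @param log_true `log10` of the true values (recycled).
#' @param gamma Positive bias slope.
#' @return Recalibrated log-deviations.
#' @export
recalibrate_estimates <- function(X_p, log_true, gamma) {
  if (!is.finite(gamma) || gamma <= 0) stop_domain("gamma must be positive")
  (X_p + log_true) / gamma - log_true
}

#' Accuracy of the recalibration baseline
#'
#' @param records Record table with `X_p` and `log_true`.
#' @param gamma Bias slope.
#' @return A one-row data frame with the collective and individual
#'   accuracies of the personal estimates before and after recalibration.
#' @export
recalibrate_baseline <- function(records, gamma = 0.9) {
  X_rec <- recalibrate_estimates(records$X_p, records$log_true, gamma)
  data.frame(collective_before = collective_accuracy(records$X_p),
             individual_before = individual_accuracy(records$X_p),
             collective_recal = collective_accuracy(X_rec),
             individual_recal = individual_accuracy(X_rec))
}

# per-condition accuracies, optionally within a subset mask
condition_accuracy_rows <- function(records, mask, subset_label) {
  conds <- unique(records[, c("treatment", "tau")])
  conds <- conds[order(conds$treatment, conds$tau), , drop = FALSE]
  rows <- lapply(seq_len(nrow(conds)), function(k) {
    sel <- mask & records$treatment == conds$treatment[k] &
      records$tau == conds$tau[k]
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(treatment = conds$treatment[k], tau = conds$tau[k],
                        subset = subset_label, n = 0L,
                        collective_before = NA_real_, collective_after = NA_real_,
                        individual_before = NA_real_, individual_after = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(treatment = conds$treatment[k], tau = conds$tau[k],
               subset = subset_label, n = n,
               collective_before = collective_accuracy(records$X_p[sel]),
               collective_after = collective_accuracy(records$X_s[sel]),
               individual_before = individual_accuracy(records$X_p[sel]),
               individual_after = individual_accuracy(records$X_s[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-condition accuracy table with subgroup splits
#'
#' Computes collective and individual accuracy before and after social
#' information sharing for every condition, over all records and within
#' the standard splits: by the sign of `D = M - X_p` and by whether a
#' record's sensitivity lies below or above the condition's median
#' sensitivity.  The sensitivity split uses clipped, defined S values
#' only; `below` means `S <= median(S)` of the condition.
#'
#' @param records Record table from [simulate_experiment()] or
#'   [read_records()].
#' @param filters Character subset of `"all"`, `"d_sign"`, `"s_split"`.
#' @param s_interval Clipping interval for the sensitivity split.
#' @return A data frame with one row per condition and subset.
#' @export
condition_accuracy <- function(records, filters = c("all", "d_sign", "s_split"),
                               s_interval = c(-1.05, 2.05)) {
  filters <- match.arg(filters, several.ok = TRUE)
  out <- list()
  if ("all" %in% filters)
    out$all <- condition_accuracy_rows(records, rep(TRUE, nrow(records)), "all")
  if ("d_sign" %in% filters) {
    out$dn <- condition_accuracy_rows(records, records$D < 0, "D<0")
    out$dp <- condition_accuracy_rows(records, records$D > 0, "D>0")
  }
  if ("s_split" %in% filters) {
    S <- compute_S(records$X_p, records$X_s, records$M)
    if (!is.null(records$kept)) S[records$kept] <- 0
    ok <- !is.na(S) & S >= s_interval[1] & S <= s_interval[2]
    cond <- interaction(records$treatment, records$tau, drop = TRUE)
    med <- stats::ave(ifelse(ok, S, NA), cond,
                      FUN = function(v) median(v, na.rm = TRUE))
    out$sb <- condition_accuracy_rows(records, ok & S <= med, "S below median")
    out$sa <- condition_accuracy_rows(records, ok & S > med, "S above median")
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Accuracy improvements with paired question-level bootstrap
#'
#' For each treatment, the improvement is the before-minus-after accuracy
#' averaged over the tau levels (the tau dependence is weak compared to
#' the sampling noise, so levels are weighted equally).  Every bootstrap
#' replicate draws one set of questions and recomputes all treatments,
#' measures, and before/after values on it, so improvements and
#' between-treatment differences are paired: their significance comes
#' from the per-replicate differences, never from overlapping bars.
#'
#' @param records Record table.
#' @param n_boot Bootstrap replicates.
#' @param conf Coverage of the asymmetric error bars.
#' @param seed Optional integer seed.
#' @return A list with `improvements` (per treatment and measure: value,
#'   asymmetric bars, `p0` that the improvement is negative) and
#'   `pairwise` (between-treatment differences in improvement with their
#'   `p0`), plus the replicate `samples` array.
#' @export
accuracy_improvements <- function(records, n_boot = 1000L, conf = 0.683,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  treatments <- sort(unique(records$treatment))
  qs <- sort(unique(records$question))
  nq <- length(qs)
  cond <- unique(records[, c("treatment", "tau")])
  cond <- cond[order(cond$treatment, cond$tau), , drop = FALSE]
  cond_key <- paste(cond$treatment, cond$tau)
  rec_key <- paste(records$treatment, records$tau)
  qfac <- factor(records$question, levels = qs)

  xp_lists <- xs_lists <- setNames(vector("list", nrow(cond)), cond_key)
  for (k in seq_len(nrow(cond))) {
    sel <- rec_key == cond_key[k]
    xp_lists[[k]] <- split(records$X_p[sel], qfac[sel])
    xs_lists[[k]] <- split(records$X_s[sel], qfac[sel])
  }

  measures <- c("collective", "individual")
  stat_all <- function(drawn) {
    impr <- matrix(NA_real_, length(treatments), length(measures),
                   dimnames = list(treatments, measures))
    for (tr in treatments) {
      ks <- which(cond$treatment == tr)
      ob <- oa <- ib <- ia <- numeric(length(ks))
      for (j in seq_along(ks)) {
        xp <- unlist(xp_lists[[ks[j]]][drawn], use.names = FALSE)
        xs <- unlist(xs_lists[[ks[j]]][drawn], use.names = FALSE)
        ob[j] <- abs(median(xp)); oa[j] <- abs(median(xs))
        ib[j] <- median(abs(xp)); ia[j] <- median(abs(xs))
      }
      impr[tr, "collective"] <- mean(ob) - mean(oa)
      impr[tr, "individual"] <- mean(ib) - mean(ia)
    }
    impr
  }

  x0 <- stat_all(seq_len(nq))
  samples <- array(NA_real_, c(n_boot, length(treatments), length(measures)),
                   dimnames = list(NULL, treatments, measures))
  for (b in seq_len(n_boot))
    samples[b, , ] <- stat_all(sample.int(nq, nq, replace = TRUE))

  impr_rows <- list()
  for (tr in treatments) for (ms in measures) {
    sm <- samples[, tr, ms]
    bars <- bootstrap_bars(sm, x0[tr, ms], conf)
    impr_rows[[paste(tr, ms)]] <- data.frame(
      treatment = tr, measure = ms, improvement = x0[tr, ms],
      b_minus = unname(bars["b_minus"]), b_plus = unname(bars["b_plus"]),
      p0 = as.numeric(p0_significance(sm, "positive")),
      stringsAsFactors = FALSE)
  }

  pair_rows <- list()
  if (length(treatments) > 1L) {
    pairs <- utils::combn(treatments, 2, simplify = FALSE)
    for (pr in pairs) for (ms in measures) {
      d <- samples[, pr[2], ms] - samples[, pr[1], ms]
      d0 <- x0[pr[2], ms] - x0[pr[1], ms]
      pair_rows[[paste(pr[2], pr[1], ms)]] <- data.frame(
        treatment_a = pr[2], treatment_b = pr[1], measure = ms,
        difference = d0,
        p0 = as.numeric(p0_significance(d, if (d0 >= 0) "positive" else "negative")),
        stringsAsFactors = FALSE)
    }
  }

  list(improvements = do.call(rbind, c(impr_rows, make.row.names = FALSE)),
       pairwise = do.call(rbind, c(pair_rows, make.row.names = FALSE)),
       samples = samples, n_boot = n_boot, conf = conf)
}

#' Full accuracy report
#'
#' Combines the per-condition accuracy table (with subgroup splits), the
#' tau-averaged improvements with paired bootstrap uncertainty, and the
#' recalibration baseline into one JSON-serializable report.
#'
#' @inheritParams condition_accuracy
#' @inheritParams accuracy_improvements
#' @param gamma Bias slope for the recalibration baseline.
#' @return A list with elements `conditions`, `improvements`, `pairwise`
#'   and `recalibration`.
#' @export
accuracy_report <- function(records, filters = c("all", "d_sign", "s_split"),
                            n_boot = 1000L, conf = 0.683, gamma = 0.9,
                            seed = NULL) {
  impr <- accuracy_improvements(records, n_boot = n_boot, conf = conf, seed = seed)
  list(conditions = condition_accuracy(records, filters = filters),
       improvements = impr$improvements,
       pairwise = impr$pairwise,
       recalibration = recalibrate_baseline(records, gamma = gamma))
}
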