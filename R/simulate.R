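#' Simulate the full estimation experiment
#'
#' Runs the agent-based model over a balanced design.  For every
#' (group, question) cell and every run, `group_size` personal
#' log-estimates are drawn from the question's truncated Laplace law, each
#' agent receives `tau` estimates selected by the cell's treatment,
#' sensitivities are drawn from the spike-and-Gaussian law and second
#' estimates computed with the update rule.  One revision round only.
#'
#' @param questions Question table from [generate_questions()].
#' @param design Cell table from [build_design()].
#' @param params An [influence_params()] object applied to all treatments,
#'   or a named list with one object per treatment.
#' @param gamma Bias slope used by the shifted-median selection.
#' @param group_size Number of agents per group.
#' @param n_runs Number of independent replications of the whole design.
#' @param seed Integer seed; all randomness in the simulation flows from
#'   it.
#' @param include_shared If `TRUE`, a `shared` column with the raw shared
#'   estimates (natural units, semicolon-separated) is added; costly for
#'   large `n_runs`.
#' @return A data frame with one row per (run, cell, subject) and columns
#'   `run`, `group`, `subject`, `question`, `treatment`, `tau`, `X_p`,
#'   `M`, `sigma`, `D`, `S`, `kept`, `X_s`, `E_p`, `E_s`, `log_true`
#'   (plus `shared` on request).  `kept` records the spike outcome, so
#'   `S == 0` identification does not rely on numeric coincidence.
#'   Attribute `guards` counts P_g clamps and `m_g`/`sigma_g` floor
#'   events over the whole simulation.
#' @export
simulate_experiment <- function(questions, design, params = default_influence_params(),
                                gamma = 0.9, group_size = 12L, n_runs = 1L,
                                seed = NULL, include_shared = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n_runs <- as.integer(n_runs)
  group_size <- as.integer(group_size)
  ncell <- nrow(design)
  n_per_run <- ncell * group_size
  if (any(design$tau >= group_size))
    stop_domain("every tau in the design must be smaller than group_size")

  qrow <- match(design$question, questions$question_id)
  if (anyNA(qrow)) stop_domain("design refers to questions absent from the table")
  # question centers live on the absolute log-estimate scale (m ~ gamma log T);
  # the simulation state X = log10(E/T) is centered at center - log_true
  centers <- questions$center[qrow] - questions$log_true[qrow]
  widths <- questions$width[qrow]
  log_true <- questions$log_true[qrow]
  trt_code <- match(design$treatment, c("random", "median", "shifted_median"))
  tau_v <- as.integer(design$tau)
  plist <- params_by_treatment(params, unique(design$treatment))

  M_all <- sig_all <- Xp_all <- S_all <- Xs_all <- numeric(n_per_run * n_runs)
  kept_all <- logical(n_per_run * n_runs)
  shared_all <- if (include_shared) character(n_per_run * n_runs) else NULL
  guards <- c(pg_clamped_low = 0L, pg_clamped_high = 0L,
              m_g_floored = 0L, sigma_g_floored = 0L)

  rec_log_true <- rep(log_true, each = group_size)
  rec_trt <- rep(design$treatment, each = group_size)
  rec_tau <- rep(tau_v, each = group_size)
  M_run <- sig_run <- numeric(n_per_run)
  shared_run <- if (include_shared) character(n_per_run) else NULL

  for (run in seq_len(n_runs)) {
    X <- matrix(rlaplace_trunc(n_per_run,
                               rep(centers, each = group_size),
                               rep(widths, each = group_size),
                               rep(-log_true, each = group_size)),
                nrow = group_size)
    for (ci in seq_len(ncell)) {
      x <- X[, ci]
      tv <- tau_v[ci]
      base <- (ci - 1L) * group_size
      if (trt_code[ci] == 1L) {
        for (i in seq_len(group_size)) {
          sel <- seq_len(group_size)[-i][sample.int(group_size - 1L, tv)]
          v <- x[sel]
          mm <- sum(v) / tv
          M_run[base + i] <- mm
          sig_run[base + i] <- sum(abs(v - mm)) / tv
          if (include_shared)
            shared_run[base + i] <- paste(10^(v + log_true[ci]), collapse = ";")
        }
      } else {
        ref <- median(x)
        if (trt_code[ci] == 3L)  # m' = m / gamma on the absolute log scale
          ref <- (ref + log_true[ci]) / gamma - log_true[ci]
        ord <- order(abs(x - ref), x, seq_len(group_size))
        top <- ord[seq_len(tv + 1L)]
        for (i in seq_len(group_size)) {
          sel <- top[top != i]
          if (length(sel) > tv) sel <- sel[seq_len(tv)]
          v <- x[sel]
          mm <- sum(v) / tv
          M_run[base + i] <- mm
          sig_run[base + i] <- sum(abs(v - mm)) / tv
          if (include_shared)
            shared_run[base + i] <- paste(10^(v + log_true[ci]), collapse = ";")
        }
      }
    }
    Xp_run <- as.vector(X)
    D_run <- M_run - Xp_run
    S_run <- numeric(n_per_run)
    kept_run <- logical(n_per_run)
    for (tr in names(plist)) {
      sel <- rec_trt == tr
      if (!any(sel)) next
      s <- draw_S(D_run[sel], sig_run[sel], rec_tau[sel], plist[[tr]])
      S_run[sel] <- as.numeric(s)
      kept_run[sel] <- attr(s, "kept")
      guards <- guards + attr(s, "guards")
    }
    Xs_run <- update_estimate(Xp_run, S_run, M_run, lower_bound = -rec_log_true)

    off <- (run - 1L) * n_per_run
    idx <- off + seq_len(n_per_run)
    Xp_all[idx] <- Xp_run; M_all[idx] <- M_run; sig_all[idx] <- sig_run
    S_all[idx] <- S_run; kept_all[idx] <- kept_run; Xs_all[idx] <- Xs_run
    if (include_shared) shared_all[idx] <- shared_run
  }

  out <- data.frame(
    run = rep(seq_len(n_runs), each = n_per_run),
    group = rep(rep(design$group, each = group_size), times = n_runs),
    subject = rep(rep(seq_len(group_size), times = ncell), times = n_runs),
    question = rep(rep(design$question, each = group_size), times = n_runs),
    treatment = rep(rec_trt, times = n_runs),
    tau = rep(rec_tau, times = n_runs),
    X_p = Xp_all, M = M_all, sigma = sig_all,
    D = M_all - Xp_all, S = S_all, kept = kept_all, X_s = Xs_all,
    E_p = 10^(Xp_all + rep(rec_log_true, times = n_runs)),
    E_s = 10^(Xs_all + rep(rec_log_true, times = n_runs)),
    log_true = rep(rec_log_true, times = n_runs),
    stringsAsFactors = FALSE
  )
  if (include_shared) out$shared <- shared_all
  attr(out, "guards") <- guards
  out
}
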