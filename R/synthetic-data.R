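#' Configuration of the synthetic experiment generator
#'
#' The generator emulates the structure of the estimation experiments the
#' package models: groups of subjects each answer a set of questions about
#' large quantities, and log10 estimates of a question follow a Laplace
#' distribution whose median underestimates the log truth by a factor
#' `gamma_bias` (the underestimation bias, slope of median log-estimate vs
#' log truth).
#'
#' @param n_questions Number of questions (36 in the emulated design).
#' @param n_groups Number of groups (18).
#' @param group_size Subjects per group (12).
#' @param gamma_bias Slope of the per-question log-estimate center on
#'   `log10` of the true value; values below 1 encode underestimation.
#' @param question_noise_sd Standard deviation of the Gaussian scatter of
#'   per-question centers around `gamma_bias * log_true`.
#' @param log_true_range Interval (length-2 numeric) from which `log10` of
#'   true values is drawn uniformly.  Must be positive so that all true
#'   values exceed 1.
#' @param width_range Interval from which per-question Laplace widths
#'   (mean absolute deviation of log-estimates) are drawn uniformly.
#' @param seed Optional integer seed used by [generate_questions()].
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_questions = 36L, n_groups = 18L, group_size = 12L,
                             gamma_bias = 0.9, question_noise_sd = 0.3,
                             log_true_range = c(2, 7), width_range = c(0.3, 0.6),
                             seed = NULL) {
  check_interval <- function(x, name, min_allowed = -Inf) {
    if (length(x) != 2L || !is.numeric(x) || anyNA(x))
      stop_domain(name, " must be a length-2 numeric interval")
    if (x[1] > x[2]) stop_domain(name, " is reversed: lower bound exceeds upper bound")
    if (x[1] < min_allowed) stop_domain(name, " must not go below ", min_allowed)
  }
  if (group_size < 2L) stop_domain("group_size must be at least 2")
  if (!is.finite(gamma_bias) || gamma_bias <= 0) stop_domain("gamma_bias must be positive")
  if (question_noise_sd < 0) stop_domain("question_noise_sd must be non-negative")
  check_interval(log_true_range, "log_true_range", min_allowed = 0)
  check_interval(width_range, "width_range", min_allowed = 0)
  structure(list(n_questions = as.integer(n_questions),
                 n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 gamma_bias = gamma_bias,
                 question_noise_sd = question_noise_sd,
                 log_true_range = as.numeric(log_true_range),
                 width_range = as.numeric(width_range),
                 seed = seed),
            class = "generator_config")
}

#' Generate a synthetic question table
#'
#' Each question carries a true value `T > 1`, the center and width of the
#' Laplace distribution of its log10 estimates, and descriptive tags.  The
#' center is `gamma_bias * log10(T)` plus Gaussian question-level noise, so
#' that a regression of centers on log truths recovers the generating bias
#' slope as the number of questions grows.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data frame with columns `question_id`, `true_value`,
#'   `log_true`, `center`, `width`, `category`, `magnitude`.
#' @export
generate_questions <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_questions
  log_true <- runif(n, config$log_true_range[1], config$log_true_range[2])
  center <- config$gamma_bias * log_true + rnorm(n, 0, config$question_noise_sd)
  width <- runif(n, config$width_range[1], config$width_range[2])
  data.frame(question_id = seq_len(n),
             true_value = 10^log_true,
             log_true = log_true,
             center = center,
             width = width,
             category = rep_len(c("knowledge", "numerosity"), n),
             magnitude = ifelse(log_true >= mean(config$log_true_range),
                                "very_large", "moderate"),
             stringsAsFactors = FALSE)
}

# Laplace CDF with location mu and scale b (mean absolute deviation = b).
plaplace <- function(q, mu = 0, b = 1) {
  ifelse(q < mu, 0.5 * exp((q - mu) / b), 1 - 0.5 * exp(-(q - mu) / b))
}

qlaplace <- function(p, mu = 0, b = 1) {
  ifelse(p <= 0.5, mu + b * log(2 * p), mu - b * log(2 * (1 - p)))
}

#' Sample from a lower-truncated Laplace distribution
#'
#' Exact inverse-CDF sampling of a Laplace distribution conditioned on
#' exceeding `lower`.  The scale is parameterized by `width`, the mean
#' absolute deviation from the median of the untruncated distribution
#' (which equals the Laplace scale parameter).  When the truncation point
#' lies at or above the center the conditional law is a shifted
#' exponential, which is sampled directly to avoid loss of precision in
#' the far tail.
#'
#' @param n Number of draws.
#' @param center,width,lower Location, width (>= 0) and lower truncation
#'   bound; recycled to length `n`.  `lower = -Inf` gives the untruncated
#'   Laplace.
#' @return Numeric vector of `n` draws, all strictly greater than `lower`.
#' @export
rlaplace_trunc <- function(n, center, width, lower = -Inf) {
  n <- as.integer(n)
  if (n < 0L) stop_domain("n must be non-negative")
  if (n == 0L) return(numeric(0))
  center <- rep_len(as.numeric(center), n)
  width <- rep_len(as.numeric(width), n)
  lower <- rep_len(as.numeric(lower), n)
  if (anyNA(width) || any(width < 0)) stop_domain("width must be non-negative")
  out <- numeric(n)

  degenerate <- width == 0
  if (any(degenerate)) {
    if (any(center[degenerate] <= lower[degenerate]))
      stop_domain("width = 0 requires center > lower bound")
    out[degenerate] <- center[degenerate]
  }

  tail <- !degenerate & lower >= center
  if (any(tail))  # P(X > lower + t | X > lower) = exp(-t / b) for lower >= center
    out[tail] <- lower[tail] + rexp(sum(tail)) * width[tail]

  body <- !degenerate & !tail
  if (any(body)) {
    p_low <- plaplace(lower[body], center[body], width[body])
    u <- p_low + runif(sum(body)) * (1 - p_low)
    out[body] <- qlaplace(u, center[body], width[body])
  }
  out
}

#' Sample personal log-estimates for one question
#'
#' Draws `n_subjects` values of `X_p = log10(E_p / T)` from the question's
#' truncated Laplace law.  The question's `center` is on the absolute
#' log-estimate scale (`m ~ gamma * log10(T)`), so the `X_p` law is
#' centered at `center - log_true`; the truncation bound `-log_true`
#' enforces that raw estimates `E_p = T * 10^X_p` always exceed 1.
#'
#' @param question One row of a [generate_questions()] table (data frame or
#'   list with `center`, `width`, `log_true`).
#' @param n_subjects Number of subjects.
#' @return Numeric vector of `n_subjects` log-estimates, all > `-log_true`.
#' @export
sample_personal_estimates <- function(question, n_subjects) {
  if (n_subjects < 1L) stop_domain("n_subjects must be at least 1")
  rlaplace_trunc(n_subjects, question$center - question$log_true,
                 question$width, lower = -question$log_true)
}

#' Build the balanced condition assignment
#'
#' Assigns a condition to every (group, question) cell with a deterministic
#' Latin-square rotation so that every group meets each condition exactly
#' twice, every question meets each condition in exactly one group, and
#' every question is asked in every group.  With 12 subjects per group this
#' yields `12 * 36 = 432` estimate records per condition.
#'
#' @param config A [generator_config()]; `n_questions` must equal twice the
#'   number of conditions and `n_groups` must equal the number of
#'   conditions.
#' @param conditions A condition table from [conditions_grid()].
#' @return A data frame with one row per (group, question) cell and columns
#'   `group`, `question`, `condition`, `treatment`, `tau`.
#' @export
build_design <- function(config, conditions = conditions_grid()) {
  stopifnot(inherits(config, "generator_config"))
  nc <- nrow(conditions)
  if (config$n_questions != 2L * nc)
    stop_domain("n_questions must equal twice the number of conditions (",
                2L * nc, "), got ", config$n_questions)
  if (config$n_groups != nc)
    stop_domain("n_groups must equal the number of conditions (", nc,
                "), got ", config$n_groups)
  if (any(conditions$tau >= config$group_size))
    stop_domain("every tau must be smaller than group_size")
  cells <- expand.grid(question = seq_len(config$n_questions),
                       group = seq_len(config$n_groups),
                       KEEP.OUT.ATTRS = FALSE)
  idx <- ((cells$group - 1L) + (cells$question - 1L)) %% nc + 1L
  out <- data.frame(group = cells$group,
                    question = cells$question,
                    condition = conditions$condition[idx],
                    treatment = conditions$treatment[idx],
                    tau = conditions$tau[idx],
                    stringsAsFactors = FALSE)
  out[order(out$group, out$question), , drop = FALSE]
}
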