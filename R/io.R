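#' Write a record table to CSV
#'
#' The on-disk schema stores raw estimates in natural units: columns
#' `run`, `group`, `subject`, `question`, `treatment`, `tau`, `E_p`,
#' `shared` (semicolon-separated raw shared estimates, as displayed to
#' subjects) and `E_s`.  Derived log-quantities are recomputed on read.
#'
#' @param records Record table from [simulate_experiment()] (simulated
#'   with `include_shared = TRUE`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("run", "group", "subject", "question", "treatment", "tau",
            "E_p", "shared", "E_s")
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop_domain("records lack column(s): ", paste(missing, collapse = ", "),
                if ("shared" %in% missing)
                  " (simulate with include_shared = TRUE)" else "")
  data.table::fwrite(records[, cols], path)
  invisible(path)
}

#' Read a record table and derive the log-scale quantities
#'
#' Reads the CSV schema of [write_records()] and derives, per record:
#' `X_p = log10(E_p / T)`, `X_s`, the mean `M` and dispersion `sigma` of
#' the shared log-estimates, `D = M - X_p`, and the sensitivity `S`
#' (exact zero where `E_s == E_p` by provenance, `NA` where `M == X_p`).
#'
#' @param path CSV path.
#' @param questions Question table supplying `log_true` per question id.
#' @return A record data frame with raw and derived columns.
#' @export
read_records <- function(path, questions) {
  raw <- as.data.frame(data.table::fread(path,
                                         colClasses = list(character = "shared")))
  need <- c("run", "group", "subject", "question", "treatment", "tau",
            "E_p", "shared", "E_s")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop_domain("record file lacks column(s): ", paste(missing, collapse = ", "))
  qrow <- match(raw$question, questions$question_id)
  if (anyNA(qrow)) {
    bad <- unique(raw$question[is.na(qrow)])
    stop_domain("question id(s) absent from the question table: ",
                paste(head(bad, 5), collapse = ", "))
  }
  if (any(raw$E_p <= 0) || any(raw$E_s <= 0))
    stop_domain("estimates must be positive; malformed row(s): ",
                paste(head(which(raw$E_p <= 0 | raw$E_s <= 0), 5), collapse = ", "))
  log_true <- questions$log_true[qrow]
  shared_logs <- lapply(strsplit(raw$shared, ";", fixed = TRUE), as.numeric)
  bad_tau <- which(lengths(shared_logs) != raw$tau)
  if (length(bad_tau))
    stop_domain("shared list length differs from tau at row(s): ",
                paste(head(bad_tau, 5), collapse = ", "))
  M_abs <- vapply(shared_logs, function(e) mean(log10(e)), numeric(1))
  sigma <- vapply(shared_logs, function(e) {
    l <- log10(e); mean(abs(l - mean(l)))
  }, numeric(1))
  out <- raw
  out$log_true <- log_true
  out$X_p <- log10(raw$E_p) - log_true
  out$X_s <- log10(raw$E_s) - log_true
  out$M <- M_abs - log_true
  out$sigma <- sigma
  out$D <- out$M - out$X_p
  out$kept <- raw$E_s == raw$E_p
  out$S <- compute_S(out$X_p, out$X_s, out$M)
  out$S[out$kept] <- 0
  out
}

#' Write and read question tables
#'
#' @param questions Question table from [generate_questions()].
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the question table (reader).
#' @export
write_questions <- function(questions, path) {
  data.table::fwrite(questions, path)
  invisible(path)
}

#' @rdname write_questions
#' @export
read_questions <- function(path) {
  q <- as.data.frame(data.table::fread(path))
  if (!"log_true" %in% names(q) && "true_value" %in% names(q))
    q$log_true <- log10(q$true_value)
  q
}

#' Read and write influence-model parameter files (YAML)
#'
#' @param params An [influence_params()] object or a named per-treatment
#'   list of them.
#' @param path YAML path.
#' @return `path` (writer, invisibly); an `influence_params` object or
#'   named list (reader).
#' @export
write_influence_params <- function(params, path) {
  strip <- function(p) list(tau1 = p$tau1, tau_gt1 = p$tau_gt1, variant = p$variant)
  obj <- if (inherits(params, "influence_params")) strip(params)
  else lapply(params, strip)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_influence_params
#' @export
read_influence_params <- function(path) {
  obj <- yaml::read_yaml(path)
  build <- function(o) influence_params(o$tau1, o$tau_gt1, o$variant %||% "full")
  if (!is.null(obj$tau1)) build(obj) else lapply(obj, build)
}

#' Run configuration
#'
#' Bundles everything one pipeline run needs: the generator settings, the
#' behavioral parameters, the bias slope, the number of runs and
#' bootstrap replicates, and the root seed all randomness flows from.
#'
#' @param generator A [generator_config()].
#' @param params An [influence_params()] object (or per-treatment list).
#' @param conditions Condition table from [conditions_grid()]; must be
#'   compatible with the generator counts (see [build_design()]).
#' @param gamma Bias slope for the shifted-median rule.
#' @param n_runs Simulation runs.
#' @param n_boot Bootstrap replicates for the accuracy report.
#' @param seed Root integer seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(generator = generator_config(),
                       params = default_influence_params(),
                       conditions = conditions_grid(),
                       gamma = 0.9, n_runs = 10L, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(generator, "generator_config"))
  structure(list(generator = generator, params = params,
                 conditions = conditions, gamma = gamma,
                 n_runs = as.integer(n_runs), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML path of a serialized run configuration.
#' @export
read_run_config <- function(path) {
  o <- yaml::read_yaml(path)
  gen <- do.call(generator_config, o$generator %||% list())
  par <- if (is.null(o$params)) default_influence_params()
  else if (!is.null(o$params$tau1))
    influence_params(o$params$tau1, o$params$tau_gt1, o$params$variant %||% "full")
  else lapply(o$params, function(p)
    influence_params(p$tau1, p$tau_gt1, p$variant %||% "full"))
  conds <- if (is.null(o$conditions)) conditions_grid()
  else conditions_grid(treatments = unique(o$conditions$treatment),
                       taus = unique(o$conditions$tau))
  run_config(generator = gen, params = par, conditions = conds,
             gamma = o$gamma %||% 0.9,
             n_runs = o$n_runs %||% 10L,
             n_boot = o$n_boot %||% 1000L,
             seed = o$seed %||% 1L)
}
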