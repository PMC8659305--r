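#' Run the full simulate - fit - report pipeline
#'
#' Executes the four analysis stages end to end: generate the synthetic
#' questions and design, simulate the experiment, recover the influence
#' parameters from the simulated records, and compute the accuracy
#' report.  Writes `records.csv`, `params_fit.yaml`, `report.json` and a
#' `manifest.json` with the seed, versions and guard counters.  The whole
#' run is deterministic given `config$seed` (stage seeds are derived from
#' it by fixed offsets).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the artifact paths and the in-memory
#'   stage results (`questions`, `design`, `records`, `fit`, `report`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  questions <- tryCatch(generate_questions(config$generator, seed = seed),
                        error = function(e) stop_domain("[generate] ", conditionMessage(e)))
  design <- tryCatch(build_design(config$generator, config$conditions),
                     error = function(e) stop_domain("[design] ", conditionMessage(e)))
  records <- tryCatch(
    simulate_experiment(questions, design, config$params, gamma = config$gamma,
                        group_size = config$generator$group_size,
                        n_runs = config$n_runs, seed = seed + 1L,
                        include_shared = TRUE),
    error = function(e) stop_domain("[simulate] ", conditionMessage(e)))
  fit <- tryCatch(fit_influence_params(records),
                  error = function(e) stop_domain("[fit] ", conditionMessage(e)))
  report <- tryCatch(
    accuracy_report(records, n_boot = config$n_boot, gamma = config$gamma,
                    seed = seed + 2L),
    error = function(e) stop_domain("[report] ", conditionMessage(e)))

  paths <- list(questions = file.path(out_dir, "questions.csv"),
                records = file.path(out_dir, "records.csv"),
                params_fit = file.path(out_dir, "params_fit.yaml"),
                report = file.path(out_dir, "report.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write_questions(questions, paths$questions)
  write_records(records, paths$records)
  if (length(fit$params)) write_influence_params(fit$params, paths$params_fit)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  manifest <- list(
    package = "crowdshift",
    version = as.character(packageVersion("crowdshift")),
    seed = seed, n_runs = config$n_runs, n_boot = config$n_boot,
    gamma = config$gamma,
    guards = as.list(attr(records, "guards")),
    s_undefined = fit$n_s_undefined,
    s_clip_removed_fraction = fit$clip_removed_fraction)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, questions = questions, design = design,
                 records = records, fit = fit, report = report))
}
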