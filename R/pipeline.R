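RUN_DEFAULTS <- list(
  seed = 1L, n_sessions = 4L, session_length = 600, sampling_rate = 10,
  device_range = 2.0, sessions_dir = NULL, epoch_seconds = c(1, 2),
  models = MODEL_NAMES, quick = FALSE, cv_folds = NULL, cv_repeats = NULL,
  train_fraction = 0.8, alpha = 0.05, merge_swim = "auto",
  energy_form = "magnitude", window = 5, stride = NULL,
  importance_model = "SVM", importance_repeats = 5, out_dir = "results")

#' Validate a run configuration
#'
#' Accepts a YAML file path or a named list, fills every documented default
#' and rejects unknown keys, bad types and missing paths with one
#' aggregated error. One master `seed` governs all stage seeds via
#' [derive_seed()].
#'
#' @param config YAML file path or named list. Keys: `seed`, generator
#'   settings (`n_sessions`, `session_length`, `sampling_rate`,
#'   `device_range`) or `sessions_dir` (manifest directory of pre-recorded
#'   CSV sessions), `epoch_seconds`, `models`, `quick`, `cv_folds`,
#'   `cv_repeats`, `train_fraction`, `alpha`, `merge_swim`
#'   (auto/always/never), `energy_form`, `window`, `stride`,
#'   `importance_model`, `importance_repeats`, `out_dir`.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  problems <- character(0)
  unknown <- setdiff(names(config), names(RUN_DEFAULTS))
  if (length(unknown))
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(RUN_DEFAULTS, config, keep.null = TRUE)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be one integer")
  chk(is.numeric(cfg$train_fraction) && cfg$train_fraction > 0 &&
        cfg$train_fraction < 1, "train_fraction must be in (0,1)")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0,1)")
  chk(all(cfg$models %in% MODEL_NAMES),
      sprintf("models must be among %s", paste(MODEL_NAMES, collapse = ",")))
  chk(cfg$merge_swim %in% c("auto", "always", "never"),
      "merge_swim must be auto, always or never")
  chk(cfg$energy_form %in% c("magnitude", "squared"),
      "energy_form must be magnitude or squared")
  chk(all(cfg$epoch_seconds > 0), "epoch_seconds must be positive")
  if (!is.null(cfg$sessions_dir))
    chk(file.exists(file.path(cfg$sessions_dir, "manifest.txt")),
        sprintf("no manifest.txt under sessions_dir '%s'", cfg$sessions_dir))
  if (length(problems))
    stopf("invalid configuration:\n  - %s",
          paste(problems, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full accelerometry-to-behaviour pipeline
#'
#' simulate (unless `sessions_dir` points at recorded sessions) -> derive
#' channels -> epoch features (per epoch length) -> swim-merge test ->
#' event split -> tune/fit all requested models -> evaluate -> report.
#' Everything is reproducible from `config$seed`; all tabular outputs are
#' written as CSV under `config$out_dir`.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return invisibly, a list: `feature_tables`, `merge_report`,
#'   `experiment` (see [run_experiment()]), `importance`, `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(cfg$sessions_dir)) {
    gen <- generator_config(sampling_rate = cfg$sampling_rate,
                            session_length = cfg$session_length,
                            device_range = cfg$device_range,
                            seed = derive_seed(cfg$seed, 20))
    sess_dir <- file.path(cfg$out_dir, "sessions")
    generate_dataset(cfg$n_sessions, gen, sess_dir)
  } else sess_dir <- cfg$sessions_dir
  sessions <- read_manifest(file.path(sess_dir, "manifest.txt"))

  tables <- list()
  for (ep in cfg$epoch_seconds) {
    tab <- build_feature_table(sessions, ep, window = cfg$window,
                               energy_form = cfg$energy_form,
                               stride = cfg$stride)
    mrep <- if (cfg$merge_swim == "auto")
      compare_swim_classes(tab, alpha = cfg$alpha) else cfg$merge_swim
    if (ep == cfg$epoch_seconds[1] && cfg$merge_swim == "auto") {
      merge_report <- mrep
      utils::write.csv(mrep$tests,
                       file.path(cfg$out_dir, "merge_report.csv"),
                       row.names = FALSE)
    }
    tab <- apply_ethogram(tab, mrep)
    tables[[as.character(ep)]] <- tab
    utils::write.csv(tab, file.path(cfg$out_dir,
                                    sprintf("features_%ss.csv", ep)),
                     row.names = FALSE)
  }
  if (cfg$merge_swim != "auto") merge_report <- cfg$merge_swim

  specs <- default_model_specs(cfg$models, cv_folds = cfg$cv_folds,
                               cv_repeats = cfg$cv_repeats,
                               seed = derive_seed(cfg$seed, 21),
                               quick = cfg$quick)
  exp <- run_experiment(tables, specs,
                        train_fraction = cfg$train_fraction,
                        seed = derive_seed(cfg$seed, 22))
  utils::write.csv(exp$comparison,
                   file.path(cfg$out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  for (key in names(exp$results)) {
    r <- exp$results[[key]]
    utils::write.csv(as.data.frame(unclass(r$confusion)),
                     file.path(cfg$out_dir,
                               sprintf("confusion_%s.csv", key)))
    utils::write.csv(r$metrics$per_class,
                     file.path(cfg$out_dir, sprintf("metrics_%s.csv", key)),
                     row.names = FALSE)
  }

  importance <- NULL
  imp_key <- sprintf("%s_%ss", cfg$importance_model,
                     cfg$epoch_seconds[length(cfg$epoch_seconds)])
  if (imp_key %in% names(exp$results)) {
    r <- exp$results[[imp_key]]
    ep <- as.character(r$epoch_s)
    test_tab <- tables[[ep]][tables[[ep]]$event_id %in% r$test_event_ids, ]
    importance <- permutation_importance(r$fit, test_tab,
                                         repeats = cfg$importance_repeats,
                                         seed = derive_seed(cfg$seed, 23))
    utils::write.csv(importance,
                     file.path(cfg$out_dir,
                               sprintf("importance_%s.csv", imp_key)),
                     row.names = FALSE)
  }

  log_lines <- c(
    sprintf("behavacc %s | R %s", utils::packageVersion("behavacc"),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("master seed: %d", cfg$seed),
    sprintf("sessions: %s", sess_dir),
    sprintf("epoch_seconds: %s", paste(cfg$epoch_seconds, collapse = ",")),
    sprintf("models: %s", paste(cfg$models, collapse = ",")),
    sprintf("quick grids: %s", cfg$quick),
    sprintf("merge decision: %s",
            if (is.character(merge_report)) merge_report
            else merge_report$decision))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(feature_tables = tables, merge_report = merge_report,
                 experiment = exp, importance = importance,
                 out_dir = cfg$out_dir))
}
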