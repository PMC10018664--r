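#' Experiment configuration
#'
#' Declarative description of a full run: which signals (simulated cohort or
#' files on disk), the chronological split, which architectures at which
#' configurations, seeds, and where to write results.
#'
#' @param architectures Architectures to run (subset of [architectures()]).
#' @param cohort NULL, or a list with `n_signals`, `mix` (named fractions),
#'   `duration_range_s`, `fs`, `seed` for [generate_cohort()].
#' @param signal_paths NULL, or character vector of signal files readable by
#'   [read_signal()]; all must exist at load time.
#' @param split A [split_spec()].
#' @param window `"recommended"` (each architecture's tuned window) or a
#'   [window_spec()] applied to every architecture.
#' @param epochs NULL (each architecture's tuned epoch count) or an integer
#'   override for desk-scale runs.
#' @param seeds Non-empty integer vector; every architecture x signal pair is
#'   trained once per seed.
#' @param output_dir Directory for the written report (created if needed);
#'   NULL keeps the run in memory.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(architectures = respredict::architectures(),
                              cohort = NULL, signal_paths = NULL,
                              split = split_spec(), window = "recommended",
                              epochs = NULL, seeds = 1L, output_dir = NULL) {
  if (!length(architectures) || !all(architectures %in% respredict::architectures()))
    stopf("`architectures` must be a non-empty subset of architectures()")
  if (is.null(cohort) && is.null(signal_paths))
    stopf("provide either `cohort` settings or `signal_paths`")
  if (!is.null(signal_paths)) {
    missing <- signal_paths[!file.exists(signal_paths)]
    if (length(missing))
      stopf("signal file(s) not found: %s", paste(missing, collapse = ", "))
  }
  if (!inherits(split, "split_spec")) stopf("`split` must be a split_spec")
  if (!identical(window, "recommended") && !inherits(window, "window_spec"))
    stopf("`window` must be \"recommended\" or a window_spec")
  if (!length(seeds)) stopf("`seeds` must be non-empty")
  structure(list(architectures = architectures, cohort = cohort,
                 signal_paths = signal_paths, split = split, window = window,
                 epochs = if (is.null(epochs)) NULL else as.integer(epochs),
                 seeds = as.integer(seeds), output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  y <- yaml::read_yaml(path)
  split <- if (is.null(y$split)) split_spec() else
    split_spec(y$split$train, y$split$val, y$split$test)
  window <- if (is.null(y$window) || identical(y$window, "recommended"))
    "recommended" else
    window_spec(y$window$input_len, y$window$output_len %||% 1L,
                y$window$horizon %||% 1L)
  cohort <- y$cohort
  if (!is.null(cohort) && !is.null(cohort$mix)) cohort$mix <- unlist(cohort$mix)
  experiment_config(
    architectures = y$architectures %||% architectures(),
    cohort = cohort, signal_paths = unlist(y$signal_paths),
    split = split, window = window, epochs = y$epochs,
    seeds = unlist(y$seeds) %||% 1L, output_dir = y$output_dir
  )
}

#' Write an experiment configuration as YAML
#' @param config An [experiment_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  cohort <- config$cohort
  if (!is.null(cohort$mix)) cohort$mix <- as.list(cohort$mix)  # keep names in YAML
  y <- list(
    architectures = config$architectures,
    cohort = cohort,
    signal_paths = config$signal_paths,
    split = list(train = config$split$train_frac, val = config$split$val_frac,
                 test = config$split$test_frac),
    window = if (identical(config$window, "recommended")) "recommended" else
      unclass(config$window),
    epochs = config$epochs,
    seeds = config$seeds,
    output_dir = config$output_dir
  )
  yaml::write_yaml(y[!vapply(y, is.null, TRUE)], path)
  invisible(path)
}

.load_signals <- function(config) {
  if (!is.null(config$signal_paths)) {
    lapply(config$signal_paths, read_signal)
  } else {
    co <- config$cohort
    generate_cohort(co$n_signals, co$mix,
                    duration_range_s = unlist(co$duration_range_s) %||% c(1380, 3600),
                    fs = co$fs %||% 26, seed = co$seed %||% 1L)
  }
}

# train + evaluate one (signal, architecture, seed) cell; metrics for the
# train and test segments, mirroring the two-block report layout.
.run_cell <- function(signal, architecture, config, seed) {
  rc <- recommended_config(architecture, seed = seed)
  spec <- rc$spec
  if (!identical(config$window, "recommended"))
    spec <- model_spec(architecture, spec$n_layers, spec$units_per_layer,
                       spec$hidden_activation, spec$output_activation,
                       spec$multistep, window = config$window)
  tc <- rc$config
  if (!is.null(config$epochs))
    tc <- train_config(tc$optimizer, tc$learning_rate, config$epochs,
                       tc$batch_size, tc$loss, seed)
  segs <- split_signal(signal, config$split)
  norm <- fit_normalizer(segs$train)
  sets <- lapply(segs, function(s) make_supervised(normalize(s, norm), spec$window))
  if (n_pairs(sets$train) == 0L) stopf("training segment too short for the window")
  if (n_pairs(sets$test) == 0L) stopf("test segment too short for the window")
  fit <- train_predictor(spec, sets$train,
                         if (n_pairs(sets$val) > 0L) sets$val else NULL, tc)
  if (fit$status != "ok") stopf("training diverged")
  train_rep <- evaluate_split(fit, sets$train, norm)
  test_rep <- evaluate_split(fit, sets$test, norm)
  list(fit = fit, norm = norm, train = train_rep, test = test_rep)
}

#' Run a full forecasting experiment
#'
#' simulate/load -> split -> normalize -> window -> train -> evaluate for
#' every architecture x signal x seed combination, with per-signal metric
#' rows, cohort mean +/- SD per architecture (train and test blocks), a
#' ranking by cohort mean test RMSE, and a provenance block (effective
#' configuration, seeds, config hash, timestamp). Deterministic given the
#' configuration and seeds, timestamps aside. A failing cell (e.g. a segment
#' too short for the window) is recorded under `failures` and the run
#' continues with the remaining cells.
#'
#' @param config An [experiment_config()].
#' @param verbose Print one line per completed cell.
#' @return An object of class `experiment_report` with `per_signal`
#'   (data.frame), `cohort` (data.frame), `ranking` (character),
#'   `failures` (data.frame), `provenance` (list).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (!inherits(config, "experiment_config")) stopf("`config` must be an experiment_config")
  signals <- .load_signals(config)
  rows <- list(); fails <- list()
  for (arch in config$architectures) {
    for (si in seq_along(signals)) {
      for (seed in config$seeds) {
        res <- tryCatch(.run_cell(signals[[si]], arch, config, seed),
                        error = function(e) e)
        if (inherits(res, "error")) {
          fails[[length(fails) + 1L]] <- data.frame(
            architecture = arch, signal_id = signals[[si]]$signal_id,
            seed = seed, error = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          architecture = arch, signal_id = signals[[si]]$signal_id, seed = seed,
          n_test = res$test$n,
          train_rmse_mm = res$train$rmse_mm, train_mae_mm = res$train$mae_mm,
          train_nrmse = res$train$nrmse,
          test_rmse_mm = res$test$rmse_mm, test_mae_mm = res$test$mae_mm,
          test_nrmse = res$test$nrmse,
          f_stat = res$test$f_stat, p_value = res$test$p_value)
        if (verbose)
          message(sprintf("%s | %s | seed %d: test RMSE %.4f mm",
                          arch, signals[[si]]$signal_id, seed,
                          res$test$rmse_mm))
      }
    }
  }
  per_signal <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(per_signal)) stopf("every experiment cell failed")

  cohort <- do.call(rbind, lapply(split(per_signal, per_signal$architecture),
    function(d) {
      sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
      data.frame(architecture = d$architecture[1], n_runs = nrow(d),
                 train_rmse_mean = mean(d$train_rmse_mm), train_rmse_sd = sd0(d$train_rmse_mm),
                 train_mae_mean = mean(d$train_mae_mm), train_mae_sd = sd0(d$train_mae_mm),
                 train_nrmse_mean = mean(d$train_nrmse),
                 test_rmse_mean = mean(d$test_rmse_mm), test_rmse_sd = sd0(d$test_rmse_mm),
                 test_mae_mean = mean(d$test_mae_mm), test_mae_sd = sd0(d$test_mae_mm),
                 test_nrmse_mean = mean(d$test_nrmse))
    }))
  cohort <- cohort[order(cohort$test_rmse_mean), ]
  rownames(cohort) <- NULL

  cfg_list <- unclass(config)
  cfg_list$split <- unclass(cfg_list$split)
  if (inherits(cfg_list$window, "window_spec")) cfg_list$window <- unclass(cfg_list$window)
  tmp <- tempfile(); yaml::write_yaml(cfg_list, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)

  report <- structure(list(
    per_signal = per_signal, cohort = cohort,
    ranking = cohort$architecture,
    failures = if (length(fails)) do.call(rbind, fails) else NULL,
    provenance = list(config = cfg_list, config_hash = cfg_hash,
                      seeds = config$seeds, timestamp = format(Sys.time()),
                      n_signals = length(signals))
  ), class = "experiment_report")

  if (!is.null(config$output_dir)) write_experiment_report(report, config$output_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d run(s), %d architecture(s); ranking by test RMSE:\n",
              nrow(x$per_signal), nrow(x$cohort)))
  for (i in seq_len(nrow(x$cohort)))
    cat(sprintf("  %d. %-13s test RMSE %.4f +/- %.4f mm (NRMSE %.4f)\n", i,
                x$cohort$architecture[i], x$cohort$test_rmse_mean[i],
                x$cohort$test_rmse_sd[i], x$cohort$test_nrmse_mean[i]))
  if (!is.null(x$failures))
    cat(sprintf("  %d failed cell(s)\n", nrow(x$failures)))
  invisible(x)
}

#' Write an experiment report to a directory
#'
#' Emits `per_signal.csv`, `cohort.csv` (the two-block mean +/- SD layout),
#' `failures.csv` (if any) and `provenance.yaml`.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_signal, file.path(dir, "per_signal.csv"), row.names = FALSE)
  utils::write.csv(report$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(report$failures))
    utils::write.csv(report$failures, file.path(dir, "failures.csv"), row.names = FALSE)
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
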