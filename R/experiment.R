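#' Configuration of the two scan-number experiments
#'
#' Bundles every tunable of the pipeline -- the stability design (samples,
#' settings, replicates), the calibration design, the generator's noise model,
#' the MDI window and offset unit, the SMDI grouping, the stability threshold
#' and the PLS component cap -- with the acquisition designs of the study as
#' defaults.  A config is plain data: it serializes to JSON and reloads to an
#' equal object, and `(config, seed)` fully determines every tabular output.
#'
#' @param n_samples_stability samples in the stability design
#' @param stability_settings scan settings of the stability design
#' @param replicates replicates per (sample, setting)
#' @param n_samples_calibration samples in the calibration design
#' @param calibration_settings scan settings of the calibration design
#' @param sigma0,gamma,drift_sd,session_sd,cold_start noise model, see
#'   [noise_model()]
#' @param window MDI window `c(lo, hi)` in cm^-1 or `NULL` for the full range
#' @param x_unit `"index"` or `"axis_value"` offsets for the moment distances
#' @param group_by SMDI standardization group key
#' @param threshold,sustained stability rule, see [recommend_min_scans()]
#' @param max_lv PLS component cap
#' @param seed master integer seed
#' @return list of class `experiment_config`
#' @export
experiment_config <- function(n_samples_stability = 12,
                              stability_settings = seq(10, 100, by = 10),
                              replicates = 5,
                              n_samples_calibration = 40,
                              calibration_settings = c(10, 20, 40, 60, 80),
                              sigma0 = 0.02, gamma = 0.5, drift_sd = 0.008,
                              session_sd = 0.022, cold_start = FALSE,
                              window = NULL, x_unit = "index",
                              group_by = "sample_id",
                              threshold = 0.05, sustained = TRUE,
                              max_lv = 10, seed = 1) {
  assert_that(length(stability_settings) >= 2,
              "stability needs >= 2 scan settings (no curve otherwise)",
              "scanstab_config_error")
  cfg <- list(n_samples_stability = as.integer(n_samples_stability),
              stability_settings = as.integer(stability_settings),
              replicates = as.integer(replicates),
              n_samples_calibration = as.integer(n_samples_calibration),
              calibration_settings = as.integer(calibration_settings),
              sigma0 = sigma0, gamma = gamma, drift_sd = drift_sd,
              session_sd = session_sd, cold_start = cold_start,
              window = if (is.null(window)) NULL else as.numeric(window),
              x_unit = x_unit, group_by = group_by,
              threshold = threshold, sustained = sustained,
              max_lv = as.integer(max_lv), seed = as.integer(seed))
  structure(cfg, class = "experiment_config")
}

#' Save / load an experiment config as JSON
#' @param config an [experiment_config()]
#' @param path JSON file path
#' @return `read_config` returns the reloaded `experiment_config`
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, raw)
}

config_noise <- function(config)
  noise_model(sigma0 = config$sigma0, gamma = config$gamma,
              drift_sd = config$drift_sd, session_sd = config$session_sd,
              cold_start = config$cold_start)

write_table_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_full)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the replicate-stability experiment
#'
#' Generates the stability dataset, computes SMDI for every acquisition, and
#' assembles the [stability_report()].  When `outdir` is given, writes
#' `smdi.csv`, `spreads.csv`, `stability_report.json`, the resolved
#' `config.json`, and (optionally) `funnel.png`; reruns with the same
#' `(config, seed)` reproduce the tabular outputs byte-identically.
#'
#' @param config an [experiment_config()]
#' @param outdir output directory, or `NULL` to skip writing
#' @param plots also write funnel plots (needs a PNG device)
#' @param quiet suppress progress messages
#' @return list with `smdi` (table) and `report` ([stability_report()])
#' @export
run_stability_experiment <- function(config = experiment_config(),
                                     outdir = NULL, plots = FALSE,
                                     quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("stability: generating %d x {%s} x %d acquisitions (seed %d)",
      config$n_samples_stability,
      paste(config$stability_settings, collapse = ","), config$replicates,
      config$seed)
  coll <- generate_stability_dataset(
    n_samples = config$n_samples_stability,
    settings = config$stability_settings,
    replicates = config$replicates,
    seed = config$seed, noise = config_noise(config))
  say("stability: computing SMDI")
  smdi <- batch_mdi(coll, window = config$window, x_unit = config$x_unit,
                    group_by = config$group_by)
  report <- stability_report(smdi, threshold = config$threshold,
                             sustained = config$sustained)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_smdi_table(smdi, file.path(outdir, "smdi.csv"))
    write_table_full(report$spreads, file.path(outdir, "spreads.csv"))
    rep_json <- list(pooled = report$pooled,
                     recommended_min_scans = report$recommended_min_scans,
                     threshold = report$threshold, sustained = report$sustained,
                     flags = report$flags)
    jsonlite::write_json(rep_json, file.path(outdir, "stability_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_config(config, file.path(outdir, "config.json"))
    if (plots) {
      grDevices::png(file.path(outdir, "funnel.png"), width = 1200, height = 900)
      plot(report, smdi = smdi)
      grDevices::dev.off()
    }
  }
  list(smdi = smdi, report = report)
}

#' Run the scan-number calibration experiment
#'
#' Generates the calibration dataset, builds a first-difference PLS1-LOOCV
#' calibration for each of the five soil properties at each scan setting, and
#' summarizes the metric trends versus scan number.  When `outdir` is given,
#' writes `metrics.csv`, `cv_predictions.csv`, `trends.csv` and `config.json`.
#'
#' @inheritParams run_stability_experiment
#' @return list with `metrics` (table from [evaluate_by_setting()]),
#'   `trends` ([trend_summary()]) and `properties` (the generated table)
#' @export
run_calibration_experiment <- function(config = experiment_config(),
                                       outdir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("calibration: generating %d samples x {%s} (seed %d)",
      config$n_samples_calibration,
      paste(config$calibration_settings, collapse = ","), config$seed)
  ds <- generate_calibration_dataset(
    n_samples = config$n_samples_calibration,
    settings = config$calibration_settings,
    seed = config$seed, noise = config_noise(config))
  say("calibration: fitting %d PLS-LOOCV cells",
      5 * length(config$calibration_settings))
  metrics <- evaluate_by_setting(ds$spectra, ds$properties,
                                 settings = config$calibration_settings,
                                 max_lv = config$max_lv)
  trends <- trend_summary(metrics)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_table_full(metrics, file.path(outdir, "metrics.csv"))
    write_table_full(attr(metrics, "cv_predictions"),
                     file.path(outdir, "cv_predictions.csv"))
    write_table_full(trends, file.path(outdir, "trends.csv"))
    write_config(config, file.path(outdir, "config.json"))
  }
  list(metrics = metrics, trends = trends, properties = ds$properties)
}

#' Reproduce the full synthetic scan-number study
#'
#' One call runs both experiments at the study designs -- the 12-sample
#' stability funnel over 10..100 scans and the 40-sample calibration at
#' \{10, 20, 40, 60, 80\} scans -- and writes a `summary.json` with the
#' conclusions: the recommended minimum scan number and the per-property
#' trend verdicts.
#'
#' @param seed master integer seed
#' @param outdir output directory (created if needed), or `NULL`
#' @param config an [experiment_config()]; its `seed` is overridden by `seed`
#' @param plots forwarded to [run_stability_experiment()]
#' @param quiet suppress progress messages
#' @return list with `stability`, `calibration`, and `summary` (list with
#'   `recommended_min_scans`, `trends`, `n_properties_improving`)
#' @export
replicate_all <- function(seed = 1, outdir = NULL,
                          config = experiment_config(), plots = FALSE,
                          quiet = TRUE) {
  config$seed <- as.integer(seed)
  stab <- run_stability_experiment(config,
                                   outdir = if (is.null(outdir)) NULL
                                            else file.path(outdir, "stability"),
                                   plots = plots, quiet = quiet)
  calib <- run_calibration_experiment(config,
                                      outdir = if (is.null(outdir)) NULL
                                               else file.path(outdir, "calibration"),
                                      quiet = quiet)
  summ <- list(
    recommended_min_scans = stab$report$recommended_min_scans,
    threshold = config$threshold,
    pooled_spread = stab$report$pooled,
    trends = calib$trends,
    n_properties_improving =
      sum(calib$trends$r2_improves & calib$trends$rmsecv_shrinks),
    seed = config$seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(stability = stab, calibration = calib, summary = summ)
}
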