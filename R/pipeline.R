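#' Default end-to-end run configuration
#'
#' Encodes the reference defaults: the full simulation design (see
#' [simConfig()]), kernel-3 median smoothing, the 60-minute gap rule, 20:00
#' day windows, a 5 x 5 output lattice, 3000 training iterations, Sakoe-Chiba
#' band 60, and all three training variants for side-by-side quantization
#' errors.
#'
#' @return nested named list consumable by [runPipeline()].
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    simulate = list(n_sites = 7L, n_days = 30L, day_length = 1440L,
                    variables = c("outdoor_temperature", "indoor_temperature",
                                  "outdoor_pm", "indoor_pm"),
                    warp_magnitude = 30, noise_sd = 0.5, spike_rate = 2,
                    spike_time_jitter_sd = 30, missing_gap_rate = 0.2,
                    outcome_logit_coefs = c(-0.5, 0.8, 0.5),
                    start_date = "2017-04-01"),
    preprocess = list(kernel = 3L, max_gap = 60L, window_start = "20:00",
                      scale_temperature = FALSE),
    train = list(variants = c("euclidean", "dtw_match", "dtw_full"),
                 rows = 5L, cols = 5L, iterations = 3000L,
                 epsilon = c(0.5, 0.01), band = 60, init = "sample",
                 kernel_cutoff = 1e-3, qe_every = 10L,
                 variable = "temperature", location = "outdoor"),
    evaluate = list(labels = "season")
  )
}

#' Validate a run configuration
#'
#' Field-by-field structural check of a (possibly partial) run configuration;
#' unknown fields and type mismatches are rejected with the offending name.
#' Missing fields fall back to [defaultRunConfig()].
#'
#' @param config nested named list (e.g. parsed from YAML).
#' @return the completed configuration, invisibly usable by [runPipeline()].
#' @export
validateRunConfig <- function(config) {
  def <- defaultRunConfig()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(def)) {
    if (is.null(config[[sec]])) { config[[sec]] <- def[[sec]]; next }
    if (sec == "seed") next
    extra <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(extra))
      stop("unknown field(s) in '", sec, "': ", paste(extra, collapse = ", "))
    for (f in names(def[[sec]]))
      if (is.null(config[[sec]][[f]])) config[[sec]][[f]] <- def[[sec]][[f]]
  }
  num_fields <- list(simulate = c("n_sites", "n_days", "day_length",
                                  "warp_magnitude", "noise_sd", "spike_rate",
                                  "spike_time_jitter_sd", "missing_gap_rate",
                                  "outcome_logit_coefs"),
                     preprocess = c("kernel", "max_gap"),
                     train = c("rows", "cols", "iterations", "epsilon", "band",
                               "kernel_cutoff", "qe_every"))
  for (sec in names(num_fields)) for (f in num_fields[[sec]])
    if (!is.numeric(config[[sec]][[f]]))
      stop("config field '", sec, ".", f, "' must be numeric")
  if (!all(config$train$variants %in% c("euclidean", "dtw_match", "dtw_full")))
    stop("config field 'train.variants' must be a subset of euclidean, dtw_match, dtw_full")
  config
}

#' Read and write long-format sensor records as CSV
#'
#' Timestamps are written in ISO-8601 (`2017-04-01T20:00:00Z`, UTC) and parsed
#' back with an explicit format. Plain `write.csv` of a POSIXct column drops
#' the time part of exact-midnight instants, after which whole-column parsing
#' silently degrades to date resolution — these helpers exist to make the
#' round trip lossless.
#'
#' @param records data.frame with a POSIXct `timestamp` column (plus `site`,
#'   `location`, `variable`, `sensor`, `value`).
#' @param path CSV file path.
#' @return `readRecordsCsv` returns the records data.frame with a POSIXct
#'   (UTC) `timestamp`; `writeRecordsCsv` returns `path` invisibly.
#' @export
writeRecordsCsv <- function(records, path) {
  records$timestamp <- format(records$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecordsCsv
#' @export
readRecordsCsv <- function(path) {
  records <- read.csv(path)
  ts <- as.POSIXct(records$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts) && !anyNA(records$timestamp))
    stop("could not parse all timestamps in ", path)
  records$timestamp <- ts
  records
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

#' Run the full pipeline: simulate, preprocess, train, evaluate
#'
#' Executes the stages in order into `out_dir`, writing `raw.csv`,
#' `truth.csv`, `outcomes.csv`, `days.csv` (wide: metadata + one column per
#' minute) plus `days_index.csv`, one `grid_<variant>.csv` /
#' `assignment_<variant>.csv` pair per requested variant, a
#' `qe_comparison.csv` table of quantization errors across variants,
#' `metrics.json`, and a `manifest.json` recording the configuration hash,
#' seed, package version and per-stage status. Reruns with the same
#' configuration reproduce identical numeric artifacts; on a stage failure the
#' manifest names the failed stage before the error is re-signalled.
#'
#' @param config nested list as from [defaultRunConfig()], or a path to a YAML
#'   file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding `config$seed`; propagated to every
#'   stage.
#' @param records optional precomputed long-format records (skips the
#'   simulation stage); `outcomes` may accompany it.
#' @param outcomes optional outcomes table used with `records`.
#' @return invisibly, a list with the manifest and in-memory stage results.
#' @export
runPipeline <- function(config = defaultRunConfig(), out_dir, seed = NULL,
                        records = NULL, outcomes = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- validateRunConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  manifest <- list(config_hash = unname(tools::md5sum(config_path)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("dtwsom")),
                   stages = list())
  fail <- function(stage, err) {
    manifest$stages[[stage]] <- paste("failed:", conditionMessage(err))
    .write_json(manifest, file.path(out_dir, "manifest.json"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  # --- simulate -------------------------------------------------------------
  truth <- NULL
  if (is.null(records)) {
    sim <- tryCatch({
      sc <- do.call(simConfig, c(config$simulate, list(seed = config$seed)))
      simulateExposure(sc)
    }, error = function(e) fail("simulate", e))
    records <- sim$records; truth <- sim$truth
    if (is.null(outcomes)) outcomes <- sim$outcomes
    writeRecordsCsv(records, file.path(out_dir, "raw.csv"))
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    write.csv(outcomes, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
    manifest$stages$simulate <- "ok"
  } else {
    manifest$stages$simulate <- "skipped (records supplied)"
    if (is.null(outcomes))
      message("no outcomes supplied: outcome overlays will be skipped")
  }

  # --- preprocess -----------------------------------------------------------
  days <- tryCatch({
    pp <- config$preprocess
    preprocessExposures(records, outcomes = outcomes, kernel = pp$kernel,
                        max_gap = pp$max_gap, window_start = pp$window_start,
                        scale_temperature = pp$scale_temperature)
  }, error = function(e) fail("preprocess", e))
  info <- dayInfo(days)
  write.csv(cbind(info, t(daySeries(days))),
            file.path(out_dir, "days.csv"), row.names = FALSE)
  write.csv(info, file.path(out_dir, "days_index.csv"), row.names = FALSE)
  manifest$stages$preprocess <- sprintf("ok (%d complete days)", ncol(days))

  # --- train + evaluate -----------------------------------------------------
  tr <- config$train
  keep <- info$variable == tr$variable & info$location == tr$location
  if (!any(keep)) fail("train", simpleError(sprintf(
    "no complete days for %s %s", tr$location, tr$variable)))
  X <- daySeries(days)[, keep, drop = FALSE]
  sub_info <- info[keep, ]

  fits <- list(); qcomp <- NULL; metrics <- list()
  for (v in tr$variants) {
    fit <- tryCatch({
      cfgv <- trainConfig(variant = v, iterations = tr$iterations,
                          epsilon = tr$epsilon, band = tr$band,
                          init = tr$init, seed = config$seed,
                          kernel_cutoff = tr$kernel_cutoff,
                          qe_every = tr$qe_every)
      trainSom(X, tr$rows, tr$cols, cfgv)
    }, error = function(e) fail(paste0("train:", v), e))
    fits[[v]] <- fit
    pos <- neuronPositions(fit@grid)
    write.csv(cbind(data.frame(row = pos[, 1], col = pos[, 2]),
                    somWeights(fit@grid)),
              file.path(out_dir, paste0("grid_", v, ".csv")), row.names = FALSE)
    write.csv(assignmentTable(fit),
              file.path(out_dir, paste0("assignment_", v, ".csv")),
              row.names = FALSE)
    rep_v <- tryCatch(
      metricsReport(fit, X, labels = sub_info[[config$evaluate$labels]],
                    outcomes = if (!is.null(outcomes)) sub_info$outcome),
      error = function(e) fail(paste0("evaluate:", v), e))
    metrics[[v]] <- rep_v[c("quantization_error", "neighbor_distance",
                            "entropy_weighted", "entropy_joint")]
    write.csv(rep_v$per_neuron,
              file.path(out_dir, paste0("per_neuron_", v, ".csv")),
              row.names = FALSE)
    qcomp <- rbind(qcomp, data.frame(variant = v,
                                     quantization_error = rep_v$quantization_error))
    manifest$stages[[paste0("train:", v)]] <- "ok"
  }
  write.csv(qcomp, file.path(out_dir, "qe_comparison.csv"), row.names = FALSE)
  .write_json(metrics, file.path(out_dir, "metrics.json"))
  manifest$stages$evaluate <- "ok"
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(manifest = manifest, days = days, fits = fits,
                 metrics = metrics, qe_comparison = qcomp))
}
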