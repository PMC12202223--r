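# Plain-text I/O: delimited ECG records with a JSON metadata sidecar,
# activation-time tables, beat annotations, results tables, and the YAML
# analysis/scenario configuration.

#' Write an ECG record as delimited text
#'
#' Writes `time_s` plus one column per lead (mV) as CSV, and a JSON sidecar
#' (`<path>.meta.json`) holding the sampling rate and phase timeline.
#'
#' @param record an [ECGRecord-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeEcgText <- function(record, path) {
  stopifnot(is(record, "ECGRecord"))
  df <- data.frame(time_s = (seq_len(nrow(record@samples)) - 1L) / record@fs,
                   record@samples, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = record@fs, leads = colnames(record@samples),
               phases = record@phases)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a delimited-text ECG record
#'
#' Expects a `time_s` column plus one column per lead; the sampling rate and
#' phase timeline come from the JSON sidecar when present, otherwise the rate
#' is inferred from the time column.
#'
#' @param path CSV path (sidecar `<path>.meta.json` is read when it exists).
#' @return an [ECGRecord-class].
#' @export
readEcgText <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing time_s column in ", path)
  metaPath <- paste0(path, ".meta.json")
  phases <- NULL
  if (file.exists(metaPath)) {
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    fs <- meta$fs
    if (!is.null(meta$phases) && length(meta$phases))
      phases <- as.data.frame(meta$phases)
  } else {
    fs <- 1 / stats::median(diff(df$time_s))
    fs <- round(fs)
  }
  m <- as.matrix(df[setdiff(names(df), "time_s")])
  ECGRecord(m, fs, phases)
}

#' Write beat annotations as CSV
#'
#' One row per beat: `sample_index` and `label` (N = normal, V = ectopic).
#'
#' @param beats a [BeatSet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeBeatAnnotations <- function(beats, path) {
  stopifnot(is(beats, "BeatSet"))
  utils::write.csv(data.frame(sample_index = beats@rPeaks,
                              label = ifelse(beats@ectopic, "V", "N")),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an activation-time table
#'
#' Delimited text with columns `point_id` and `activation_time_s`, one row
#' per activation.
#'
#' @param path CSV path.
#' @return an [ActivationSet-class].
#' @export
readActivationText <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("point_id", "activation_time_s") %in% names(df)))
    stop("need columns point_id, activation_time_s in ", path)
  if (!nrow(df)) stop("empty activation file: ", path)
  sp <- split(df$activation_time_s, df$point_id)
  sp <- lapply(sp, sort)
  ActivationSet(unname(sp), ids = names(sp))
}

#' Write an activation-time table
#'
#' @param set an [ActivationSet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeActivationText <- function(set, path) {
  stopifnot(is(set, "ActivationSet"))
  df <- do.call(rbind, lapply(seq_along(set@times), function(i)
    data.frame(point_id = set@ids[i], activation_time_s = set@times[[i]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' Every threshold of the analysis pipeline with its default: the S quality
#' gate (0.3) and 10% recording rule, ectopic classification thresholds,
#' the piCA scan band, the quarter-period delay rule, the peak-condition
#' threshold, the comparison graph and alpha, and the harmonic-search
#' numerical parameters. Round-trips losslessly through YAML.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `analysisConfig`.
#' @export
defaultAnalysisConfig <- function(...) {
  cfg <- list(
    analysisLead = "V1",
    detectionLead = NULL,          # NULL = auto (largest QRS energy)
    corrThreshold = 0.9,
    rrTol = 0.4,
    beatWindow = c(-0.25, 0.45),
    sThreshold = 0.3,
    recordingBadFraction = 0.1,
    minValidFraction = 0.5,
    anchorBand = c(4, 12),
    gridStep = 0.01,
    goldenTol = 1e-4,
    respBand = c(0.08, 0.5),
    qDelays = 2L,               # NA = quarter respiratory period

    maxGapSeconds = 5,
    minRunSeconds = 60,
    peakFraction = 0.25,
    peakHalfBand = 0.05,
    simRespRate = 0.14,
    activationWindowSeconds = 10,  # final-window restriction; NULL = full
    alpha = 0.05,
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  for (nm in names(over)) cfg[nm] <- list(over[[nm]])  # NULL-safe
  structure(cfg, class = "analysisConfig")
}

#' Write / read the analysis configuration (YAML)
#'
#' @param config an `analysisConfig` list.
#' @param path YAML file path.
#' @return `writeAnalysisConfig`: the path, invisibly;
#'   `readAnalysisConfig`: the configuration.
#' @export
writeAnalysisConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeAnalysisConfig
#' @export
readAnalysisConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(defaultAnalysisConfig, raw)
}

#' Write a results table with provenance
#'
#' CSV with snake_case columns (units in a leading comment line) plus a JSON
#' sidecar holding the configuration and package version.
#'
#' @param table results data.frame.
#' @param path output CSV path.
#' @param config optional `analysisConfig` recorded in the sidecar.
#' @return the path, invisibly.
#' @export
writeResultsTable <- function(table, path, config = NULL) {
  con <- file(path, "w")
  writeLines(paste0("# ff_hz: Hz; fhr_bpm: bpm; frr_hz: Hz; ",
                    "delta_ff_hz: Hz; pr_pct: percent"), con)
  utils::write.csv(table, con, row.names = FALSE)
  close(con)
  meta <- list(package = "fwavetilt",
               version = as.character(utils::packageVersion("fwavetilt")))
  if (!is.null(config)) meta$config <- unclass(config)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a results table written by [writeResultsTable()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readResultsTable <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
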