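# Readers and writers binding the pipeline stages together. CSV is the
# canonical interchange (RFC-4180, UTF-8, '.' decimal); every writer drops a
# JSON sidecar naming the generating stage and parameters for provenance.

write_sidecar <- function(path, stage, params = list()) {
  side <- paste0(path, ".meta.json")
  jsonlite::write_json(list(stage = stage, package = "eegflow",
                            params = params),
                       side, auto_unbox = TRUE, null = "null")
  invisible(side)
}

#' Read a per-player gameplay metrics CSV
#'
#' Expects columns `level`, `TC`, `TM`, `OH`.
#'
#' @param path CSV path.
#' @return Data frame ready for [calibrate_levels()].
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("level", "TC", "TM", "OH")
  if (!all(need %in% names(df)))
    stop_input(sprintf("metrics file '%s' must have columns %s", path,
                       paste(need, collapse = ", ")))
  df[need]
}

#' Write a calibration table CSV
#'
#' Mirrors the worked-example datasheet columns (level, raw and normalised
#' metrics, PI, %PI') plus the three assigned session levels.
#'
#' @param calib a [calibrate_levels()] result.
#' @param path output CSV path.
#' @export
write_calibration_csv <- function(calib, path) {
  tab <- as.data.frame(calib$table)
  tab$easy_level <- calib$easy_level
  tab$optimal_level <- calib$optimal_level
  tab$hard_level <- calib$hard_level
  utils::write.csv(tab, path, row.names = FALSE)
  write_sidecar(path, "calibrate",
                list(weights_mode = calib$weights$rounding_mode,
                     capped = calib$capped))
  invisible(path)
}

#' Read flow-scale responses from CSV
#'
#' Expects columns `subject_id`, `session`, `item_1` .. `item_14`.
#'
#' @param path CSV path.
#' @return List of [flow_response()] objects.
#' @export
read_responses_csv <- function(path) {
  df <- utils::read.csv(path)
  items <- paste0("item_", 1:14)
  if (!all(c("subject_id", "session", items) %in% names(df)))
    stop_input("responses file must have subject_id, session, item_1..item_14")
  lapply(seq_len(nrow(df)), function(i)
    flow_response(as.integer(df[i, items]), df$subject_id[i], df$session[i]))
}

#' Write flow responses / labels CSVs
#'
#' @param responses list of [flow_response()]s.
#' @param path output CSV path.
#' @export
write_responses_csv <- function(responses, path) {
  rows <- lapply(responses, function(r) {
    v <- as.list(stats::setNames(r$items, paste0("item_", 1:14)))
    c(list(subject_id = r$subject_id, session = r$session), v)
  })
  utils::write.csv(dplyr::bind_rows(lapply(rows, tibble::as_tibble)), path,
                   row.names = FALSE)
  write_sidecar(path, "responses")
  invisible(path)
}

#' @rdname write_responses_csv
#' @param labels tibble from [label_sessions()].
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE)
  write_sidecar(path, "label")
  invisible(path)
}

#' Read / write an EEG recording as CSV
#'
#' Layout: rows = samples, columns = channels, header row of channel names.
#'
#' @param rec an [eeg_recording()].
#' @param path CSV path.
#' @export
write_recording_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, "recording",
                list(fs = rec$fs, subject_id = rec$subject_id,
                     session = rec$session))
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs sampling rate, Hz.
#' @param subject_id,session provenance keys.
#' @export
read_recording_csv <- function(path, fs = 128, subject_id = "s01",
                               session = "optimal") {
  df <- utils::read.csv(path, check.names = FALSE)
  eeg_recording(t(as.matrix(df)), channel_names = names(df), fs = fs,
                subject_id = subject_id, session = session)
}

#' Write a feature table CSV with its metadata sidecar
#'
#' @param features a [build_feature_table()] result.
#' @param path output CSV path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  b <- attr(features, "bands")
  write_sidecar(path, "features",
                list(feature_cols = feature_cols(features),
                     nw = attr(features, "nw"),
                     bands = if (!is.null(b)) unclass(b) else NULL,
                     n_excluded_neutral = attr(features, "n_excluded_neutral")))
  invisible(path)
}

#' Write an SQI report CSV shaped like the study's quality table
#'
#' @param report an [sqi_report()] result.
#' @param path output CSV path.
#' @export
write_sqi_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report$table), path, row.names = FALSE)
  write_sidecar(path, "sqi")
  invisible(path)
}
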