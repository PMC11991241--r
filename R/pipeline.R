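# End-to-end pipeline driver: simulate (or ingest) -> calibrate -> label ->
# preprocess -> features -> SQI -> statistics -> classification, with stage
# toggles and a fully serialised run configuration for provenance.

#' Run configuration
#'
#' Validated bundle of every pipeline parameter. Unknown keys are rejected.
#'
#' @param out_dir output directory for run artifacts (created if missing).
#' @param sim a [simulation_config()] describing the synthetic cohort.
#' @param ica ICA muscle-artifact stage: `"none"` or `"ica-infomax"`.
#' @param sqi,stats,ml logical stage toggles.
#' @param weights_mode Performance Index weight rounding mode.
#' @param neutral_band flow-scale neutral band (`c(lo, hi)` or NULL).
#' @param bands a [band_definition()].
#' @param nw multitaper time-bandwidth product.
#' @param feature_set,channel_mode passed to [build_feature_table()].
#' @param model a [model_spec()] (applied in both evaluation modes).
#' @param scheme_within,scheme_cross [cv_scheme()]s for the two designs.
#' @param seed master seed for the evaluation schemes.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("eegflow_run_"),
                       sim = simulation_config(),
                       ica = c("none", "ica-infomax"),
                       sqi = TRUE, stats = TRUE, ml = TRUE,
                       weights_mode = "paper-rounded-4dp",
                       neutral_band = c(3.75, 4.25),
                       bands = band_definition(), nw = 2,
                       feature_set = "combined",
                       channel_mode = "per-channel",
                       model = model_spec("svm"),
                       scheme_within = NULL, scheme_cross = NULL,
                       seed = 1L) {
  ica <- match.arg(ica)
  cfg <- list(out_dir = out_dir, sim = sim, ica = ica, sqi = sqi,
              stats = stats, ml = ml, weights_mode = weights_mode,
              neutral_band = neutral_band, bands = bands, nw = nw,
              feature_set = feature_set, channel_mode = channel_mode,
              model = model,
              scheme_within = scheme_within %||%
                cv_scheme("within-subject", tuning_folds = 5, seed = seed),
              scheme_cross = scheme_cross %||%
                cv_scheme("cross-subject", tuning_folds = 5, seed = seed),
              seed = as.integer(seed))
  assert_that(inherits(cfg$sim, "simulation_config"), "sim must be a simulation_config")
  assert_that(inherits(cfg$bands, "band_definition"), "bands must be a band_definition")
  assert_that(inherits(cfg$model, "model_spec"), "model must be a model_spec")
  structure(cfg, class = "run_config")
}

serializable <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) return(lapply(unclass(x), serializable))
  x
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> calibrate -> label -> filter (-> ICA) -> epoch ->
#' features -> SQI -> group statistics -> classification, writing every
#' artifact (CSV + JSON sidecars) under `cfg$out_dir`. Stages toggled off are
#' skipped; a stage failure propagates with partial outputs retained.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory artifacts: `cohort`,
#'   `calibrations`, `labels`, `features`, `sqi`, `stats`, `ml`, `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  assert_that(inherits(cfg, "run_config"), "cfg must be a run_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(serializable(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)

  cohort <- simulate_cohort(cfg$sim)
  w <- weight_scheme(rounding_mode = cfg$weights_mode)
  calibs <- lapply(cohort$metrics, calibrate_levels, w = w)
  for (sid in names(calibs))
    write_calibration_csv(calibs[[sid]],
                          file.path(cfg$out_dir, sprintf("calibration_%s.csv", sid)))

  labels <- label_sessions(cohort$responses, neutral_band = cfg$neutral_band)
  write_labels_csv(labels, file.path(cfg$out_dir, "labels.csv"))

  retained <- labels[labels$retained & labels$label != "neutral", ]
  epoch_list <- lapply(seq_len(nrow(retained)), function(i) {
    key <- paste(retained$subject_id[i], retained$session[i], sep = "/")
    rec <- bandpass_filter(cohort$recordings[[key]])
    if (cfg$ica != "none")
      rec <- remove_artifact_components(rec, method = cfg$ica)
    epoch_recording(rec, label = retained$label[i])
  })
  features <- build_feature_table(epoch_list, bands = cfg$bands,
                                  feature_set = cfg$feature_set,
                                  channel_mode = cfg$channel_mode, nw = cfg$nw)
  features <- dplyr::left_join(features, cohort$subjects, by = "subject_id")
  attr(features, "feature_cols") <- setdiff(
    names(features), c("subject_id", "session", "label", "epoch", "age_group"))
  write_features_csv(features, file.path(cfg$out_dir, "features.csv"))

  sqi <- NULL
  if (isTRUE(cfg$sqi)) {
    per_subject <- split(cohort$recordings,
                         vapply(strsplit(names(cohort$recordings), "/"),
                                `[[`, "", 1))
    sqi <- sqi_report(per_subject, bands = cfg$bands, nw = cfg$nw)
    write_sqi_csv(sqi, file.path(cfg$out_dir, "sqi.csv"))
  }

  stats_out <- NULL
  if (isTRUE(cfg$stats)) {
    rated <- stats::reshape(as.data.frame(labels[, c("subject_id", "session",
                                                     "rated_score")]),
                            direction = "wide", idvar = "subject_id",
                            timevar = "session")
    m <- as.matrix(rated[, -1])
    colnames(m) <- sub("^rated_score\\.", "", colnames(m))
    fr <- friedman_test(m)
    stats_out <- list(normality = normality_screen(m), friedman = fr,
                      posthoc = posthoc_pairwise(fr))
    utils::write.csv(data.frame(chi2 = fr$chi2, df = fr$df, p = fr$p,
                                t(fr$mean_ranks)),
                     file.path(cfg$out_dir, "friedman_rated.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(stats_out$posthoc),
                     file.path(cfg$out_dir, "posthoc_rated.csv"),
                     row.names = FALSE)
  }

  ml_out <- NULL
  if (isTRUE(cfg$ml)) {
    ml_out <- list(
      within = evaluate_within_subject(features, cfg$model, cfg$scheme_within),
      cross = evaluate_cross_subject(features, cfg$model, cfg$scheme_cross))
    utils::write.csv(as.data.frame(ml_out$within$per_unit),
                     file.path(cfg$out_dir, "within_subject_report.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ml_out$cross$per_unit),
                     file.path(cfg$out_dir, "cross_subject_report.csv"),
                     row.names = FALSE)
  }

  invisible(list(cohort = cohort, calibrations = calibs, labels = labels,
                 features = features, sqi = sqi, stats = stats_out,
                 ml = ml_out, out_dir = cfg$out_dir))
}
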