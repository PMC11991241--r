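# High/low engagement classification: random forest and SVM with grid-search
# hyperparameter tuning, stratified 80/20 holdout, and within-subject or
# cross-subject (pooled or leave-one-subject-out) evaluation. The scaler and
# the tuning CV touch only training rows; the holdout supplies the reported
# metrics. The positive class for F1 is "high".

#' Classifier specification and tuning grid
#'
#' Default grids follow the study's tuning design. The SVM grid is verbatim:
#' C in 0.1/1/10/100, gamma `"scale"` (1 / (p * var(X))) or `"auto"` (1 / p),
#' kernel RBF or linear. The random-forest grid is expressed in
#' `randomForest`'s native controls: `ntree` 100/200/300, `nodesize` (minimum
#' terminal-node size) 1/2/4, `maxnodes` (tree-size proxy for maximum depth)
#' unrestricted/32/256, and `replace` (bootstrap) TRUE/FALSE.
#'
#' @param family `"svm"` or `"random-forest"`.
#' @param grid named list of candidate vectors overriding the default grid.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("svm", "random-forest"), grid = NULL) {
  family <- match.arg(family)
  default <- if (family == "svm")
    list(C = c(0.1, 1, 10, 100), gamma = c("scale", "auto"),
         kernel = c("rbf", "linear"))
  else
    list(ntree = c(100, 200, 300), nodesize = c(1, 2, 4),
         maxnodes = c(NA, 32, 256), replace = c(TRUE, FALSE))
  grid <- grid %||% default
  assert_that(length(grid) > 0 && all(lengths(grid) > 0), "grid must be non-empty")
  structure(list(family = family, grid = grid), class = "model_spec")
}

#' Cross-validation scheme
#'
#' Reconciles the 80/20 holdout with the tuning folds: the reported metrics
#' always come from the stratified 20% holdout, and all cross-validation for
#' hyperparameter selection runs inside the 80% training partition (10 folds
#' for a single-index within-subject model, 5 for combined/cross-subject;
#' nested outer-5/inner-3 for the combined within-subject design).
#'
#' @param mode `"within-subject"` or `"cross-subject"`.
#' @param holdout_fraction test fraction in (0, 0.5].
#' @param tuning_folds CV folds for the grid search.
#' @param nested use nested CV (outer 5 / inner 3) inside the training split.
#' @param stratified stratify splits and folds by label.
#' @param seed integer seed driving every split.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(mode = c("within-subject", "cross-subject"),
                      holdout_fraction = 0.2, tuning_folds = 5,
                      nested = FALSE, stratified = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  assert_that(holdout_fraction > 0 && holdout_fraction <= 0.5,
              "holdout_fraction must be in (0, 0.5]")
  assert_that(tuning_folds >= 2, "tuning_folds must be >= 2")
  structure(list(mode = mode, holdout_fraction = holdout_fraction,
                 tuning_folds = tuning_folds, nested = nested,
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Standard-scale a feature table
#'
#' Centers and scales every feature column to mean 0 / SD 1 using statistics
#' computed on `fit_on` rows only; the same affine transform is then applied
#' to all rows (so a held-out partition generally does not have mean 0).
#' Zero-variance columns are flagged and passed through with scale 1.
#'
#' @param x numeric matrix (rows = epochs, columns = features).
#' @param fit_on integer row indices the scaler is fitted on.
#' @return List with `scaled` (matrix), `center`, `scale`, `flagged`
#'   (zero-variance column names).
#' @export
standardize <- function(x, fit_on = seq_len(nrow(x))) {
  x <- as.matrix(x)
  assert_that(length(fit_on) > 0, "fit_on must be non-empty")
  ctr <- colMeans(x[fit_on, , drop = FALSE])
  scl <- apply(x[fit_on, , drop = FALSE], 2, stats::sd)
  flagged <- colnames(x)[!is.na(scl) & scl == 0]
  scl[is.na(scl) | scl == 0] <- 1
  list(scaled = sweep(sweep(x, 2, ctr), 2, scl, "/"),
       center = ctr, scale = scl, flagged = flagged)
}

stratified_split <- function(labels, frac, seed, stratified = TRUE) {
  with_seed(seed, {
    if (stratified) {
      test <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
        n_test <- max(1, round(length(idx) * frac))
        sample(idx, n_test)
      }), use.names = FALSE)
    } else {
      test <- sample(seq_along(labels), max(1, round(length(labels) * frac)))
    }
    sort(test)
  })
}

make_folds <- function(labels, k, seed, stratified = TRUE) {
  with_seed(seed, {
    fold <- integer(length(labels))
    groups <- if (stratified) split(seq_along(labels), labels)
              else list(seq_along(labels))
    for (idx in groups)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    fold
  })
}

resolve_gamma <- function(gamma, x) {
  if (is.numeric(gamma)) return(gamma)
  p <- ncol(x)
  if (gamma == "scale") 1 / (p * max(stats::var(as.vector(x)), 1e-12))
  else if (gamma == "auto") 1 / p
  else stop_input(sprintf("unknown gamma '%s'", gamma))
}

fit_model <- function(spec, params, x, y, seed = 1L) {
  y <- factor(y, levels = c("high", "low"))
  if (spec$family == "svm") {
    kern <- if (params$kernel == "rbf") "radial" else params$kernel
    e1071::svm(x, y, kernel = kern, cost = as.numeric(params$C),
               gamma = resolve_gamma(params$gamma, x), scale = FALSE)
  } else {
    mx <- params$maxnodes
    if (is.na(mx)) mx <- NULL else mx <- as.integer(mx)
    with_seed(seed,
      randomForest::randomForest(
        x, y, ntree = as.integer(params$ntree),
        nodesize = as.integer(params$nodesize), maxnodes = mx,
        replace = as.logical(params$replace)))
  }
}

predict_labels <- function(model, x) as.character(predict(model, x))

#' Classification metrics with a fixed positive class
#'
#' @param truth,pred character vectors of `"high"`/`"low"` labels.
#' @return List with `accuracy`, `f1` (positive class `"high"`), `confusion`
#'   (2x2 table, truth in rows), `n`.
#' @export
classification_metrics <- function(truth, pred) {
  lv <- c("high", "low")
  cm <- table(factor(truth, lv), factor(pred, lv), dnn = c("truth", "pred"))
  tp <- cm["high", "high"]; fp <- cm["low", "high"]
  fn <- cm["high", "low"]
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(accuracy = sum(diag(cm)) / sum(cm), f1 = f1, confusion = cm,
       n = length(truth))
}

grid_combos <- function(grid) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

# Grid search by k-fold CV accuracy on (x, y); deterministic tie-break on
# grid order. Returns the winning parameter list.
grid_search <- function(spec, x, y, folds, seed = 1L) {
  combos <- grid_combos(spec$grid)
  if (length(combos) == 1) return(combos[[1]])
  scores <- vapply(combos, function(par) {
    accs <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      mdl <- fit_model(spec, par, x[tr, , drop = FALSE], y[tr], seed)
      mean(predict_labels(mdl, x[!tr, , drop = FALSE]) == y[!tr])
    }, 0)
    mean(accs, na.rm = TRUE)
  }, 0)
  combos[[which.max(scores)]]
}

# Nested tuning: outer folds each run an inner grid search; the most
# frequently selected parameter set wins (grid-order tie-break).
nested_grid_search <- function(spec, x, y, outer = 5, inner = 3, seed = 1L,
                               stratified = TRUE) {
  ofold <- make_folds(y, outer, substream_seed(seed, "outer"), stratified)
  combos <- grid_combos(spec$grid)
  key <- function(par) paste(unlist(par), collapse = "|")
  picks <- vapply(sort(unique(ofold)), function(f) {
    tr <- ofold != f
    ifold <- make_folds(y[tr], inner, substream_seed(seed, "inner", f), stratified)
    key(grid_search(spec, x[tr, , drop = FALSE], y[tr], ifold, seed))
  }, "")
  keys <- vapply(combos, key, "")
  combos[[which.max(vapply(keys, function(k) sum(picks == k), 0))]]
}

evaluate_unit <- function(spec, scheme, x, y, seed) {
  test <- stratified_split(y, scheme$holdout_fraction, seed, scheme$stratified)
  tr <- setdiff(seq_along(y), test)
  sc <- standardize(x, fit_on = tr)
  xs <- sc$scaled
  params <- if (scheme$nested)
    nested_grid_search(spec, xs[tr, , drop = FALSE], y[tr], 5, 3, seed,
                       scheme$stratified)
  else
    grid_search(spec, xs[tr, , drop = FALSE], y[tr],
                make_folds(y[tr], scheme$tuning_folds,
                           substream_seed(seed, "folds"), scheme$stratified),
                seed)
  mdl <- fit_model(spec, params, xs[tr, , drop = FALSE], y[tr], seed)
  met <- classification_metrics(y[test], predict_labels(mdl, xs[test, , drop = FALSE]))
  list(metrics = met, params = params, n_train = length(tr), n_test = length(test))
}

report_row <- function(unit, res) {
  cm <- res$metrics$confusion
  tibble::tibble(unit = unit, n_test = res$metrics$n,
                 accuracy = res$metrics$accuracy, f1 = res$metrics$f1,
                 tp = cm["high", "high"], fn = cm["high", "low"],
                 fp = cm["low", "high"], tn = cm["low", "low"],
                 params = paste(names(res$params),
                                vapply(res$params, as.character, ""),
                                sep = "=", collapse = ","))
}

new_report <- function(per_unit, mode, spec, scheme, features) {
  summary <- tibble::tibble(mean_accuracy = mean(per_unit$accuracy),
                            sd_accuracy = stats::sd(per_unit$accuracy),
                            mean_f1 = mean(per_unit$f1),
                            sd_f1 = stats::sd(per_unit$f1))
  by_age <- NULL
  if ("age_group" %in% names(per_unit))
    by_age <- dplyr::summarise(dplyr::group_by(per_unit, age_group),
                               mean_accuracy = mean(accuracy),
                               mean_f1 = mean(f1), n = dplyr::n(),
                               .groups = "drop")
  structure(list(per_unit = per_unit, summary = summary, by_age = by_age,
                 mode = mode, family = spec$family,
                 positive_class = "high",
                 feature_cols = feature_cols(features),
                 scheme = scheme),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s %s: mean accuracy %.3f, mean F1 %.3f (n = %d)\n",
              x$mode, x$family, x$summary$mean_accuracy, x$summary$mean_f1,
              nrow(x$per_unit)))
  invisible(x)
}

check_features <- function(features) {
  assert_that(is.data.frame(features) &&
              all(c("subject_id", "label") %in% names(features)),
              "features must carry subject_id and label columns")
  assert_that(all(features$label %in% c("high", "low")),
              "feature labels must be high/low (neutral removed upstream)")
}

#' Within-subject evaluation
#'
#' For every retained subject: stratified 80/20 split of their epochs, scaler
#' and grid-search CV confined to the training 80%, best model refitted and
#' scored on the 20% holdout. Aggregates mean +/- SD across subjects and by
#' age group when an `age_group` column is present.
#'
#' @param features an [build_feature_table()] result (plus optional
#'   `age_group` column); every subject must carry both classes.
#' @param model a [model_spec()].
#' @param scheme a [cv_scheme()] with mode `"within-subject"`.
#' @return An `evaluation_report`: `per_unit` (one row per subject with
#'   accuracy, F1, confusion counts and chosen hyperparameters), `summary`,
#'   `by_age`.
#' @export
evaluate_within_subject <- function(features, model = model_spec("svm"),
                                    scheme = cv_scheme("within-subject")) {
  check_features(features)
  fc <- feature_cols(features)
  rows <- list()
  for (sid in unique(features$subject_id)) {
    sub <- features[features$subject_id == sid, , drop = FALSE]
    if (length(unique(sub$label)) < 2)
      stop_input(sprintf(
        "subject %s has a single class; apply the flow-scale retention rule first", sid))
    res <- evaluate_unit(model, scheme, as.matrix(sub[, fc]), sub$label,
                         substream_seed(scheme$seed, sid))
    row <- report_row(sid, res)
    if ("age_group" %in% names(sub)) row$age_group <- sub$age_group[1]
    rows[[sid]] <- row
  }
  new_report(dplyr::bind_rows(rows), "within-subject", model, scheme, features)
}

#' Cross-subject evaluation
#'
#' Default (`pooling = "pooled"`): all epochs pooled, stratified 80/20 split,
#' grid search by CV on the training partition, metrics on the holdout.
#' Because pooled splitting lets one subject appear in both partitions, the
#' alternative `pooling = "loso"` holds out each subject in turn and reports
#' per-held-out-subject metrics.
#'
#' @param features an [build_feature_table()] result spanning >= 2 subjects.
#' @param model a [model_spec()].
#' @param scheme a [cv_scheme()] with mode `"cross-subject"`.
#' @param pooling `"pooled"` or `"loso"`.
#' @return An `evaluation_report` (one `per_unit` row for the pooled design,
#'   one per held-out subject for LOSO).
#' @export
evaluate_cross_subject <- function(features, model = model_spec("svm"),
                                   scheme = cv_scheme("cross-subject"),
                                   pooling = c("pooled", "loso")) {
  check_features(features)
  pooling <- match.arg(pooling)
  assert_that(length(unique(features$subject_id)) >= 2,
              "cross-subject evaluation needs >= 2 subjects")
  fc <- feature_cols(features)
  x <- as.matrix(features[, fc])
  y <- features$label
  if (pooling == "pooled") {
    res <- evaluate_unit(model, scheme, x, y, substream_seed(scheme$seed, "pooled"))
    rep <- new_report(report_row("pooled", res), "cross-subject", model,
                      scheme, features)
    rep$pooling <- "pooled"
    return(rep)
  }
  rows <- list()
  for (sid in unique(features$subject_id)) {
    test <- which(features$subject_id == sid)
    tr <- setdiff(seq_along(y), test)
    sc <- standardize(x, fit_on = tr)
    params <- grid_search(model, sc$scaled[tr, , drop = FALSE], y[tr],
                          make_folds(y[tr], scheme$tuning_folds,
                                     substream_seed(scheme$seed, sid, "folds"),
                                     scheme$stratified),
                          scheme$seed)
    mdl <- fit_model(model, params, sc$scaled[tr, , drop = FALSE], y[tr],
                     scheme$seed)
    met <- classification_metrics(y[test],
                                  predict_labels(mdl, sc$scaled[test, , drop = FALSE]))
    rows[[sid]] <- report_row(sid, list(metrics = met, params = params))
  }
  rep <- new_report(dplyr::bind_rows(rows), "cross-subject", model, scheme,
                    features)
  rep$pooling <- "loso"
  rep
}

#' Compare evaluation reports
#'
#' Tabulates mean accuracy/F1 across reports by a grouping key and marks the
#' best cell (ties flagged).
#'
#' @param reports named list of `evaluation_report`s (names become the
#'   `classifier`/`feature_set` key as appropriate).
#' @param grouping `"classifier"`, `"feature_set"` or `"age_group"`.
#' @return A tibble with the group key, `mean_accuracy`, `mean_f1`, `best`
#'   (logical) and attribute `"tie"`.
#' @export
compare_reports <- function(reports, grouping = c("classifier", "feature_set",
                                                  "age_group")) {
  grouping <- match.arg(grouping)
  assert_that(length(reports) >= 1, "need at least one report")
  ns <- vapply(reports, function(r) nrow(r$per_unit), 0)
  if (grouping != "age_group" && length(unique(ns)) > 1)
    stop_input("comparison error: reports evaluate different cohorts")
  if (grouping == "age_group") {
    tabs <- lapply(reports, function(r) {
      assert_that(!is.null(r$by_age), "reports lack age-group breakdowns")
      r$by_age
    })
    tab <- dplyr::summarise(dplyr::group_by(dplyr::bind_rows(tabs), age_group),
                            mean_accuracy = mean(mean_accuracy),
                            mean_f1 = mean(mean_f1), .groups = "drop")
    names(tab)[1] <- grouping
  } else {
    tab <- tibble::tibble(
      group = names(reports) %||% paste0("report", seq_along(reports)),
      mean_accuracy = vapply(reports, function(r) r$summary$mean_accuracy, 0),
      mean_f1 = vapply(reports, function(r) r$summary$mean_f1, 0))
    names(tab)[1] <- grouping
  }
  tab$best <- tab$mean_f1 == max(tab$mean_f1)
  attr(tab, "tie") <- sum(tab$best) > 1
  tab
}
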