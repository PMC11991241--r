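# Classification harness: scaling, splits, tuning, evaluation, leakage.

test_that("standardize matches closed-form z-scores and flags constant columns", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  sc <- standardize(x)
  expect_equal(sc$scaled[, "a"], c(-1, 0, 1), tolerance = 1e-6)
  expect_equal(unname(sc$scaled[1, "a"]) * sd(c(1, 2, 3)), -1)  # scale = sample SD
  expect_identical(sc$flagged, "b")
  expect_equal(sc$scaled[, "b"], c(0, 0, 0))
})

test_that("scaler fitted on train only leaves the test partition off-center", {
  x <- cbind(f = c(rep(0, 50), rep(10, 10)))
  sc <- standardize(x, fit_on = 1:50)
  expect_equal(mean(sc$scaled[1:50, 1]), 0)
  expect_gt(abs(mean(sc$scaled[51:60, 1])), 1)
})

test_that("default grids carry the documented tuning ranges", {
  svm <- model_spec("svm")
  expect_equal(svm$grid$C, c(0.1, 1, 10, 100))
  expect_setequal(svm$grid$gamma, c("scale", "auto"))
  expect_setequal(svm$grid$kernel, c("rbf", "linear"))
  rf <- model_spec("random-forest")
  expect_equal(rf$grid$ntree, c(100, 200, 300))
  expect_equal(rf$grid$nodesize, c(1, 2, 4))
  expect_error(model_spec("svm", grid = list()), "non-empty")
})

test_that("metrics are mutually consistent and use high as the positive class", {
  truth <- c(rep("high", 6), rep("low", 4))
  pred <- c(rep("high", 5), "low", "high", rep("low", 3))
  m <- classification_metrics(truth, pred)
  expect_equal(sum(m$confusion), 10)
  expect_equal(m$accuracy, 8 / 10)
  prec <- 5 / 6; rec <- 5 / 6
  expect_equal(m$f1, 2 * prec * rec / (prec + rec))
})

test_that("a 360-epoch subject yields a 72-epoch test set; 5760 pooled rows yield 1152", {
  ft <- fake_features(n_sub = 1, n_ep = 180, n_feat = 3, seed = 2)
  rep <- evaluate_within_subject(ft, small_svm(), fast_scheme(seed = 3))
  expect_equal(rep$per_unit$n_test, 72)
  expect_equal(rep$per_unit$tp + rep$per_unit$fn +
               rep$per_unit$fp + rep$per_unit$tn, 72)
  labels <- rep(c("high", "low"), c(3840, 1920))
  test <- eegflow:::stratified_split(labels, 0.2, seed = 1)
  expect_equal(length(test), 1152)
  # stratification preserves the 2:1 imbalance
  expect_equal(sum(labels[test] == "high"), 768)
})

test_that("separable subjects reach near-perfect F1; shuffled labels fall to baseline", {
  ft <- fake_features(n_sub = 3, n_ep = 60, sep = 4, seed = 5)
  rep <- evaluate_within_subject(ft, small_svm(), fast_scheme(seed = 7))
  expect_gte(rep$summary$mean_f1, 0.95)
  expect_true(all(c("older", "young") %in% rep$by_age$age_group))

  # shuffled labels at the study's 2:1 imbalance fall to the majority baseline
  fti <- fake_features(n_sub = 2, n_ep = 40, sep = 4, seed = 5, imbalance = 2)
  base <- majority_f1(fti$label)
  f1s <- vapply(1:20, function(s) {
    sh <- fti
    set.seed(100 + s)
    sh$label <- sample(sh$label)
    attr(sh, "feature_cols") <- attr(fti, "feature_cols")
    evaluate_within_subject(sh, small_svm(),
                            fast_scheme(seed = s))$summary$mean_f1
  }, 0)
  expect_lt(abs(mean(f1s) - base), 0.1)
})

test_that("single-class subjects are rejected as a contract violation", {
  ft <- fake_features(n_sub = 2, n_ep = 20, seed = 6)
  ft1 <- ft[!(ft$subject_id == "s01" & ft$label == "low"), ]
  attr(ft1, "feature_cols") <- attr(ft, "feature_cols")
  expect_error(evaluate_within_subject(ft1, small_svm(), fast_scheme()),
               "single class")
})

test_that("cross-subject pooled evaluation works and LOSO exposes a label-swapped subject", {
  ft <- fake_features(n_sub = 4, n_ep = 30, sep = 4, seed = 8)
  pooled <- evaluate_cross_subject(ft, small_svm(),
                                   fast_scheme("cross-subject", seed = 9))
  expect_gte(pooled$summary$mean_f1, 0.95)
  expect_identical(pooled$pooling, "pooled")

  sw <- ft
  swap <- sw$subject_id == "s04"
  sw$label[swap] <- ifelse(sw$label[swap] == "high", "low", "high")
  attr(sw, "feature_cols") <- attr(ft, "feature_cols")
  loso <- evaluate_cross_subject(sw, small_svm(),
                                 fast_scheme("cross-subject", seed = 9),
                                 pooling = "loso")
  f1 <- loso$per_unit$f1
  names(f1) <- loso$per_unit$unit
  expect_lt(f1[["s04"]], 0.2)
  expect_gt(min(f1[c("s01", "s02", "s03")]), 0.9)
  expect_error(evaluate_cross_subject(ft[ft$subject_id == "s01", ],
                                      small_svm()), ">= 2 subjects")
})

test_that("random forest evaluates under its native grid", {
  ft <- fake_features(n_sub = 2, n_ep = 40, sep = 4, seed = 10)
  rep <- evaluate_within_subject(ft, small_rf(), fast_scheme(seed = 11))
  expect_gte(rep$summary$mean_f1, 0.9)
})

test_that("nested tuning runs inside the training split", {
  ft <- fake_features(n_sub = 1, n_ep = 50, sep = 3, seed = 12)
  sch <- cv_scheme("within-subject", nested = TRUE, seed = 13)
  rep <- evaluate_within_subject(ft, small_svm(), sch)
  expect_gte(rep$summary$mean_f1, 0.9)
})

test_that("fixed seeds reproduce splits, hyperparameters and metrics exactly", {
  ft <- fake_features(n_sub = 2, n_ep = 30, sep = 1, seed = 14)
  r1 <- evaluate_within_subject(ft, small_svm(), fast_scheme(seed = 15))
  r2 <- evaluate_within_subject(ft, small_svm(), fast_scheme(seed = 15))
  expect_identical(r1$per_unit, r2$per_unit)
  r3 <- evaluate_within_subject(ft, small_svm(), fast_scheme(seed = 16))
  expect_false(identical(r1$per_unit$params, r3$per_unit$params) &&
               identical(r1$per_unit$accuracy, r3$per_unit$accuracy) &&
               identical(r1$per_unit$tp, r3$per_unit$tp))
})

test_that("a marker feature informative only in the test rows cannot be exploited", {
  # features carry no signal except a marker column that equals the label --
  # but only on the rows the holdout will select; training rows get noise.
  ft <- fake_features(n_sub = 1, n_ep = 100, n_feat = 4, sep = 0, seed = 17,
                      imbalance = 2)
  sch <- fast_scheme(seed = 18)
  test_rows <- eegflow:::stratified_split(ft$label, sch$holdout_fraction,
                                          eegflow:::substream_seed(sch$seed, "s01"),
                                          TRUE)
  set.seed(19)
  marker <- rnorm(nrow(ft))
  marker[test_rows] <- ifelse(ft$label[test_rows] == "high", 5, -5)
  ft$marker <- marker
  attr(ft, "feature_cols") <- c(attr(fake_features(1, 1, 4), "feature_cols"),
                                "marker")
  rep <- evaluate_within_subject(ft, small_svm(), sch)
  # if any test information leaked into training, the marker would be learned
  # and F1 would approach 1; at baseline it stays near the majority rate
  expect_lt(rep$summary$mean_f1, majority_f1(ft$label) + 0.1)
})

test_that("compare_reports tabulates groups, flags ties, and rejects mismatched cohorts", {
  ft <- fake_features(n_sub = 2, n_ep = 30, sep = 4, seed = 20)
  r1 <- evaluate_within_subject(ft, small_svm(), fast_scheme(seed = 21))
  cmp <- compare_reports(list(svm = r1, svm2 = r1), grouping = "classifier")
  expect_equal(unname(cmp$mean_f1[1]), unname(cmp$mean_f1[2]))
  expect_true(attr(cmp, "tie"))
  age <- compare_reports(list(svm = r1), grouping = "age_group")
  expect_setequal(age$age_group, c("older", "young"))
  other <- evaluate_within_subject(fake_features(n_sub = 3, n_ep = 30, seed = 22),
                                   small_svm(), fast_scheme(seed = 23))
  expect_error(compare_reports(list(a = r1, b = other), "classifier"),
               "cohorts")
})
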