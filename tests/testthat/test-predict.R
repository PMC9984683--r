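test_that("ROC metrics match hand-computed oracles", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  m <- roc_metrics(scores, labels)
  # concordant pairs: 8 of 9 -> AUC = 8/9
  expect_equal(m$auc, 8 / 9, tolerance = 1e-12)
  expect_true(m$sensitivity >= 0 && m$sensitivity <= 1)
  # ties count one half
  m2 <- roc_metrics(c(0.6, 0.6, 0.6, 0.6), c(1, 1, 0, 0))
  expect_equal(m2$auc, 0.5, tolerance = 1e-12)
  # fixed threshold is honoured
  m3 <- roc_metrics(scores, labels, threshold = 0.5)
  expect_equal(m3$sensitivity, 2 / 3)  # 0.9, 0.8 above; 0.4 below
  expect_equal(m3$specificity, 2 / 3)  # 0.7 misclassified; 0.3, 0.1 correct
  expect_true(is.na(roc_metrics(scores, rep(1, 6))$auc))
})

test_that("perfect separation gives AUC 1 at the Youden point", {
  m <- roc_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
})

test_that("McNemar comparison follows the printed decision rule", {
  # 10 vs 0 discordant: exact two-sided binomial, p = 2 * 0.5^10
  labels <- rep(1, 12)
  a <- rep(1, 12)
  b <- c(rep(0, 10), 1, 1)
  mc <- mcnemar_compare(a, b, labels)
  expect_equal(mc$method, "exact")
  expect_equal(unname(mc$statistic["b"]), 10)
  expect_equal(unname(mc$statistic["c"]), 0)
  expect_equal(mc$p, 2 * 0.5^10, tolerance = 1e-12)

  # 15 vs 5: exact binomial oracle
  labels2 <- rep(1, 20)
  a2 <- c(rep(1, 15), rep(0, 5))
  b2 <- c(rep(0, 15), rep(1, 5))
  mc2 <- mcnemar_compare(a2, b2, labels2)
  expect_equal(mc2$method, "exact")
  expect_equal(mc2$p, stats::binom.test(15, 20, 0.5)$p.value, tolerance = 1e-12)
  expect_equal(mc2$p, 0.04139, tolerance = 1e-4)

  # >= 25 discordant pairs: chi-square with continuity correction
  labels3 <- rep(1, 30)
  a3 <- c(rep(1, 20), rep(0, 10))
  b3 <- c(rep(0, 20), rep(1, 10))
  mc3 <- mcnemar_compare(a3, b3, labels3)
  expect_equal(mc3$method, "chi-square")
  expect_equal(mc3$p,
               stats::mcnemar.test(matrix(c(0, 10, 20, 0), 2))$p.value,
               tolerance = 1e-12)

  # identical classifiers: no discordance, p = 1
  mc4 <- mcnemar_compare(a, a, labels)
  expect_equal(mc4$p, 1)
})

test_that("BH adjustment matches the textbook example and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  adj <- fdr_adjust(p)
  expect_equal(adj, stats::p.adjust(p, "BH"))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p))
})

test_that("IMPACT score reproduces the logistic oracle from its config", {
  cfg <- list(intercept = -2,
              coefficients = list(age = 0.03, motor = -0.2))
  cov <- data.frame(age = c(40, 80), motor = c(6, 1))
  p <- impact_score(cov, cfg)
  expect_equal(p, stats::plogis(c(-2 + 0.03 * 40 - 0.2 * 6,
                                  -2 + 0.03 * 80 - 0.2 * 1)),
               tolerance = 1e-12)
  expect_true(all(diff(p) > 0))
  expect_error(impact_score(data.frame(age = 50), cfg), "motor")
})

test_that("the shipped synthetic IMPACT config loads and scores", {
  tab <- fix_small_table()
  p <- impact_score(tab[!duplicated(tab$patient_id), covariate_names()],
                    impact_config_path())
  expect_true(all(p > 0 & p < 1))
  expect_length(p, length(unique(tab$patient_id)))
})

test_that("median imputation reuses training statistics on test data", {
  x <- data.frame(a = c(1, 2, NA, 4), b = c(NA, 1, 1, 1))
  tr <- median_impute(x)
  expect_false(anyNA(tr$x))
  expect_equal(tr$x$a[3], 2)
  te <- median_impute(data.frame(a = c(NA, 10), b = c(2, NA)),
                      stats = tr$stats)
  expect_equal(te$x$a[1], 2)   # training median, not the test one
  expect_equal(te$x$b[2], 1)
})

test_that("folds are patient-grouped and stratified", {
  tab <- fix_small_table()
  agg <- aggregate_features(tab, 24)
  fold <- qeegtbi:::make_folds(agg$patient_id, agg$y, k = 3, seed = 1)
  expect_length(fold, length(unique(agg$patient_id)))
  y_pat <- tapply(agg$y, agg$patient_id, `[`, 1)
  for (f in unique(fold)) {
    cls <- y_pat[names(fold)[fold == f]]
    expect_true(all(table(cls) >= 1))
  }
})

test_that("aggregate_features concatenates timepoints and flags missing ones", {
  tab <- fix_small_table()
  two <- rbind(tab, within(tab, timepoint_h <- 48))
  # drop one patient's late recording entirely
  drop_id <- two$patient_id[1]
  two <- two[!(two$patient_id == drop_id & two$timepoint_h == 48), ]
  agg <- aggregate_features(two, c(24, 48))
  expect_true(all(paste0("abs_power.alpha@", c(24, 48), "h") %in% names(agg$x)))
  expect_equal(nrow(agg$x), nrow(tab))
  expect_true(all(agg$imputed[agg$patient_id == drop_id]))
  expect_false(any(agg$imputed[agg$patient_id != drop_id]))
})

test_that("cross-validation is deterministic, grouped, and leak-free by design", {
  tab <- fix_small_table()
  cv1 <- crossvalidate(tab, 24, k = 3, n_trees = 100, seed = 5)
  cv2 <- crossvalidate(tab, 24, k = 3, n_trees = 100, seed = 5)
  expect_equal(cv1$patient$score, cv2$patient$score)
  expect_equal(cv1$mean_auc, cv2$mean_auc)
  expect_s3_class(cv1, "qeeg_cv")
  # every patient scored exactly once, in exactly one fold
  expect_setequal(cv1$patient$patient_id, unique(tab$patient_id))
  expect_false(anyDuplicated(cv1$patient$patient_id) > 0)
  expect_length(cv1$fold_auc, 3)
  expect_named(cv1$importance)
  expect_output(print(cv1), "mean AUC")
})

test_that("backward elimination walks the path and obeys the stop rule", {
  tab <- fix_small_table()
  feats <- c("abs_power.alpha", "abs_power.delta", "bsi",
             "variability.alpha", "sef90", "coherence")
  be <- backward_elimination(tab, 24, features = feats, k = 3, n_trees = 100,
                             seed = 5)
  expect_s3_class(be, "qeeg_elimination")
  expect_equal(be$trace$n_features, seq(length(feats), 1))
  expect_true(all(be$selected %in% feats))
  best <- max(be$trace$auc)
  sel_auc <- be$trace$auc[be$trace$n_features == length(be$selected)]
  expect_gte(sel_auc, best - 0.02)
  # no smaller subset along the path satisfies the rule
  smaller <- be$trace$auc[be$trace$n_features < length(be$selected)]
  if (length(smaller)) expect_true(all(smaller < best - 0.02))
})

test_that("combined model labels importance by source", {
  tab <- fix_small_table()
  cm <- combined_model(tab, 24, features = c("abs_power.alpha", "bsi"),
                       covariates = c("age", "motor"), k = 3, n_trees = 100)
  expect_s3_class(cm, "qeeg_cv")
  it <- cm$importance_table
  expect_setequal(it$feature, c("abs_power.alpha", "bsi", "age", "motor"))
  expect_equal(unname(vapply(c("age", "motor"), function(f)
    it$source[it$feature == f], character(1))), rep("clinical", 2))
  expect_equal(it$source[it$feature == "bsi"], "EEG")
  expect_true(all(diff(it$importance) <= 0))
})
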