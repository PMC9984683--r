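#' Build model matrices from the cohort feature table
#'
#' For a single timepoint, returns the per-segment rows (three rows per
#' patient: the segment-level data augmentation). For several timepoints the
#' feature columns are concatenated across timepoints (suffixed `@<t>h`),
#' matching rows by patient and segment; a patient missing a timepoint gets
#' NA features there (flagged in `imputed`), to be filled from training-fold
#' medians at fit time.
#'
#' @param table cohort feature table from [extract_cohort_features()].
#' @param timepoints one or more timepoints in hours.
#' @param features feature column names (default [feature_names()]).
#' @param covariates optional clinical covariate columns appended once.
#' @return List: `x` (data.frame of predictors), `y` (0/1 labels),
#'   `patient_id`, `imputed` (logical rows with any missing timepoint).
#' @export
aggregate_features <- function(table, timepoints, features = feature_names(),
                               covariates = character(0)) {
  features <- intersect(features, names(table))
  base <- subset(table, table$timepoint_h == timepoints[1])
  key <- paste(base$patient_id, base$segment_id)
  x <- base[, features, drop = FALSE]
  if (length(timepoints) > 1) {
    names(x) <- paste0(features, "@", timepoints[1], "h")
    for (tp in timepoints[-1]) {
      tt <- subset(table, table$timepoint_h == tp)
      m <- match(key, paste(tt$patient_id, tt$segment_id))
      xt <- tt[m, features, drop = FALSE]
      names(xt) <- paste0(features, "@", tp, "h")
      x <- cbind(x, xt)
    }
  }
  if (length(covariates)) x <- cbind(x, base[, covariates, drop = FALSE])
  list(x = x, y = base$outcome, patient_id = base$patient_id,
       imputed = !stats::complete.cases(x))
}

#' Train the random-forest outcome classifier
#'
#' Bagged decision-tree ensemble (200 trees by default, per-tree feature
#' subsampling) for poor-outcome classification, exposing the out-of-bag
#' error curve and mean-decrease-in-Gini feature importances.
#'
#' @param x predictor data.frame/matrix (complete cases; see
#'   [median_impute()]).
#' @param y 0/1 outcome labels (1 = poor).
#' @param n_trees ensemble size.
#' @param seed integer seed (fixed seed gives identical predictions).
#' @return `randomForest` object.
#' @export
train_random_forest <- function(x, y, n_trees = 200, seed = 1) {
  set.seed(seed)
  randomForest::randomForest(x = as.data.frame(x), y = factor(y, levels = 0:1),
                             ntree = n_trees, importance = FALSE)
}

#' Median imputation from training statistics
#'
#' @param x data.frame with possible NAs.
#' @param stats named medians to impute from (default: computed from `x`).
#' @return List `x` (complete) and `stats`.
#' @export
median_impute <- function(x, stats = NULL) {
  if (is.null(stats))
    stats <- vapply(x, function(col) stats::median(col, na.rm = TRUE),
                    numeric(1))
  stats[!is.finite(stats)] <- 0
  for (j in seq_along(x)) {
    bad <- !is.finite(x[[j]])
    if (any(bad)) x[[j]][bad] <- stats[[names(x)[j]]]
  }
  list(x = x, stats = stats)
}

#' ROC metrics at the patient level
#'
#' AUC by the trapezoidal rule (ties counted one half), with sensitivity and
#' specificity for the poor-outcome-positive class at a given probability
#' threshold (default: the Youden-optimal point of these scores).
#'
#' @param scores predicted probabilities of poor outcome, one per patient.
#' @param labels 0/1 outcome labels.
#' @param threshold probability cutoff for the operating point; `NULL` picks
#'   the Youden optimum on (`scores`, `labels`).
#' @return List `auc`, `sensitivity`, `specificity`, `threshold`, `roc`
#'   (data.frame of ROC points). `auc` is NA when a class is absent.
#' @export
roc_metrics <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    return(list(auc = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, threshold = threshold, roc = NULL))
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  if (is.null(threshold)) {
    cs <- pROC::coords(r, "best", best.method = "youden",
                       ret = "threshold", transpose = FALSE)
    threshold <- cs$threshold[1]
  }
  hard <- as.integer(scores >= threshold)
  sens <- sum(hard == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(hard == 0 & labels == 0) / sum(labels == 0)
  list(auc = as.numeric(pROC::auc(r)), sensitivity = sens,
       specificity = spec, threshold = threshold,
       roc = data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities))
}

# stratified patient-grouped fold assignment
make_folds <- function(patient_id, y, k, seed) {
  pats <- !duplicated(patient_id)
  pid <- patient_id[pats]
  py <- y[pats]
  set.seed(seed)
  fold <- integer(length(pid))
  for (cls in unique(py)) {
    idx <- sample(which(py == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  stats::setNames(fold, pid)
}

#' Cross-validated outcome prediction
#'
#' 5-fold cross-validation stratified by outcome and grouped by patient:
#' all three segment rows of a patient share a fold, so augmentation can
#' never leak between training and test. Missing predictor values are
#' imputed with training-fold medians. Per-patient test scores are the mean
#' of the patient's segment scores; the hard-label operating point is the
#' Youden-optimal threshold of the training patients' out-of-bag scores.
#'
#' @param table cohort feature table (needs `patient_id`, `outcome`,
#'   `timepoint_h`, `segment_id` and feature columns).
#' @param timepoints timepoint(s) defining the model.
#' @param features feature columns used as predictors.
#' @param covariates clinical covariate columns appended as predictors.
#' @param k number of folds.
#' @param n_trees forest size.
#' @param seed integer seed for folds and forests.
#' @return List of class `qeeg_cv`: `fold_auc`, `fold_sensitivity`,
#'   `fold_specificity`, `mean_auc`, `patient` (data.frame patient_id,
#'   outcome, score, pred, fold), `importance` (mean Gini importance across
#'   folds).
#' @export
crossvalidate <- function(table, timepoints, features = feature_names(),
                          covariates = character(0), k = 5, n_trees = 200,
                          seed = 1) {
  agg <- aggregate_features(table, timepoints, features, covariates)
  y_pat <- tapply(agg$y, agg$patient_id, function(v) v[1])
  if (min(table(y_pat)) < 2) stop("need at least 2 patients per class")
  fold <- make_folds(agg$patient_id, agg$y, k, seed)
  row_fold <- fold[agg$patient_id]
  fold_auc <- fold_sens <- fold_spec <- rep(NA_real_, k)
  pat_rows <- list()
  imp <- NULL
  for (f in seq_len(k)) {
    tr <- row_fold != f
    te <- !tr
    trn <- median_impute(agg$x[tr, , drop = FALSE])
    tst <- median_impute(agg$x[te, , drop = FALSE], stats = trn$stats)
    model <- train_random_forest(trn$x, agg$y[tr], n_trees = n_trees,
                                 seed = seed * 100 + f)
    gi <- randomForest::importance(model)[, "MeanDecreaseGini"]
    if (is.null(names(gi))) names(gi) <- colnames(agg$x)  # 1-predictor case
    imp <- if (is.null(imp)) gi else imp + gi
    # operating point from training-fold out-of-bag patient scores
    oob <- model$votes[, "1"]
    tr_pat <- tapply(oob, agg$patient_id[tr], mean)
    tr_lab <- y_pat[names(tr_pat)]
    thr <- if (length(unique(tr_lab)) == 2)
      roc_metrics(as.numeric(tr_pat), tr_lab)$threshold else 0.5
    prob <- stats::predict(model, tst$x, type = "prob")[, "1"]
    te_pat <- tapply(prob, agg$patient_id[te], mean)
    te_lab <- y_pat[names(te_pat)]
    if (length(unique(te_lab)) == 2) {
      m <- roc_metrics(as.numeric(te_pat), te_lab, threshold = thr)
      fold_auc[f] <- m$auc
      fold_sens[f] <- m$sensitivity
      fold_spec[f] <- m$specificity
    } else {
      warning("fold ", f, " contains a single outcome class; AUC undefined")
    }
    pat_rows[[f]] <- data.frame(patient_id = names(te_pat),
                                outcome = as.integer(te_lab),
                                score = as.numeric(te_pat),
                                pred = as.integer(te_pat >= thr),
                                fold = f, stringsAsFactors = FALSE)
  }
  structure(list(fold_auc = fold_auc, fold_sensitivity = fold_sens,
                 fold_specificity = fold_spec,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 patient = do.call(rbind, pat_rows),
                 importance = imp / k, timepoints = timepoints,
                 features = c(features, covariates)),
            class = "qeeg_cv")
}

#' @export
print.qeeg_cv <- function(x, ...) {
  cat(sprintf("<qeeg_cv> timepoint(s) %s h: mean AUC %.3f (folds: %s)\n",
              paste(x$timepoints, collapse = "+"), x$mean_auc,
              paste(sprintf("%.2f", x$fold_auc), collapse = " ")))
  invisible(x)
}

#' Backward feature elimination
#'
#' Starting from the full feature set, repeatedly records the
#' cross-validated AUC, then drops the feature with the lowest mean Gini
#' importance (ties broken by dropping the lexicographically last name).
#' The chosen subset is the smallest one whose AUC is within `drop_tol` of
#' the best AUC along the path.
#'
#' @inheritParams crossvalidate
#' @param drop_tol tolerated AUC drop from the path maximum.
#' @return List of class `qeeg_elimination`: `trace` (data.frame
#'   n_features, removed, auc), `selected` feature names.
#' @export
backward_elimination <- function(table, timepoints,
                                 features = feature_names(),
                                 covariates = character(0), k = 5,
                                 n_trees = 200, seed = 1, drop_tol = 0.02) {
  features <- intersect(features, names(table))
  cur <- features
  trace <- data.frame(n_features = integer(0), removed = character(0),
                      auc = numeric(0), stringsAsFactors = FALSE)
  sets <- list()
  step <- 0
  while (length(cur) >= 1) {
    cv <- crossvalidate(table, timepoints, cur, covariates, k = k,
                        n_trees = n_trees, seed = seed)
    sets[[length(sets) + 1]] <- cur
    imp <- cv$importance[cur]
    worst <- names(imp)[imp == min(imp)]
    worst <- sort(worst)[length(worst)]  # lexicographically last on ties
    trace <- rbind(trace, data.frame(n_features = length(cur),
                                     removed = worst, auc = cv$mean_auc,
                                     stringsAsFactors = FALSE))
    if (length(cur) == 1) break
    cur <- setdiff(cur, worst)
    step <- step + 1
  }
  best <- max(trace$auc, na.rm = TRUE)
  ok <- which(trace$auc >= best - drop_tol)
  pick <- ok[which.min(trace$n_features[ok])]
  structure(list(trace = trace, selected = sets[[pick]]),
            class = "qeeg_elimination")
}

#' McNemar comparison of two classifiers
#'
#' Paired comparison of hard predictions on the same patients, built on the
#' 2x2 discordance table of correctness. With fewer than 25 discordant
#' pairs the exact two-sided binomial test is used, otherwise the
#' chi-square approximation with continuity correction.
#'
#' @param preds_a,preds_b hard 0/1 predictions.
#' @param labels true 0/1 labels.
#' @return List `statistic` (discordant counts b, c), `p`, `method`.
#' @export
mcnemar_compare <- function(preds_a, preds_b, labels) {
  stopifnot(length(preds_a) == length(labels),
            length(preds_b) == length(labels))
  a_ok <- preds_a == labels
  b_ok <- preds_b == labels
  b <- sum(a_ok & !b_ok)
  cc <- sum(!a_ok & b_ok)
  if (b + cc == 0)
    return(list(statistic = c(b = b, c = cc), p = 1, method = "exact"))
  if (b + cc < 25) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    method <- "exact"
  } else {
    tab <- matrix(c(sum(a_ok & b_ok), cc, b, sum(!a_ok & !b_ok)), 2)
    p <- stats::mcnemar.test(tab, correct = TRUE)$p.value
    method <- "chi-square"
  }
  list(statistic = c(b = b, c = cc), p = min(1, p), method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values numeric vector of raw p-values.
#' @return Adjusted p-values (monotone step-up, in `[0, 1]`).
#' @export
fdr_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' IMPACT-style logistic prognostic score
#'
#' Probability of poor outcome from the logistic model
#' `plogis(intercept + sum(coef * covariate))`. The coefficient set is
#' supplied as configuration (named list or YAML path with `intercept` and
#' `coefficients`); published coefficient values must be provided by the
#' user. A synthetic example configuration ships with the package
#' (`system.file("extdata", "impact_coefficients_synthetic.yaml",
#' package = "qeegtbi")`).
#'
#' @param covariates data.frame of clinical covariates.
#' @param config named list with `intercept` and named `coefficients`, or a
#'   YAML file path.
#' @return Probabilities of poor outcome in (0, 1).
#' @export
impact_score <- function(covariates, config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  coefs <- unlist(config$coefficients)
  missing <- setdiff(names(coefs), names(covariates))
  if (length(missing))
    stop("missing covariate(s): ", paste(missing, collapse = ", "))
  lp <- config$intercept +
    as.matrix(covariates[, names(coefs), drop = FALSE]) %*% coefs
  stats::plogis(as.numeric(lp))
}

#' Combined EEG + clinical model
#'
#' Cross-validated random forest on the union of selected EEG features and
#' the clinical covariates, with the same patient-grouped protocol, plus a
#' source-labelled importance ranking.
#'
#' @inheritParams crossvalidate
#' @return `qeeg_cv` with an extra `importance_table` (feature, source,
#'   importance, sorted descending).
#' @export
combined_model <- function(table, timepoints, features = feature_names(),
                           covariates = names(default_covariate_model()),
                           k = 5, n_trees = 200, seed = 1) {
  covariates <- intersect(covariates, names(table))
  cv <- crossvalidate(table, timepoints, features, covariates, k = k,
                      n_trees = n_trees, seed = seed)
  imp <- sort(cv$importance, decreasing = TRUE)
  cv$importance_table <- data.frame(
    feature = names(imp),
    source = ifelse(sub("@.*", "", names(imp)) %in% covariates,
                    "clinical", "EEG"),
    importance = as.numeric(imp), stringsAsFactors = FALSE)
  cv
}
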