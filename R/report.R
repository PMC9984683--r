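#' Compare outcome models across timepoints
#'
#' Assembles a boxplot-ready per-fold AUC table and a pairwise McNemar
#' comparison (on patient-level hard predictions, FDR-adjusted) for a set
#' of cross-validation results, e.g. one per monitoring timepoint or
#' timepoint combination.
#'
#' @param cv_results named list of `qeeg_cv` objects.
#' @param alpha significance level applied to adjusted p-values.
#' @return List of class `qeeg_comparison`: `auc_table` (model, fold, auc),
#'   `pairwise` (model_a, model_b, b, c, p, p_adj, winner), where `winner`
#'   names the higher-AUC model of each pair significant at `alpha`.
#' @export
compare_timepoints <- function(cv_results, alpha = 0.05) {
  stopifnot(is.list(cv_results), length(cv_results) >= 1)
  if (is.null(names(cv_results)))
    names(cv_results) <- paste0("model", seq_along(cv_results))
  auc_table <- do.call(rbind, lapply(names(cv_results), function(nm) {
    data.frame(model = nm, fold = seq_along(cv_results[[nm]]$fold_auc),
               auc = cv_results[[nm]]$fold_auc, stringsAsFactors = FALSE)
  }))
  nms <- names(cv_results)
  pw <- NULL
  if (length(nms) >= 2) {
    combs <- utils::combn(nms, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- cv_results[[combs[1, i]]]$patient
      b <- cv_results[[combs[2, i]]]$patient
      m <- merge(a[, c("patient_id", "outcome", "pred")],
                 b[, c("patient_id", "pred")], by = "patient_id")
      mc <- mcnemar_compare(m$pred.x, m$pred.y, m$outcome)
      data.frame(model_a = combs[1, i], model_b = combs[2, i],
                 b = mc$statistic[["b"]], c = mc$statistic[["c"]],
                 p = mc$p, stringsAsFactors = FALSE)
    }))
    pw$p_adj <- fdr_adjust(pw$p)
    mean_auc <- vapply(cv_results, function(cv) cv$mean_auc, numeric(1))
    pw$winner <- ifelse(pw$p_adj < alpha,
                        ifelse(mean_auc[pw$model_a] >= mean_auc[pw$model_b],
                               pw$model_a, pw$model_b),
                        NA_character_)
  } else {
    pw <- data.frame(model_a = character(0), model_b = character(0),
                     b = integer(0), c = integer(0), p = numeric(0),
                     p_adj = numeric(0), winner = character(0),
                     stringsAsFactors = FALSE)
  }
  structure(list(auc_table = auc_table, pairwise = pw, alpha = alpha),
            class = "qeeg_comparison")
}

#' Ranked feature-importance report
#'
#' Features sorted by mean-decrease-in-Gini importance, labelled by source
#' (EEG feature vs clinical covariate).
#'
#' @param cv a `qeeg_cv` (importance averaged over folds).
#' @param clinical names treated as clinical covariates.
#' @return data.frame feature, source, importance (descending).
#' @export
importance_report <- function(cv, clinical = names(default_covariate_model())) {
  imp <- sort(cv$importance, decreasing = TRUE)
  data.frame(feature = names(imp),
             source = ifelse(sub("@.*", "", names(imp)) %in% clinical,
                             "clinical", "EEG"),
             importance = as.numeric(imp),
             stringsAsFactors = FALSE)
}

#' Write comparison and importance reports to CSV
#'
#' @param comparison a `qeeg_comparison`.
#' @param importance importance data.frame from [importance_report()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_reports <- function(comparison, importance, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "auc_by_fold.csv")
  p2 <- file.path(dir, "pairwise_mcnemar.csv")
  p3 <- file.path(dir, "feature_importance.csv")
  utils::write.csv(comparison$auc_table, p1, row.names = FALSE)
  utils::write.csv(comparison$pairwise, p2, row.names = FALSE)
  utils::write.csv(importance, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
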