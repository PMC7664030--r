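# Scoring, multi-threshold ROC, model comparison, and the explanation
# utilities: unit-perturbation attribution, drug-mutation interaction
# analysis, and the signed PPI edge-impact table.

#' Regression scores
#'
#' Coefficient of determination `R^2 = 1 - RSS/TSS` and root-mean-square
#' error. A constant actual vector leaves R-squared undefined (`NA` with a
#' warning).
#'
#' @param predictions,actuals Equal-length finite numeric vectors
#'   (`n >= 2`).
#' @return A list: `r2`, `rmse`.
#' @export
score <- function(predictions, actuals) {
  stopifnot(length(predictions) == length(actuals),
            length(actuals) >= 2L,
            all(is.finite(predictions)), all(is.finite(actuals)))
  rss <- sum((actuals - predictions)^2)
  tss <- sum((actuals - mean(actuals))^2)
  r2 <- if (tss == 0) {
    warning("zero total sum of squares: R^2 undefined")
    NA_real_
  } else 1 - rss / tss
  list(r2 = r2, rmse = sqrt(mean((actuals - predictions)^2)))
}

#' Multi-threshold averaged ROC/AUC
#'
#' Sensitivity classification from a regression of log-IC50: at each
#' threshold `t`, a response is labeled sensitive when its actual log-IC50
#' is below `t` (lower IC50 = more sensitive), scored by the negated
#' prediction, and an ROC AUC is computed; the scalar summary is the mean
#' AUC over thresholds. Averaging over several thresholds avoids the
#' overestimate a single lenient cut can give. Thresholds yielding a single
#' class are skipped and recorded.
#'
#' @param predictions,actuals Numeric log-IC50 vectors.
#' @param thresholds Numeric cutoffs (default `c(-4, -3, -2, -1, 0)`).
#' @return A list: `auc_by_threshold` (named, `NA` where skipped),
#'   `mean_auc`, `skipped` (thresholds that yielded one class).
#' @export
multithreshold_roc <- function(predictions, actuals,
                               thresholds = c(-4, -3, -2, -1, 0)) {
  aucs <- stats::setNames(rep(NA_real_, length(thresholds)),
                          as.character(thresholds))
  skipped <- numeric(0)
  for (i in seq_along(thresholds)) {
    lab <- actuals < thresholds[i]
    if (length(unique(lab)) < 2L) {
      skipped <- c(skipped, thresholds[i])
      next
    }
    aucs[i] <- as.numeric(pROC::auc(
      response = factor(lab, levels = c(FALSE, TRUE)),
      predictor = -predictions, direction = "<", quiet = TRUE))
  }
  if (length(skipped))
    message("multithreshold_roc: skipped single-class threshold(s) ",
            paste(format(skipped), collapse = ", "))
  list(auc_by_threshold = aucs,
       mean_auc = mean(aucs, na.rm = TRUE),
       skipped = skipped)
}

#' Unit-perturbation effect attribution
#'
#' Increases one feature by `delta` units in every row, holds everything
#' else fixed, and reports the change in mean prediction — for the linear
#' view this equals the feature's coefficient times `delta` exactly; for
#' the network it is a finite-difference attribution through the forward
#' pass.
#'
#' @param model A `qsmart_linear` or `qsmart_network`.
#' @param feature Feature name (must be in the model).
#' @param data Numeric matrix of rows to attribute over.
#' @param delta Perturbation size (default 1).
#' @return A list: `feature`, `baseline_mean`, `perturbed_mean`, `delta`
#'   (per-unit effect: mean difference divided by `delta`).
#' @export
perturb_effect <- function(model, feature, data, delta = 1) {
  if (!feature %in% model$features)
    stop("feature not in model: ", feature, call. = FALSE)
  base <- mean(stats::predict(model, data))
  pert_data <- data
  pert_data[, feature] <- pert_data[, feature] + delta
  pert <- mean(stats::predict(model, pert_data))
  list(feature = feature, baseline_mean = base, perturbed_mean = pert,
       delta = (pert - base) / delta)
}

#' Drug-mutation interaction analysis
#'
#' The same nested-model F-test as the interaction engine applied to one
#' fingerprint-bit / residue-feature pair, plus the group-mean response in
#' the four cells (bit 0/1 by residue feature positive vs non-positive)
#' for an interaction plot; non-parallel cell-mean lines indicate a
#' crossing interaction.
#'
#' @param responses Numeric log-IC50 vector.
#' @param fingerprint Numeric 0/1 fingerprint-bit column.
#' @param residue Numeric residue-feature column.
#' @return A list: `f_stat`, `p_value`, `cell_means` (data frame: `bit`,
#'   `residue_positive`, `mean_response`, `n`), `degenerate_cells`.
#' @export
interaction_analysis <- function(responses, fingerprint, residue) {
  ft <- ftest_term(responses, fingerprint, residue)
  cells <- expand.grid(bit = c(0, 1), residue_positive = c(FALSE, TRUE))
  cells$mean_response <- NA_real_
  cells$n <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- fingerprint == cells$bit[i] &
      (residue > 0) == cells$residue_positive[i]
    cells$n[i] <- sum(sel)
    if (any(sel)) cells$mean_response[i] <- mean(responses[sel])
  }
  degenerate <- cells$n == 0L
  if (any(degenerate))
    message("interaction_analysis: ", sum(degenerate), " empty cell(s)")
  list(f_stat = ft$f_stat, p_value = ft$p_value, cell_means = cells,
       degenerate_cells = sum(degenerate))
}

#' Signed PPI edge-impact table
#'
#' For every expression-weighted protein-protein interaction term in the
#' model, the unit-perturbation effect on predicted log-IC50 and a sign
#' class: `positive` / `negative` when the absolute effect reaches `cut`,
#' otherwise `weak positive` / `weak negative`.
#'
#' @param model A `qsmart_linear` or `qsmart_network` containing PPI terms.
#' @param ppi_terms Data frame with `term`, `component_a`, `component_b`
#'   (the retained PPI candidates).
#' @param data Numeric matrix of rows to attribute over.
#' @param cut Strong/weak absolute-effect cut (default 0.05).
#' @return Data frame: `gene_a`, `gene_b`, `term`, `delta`, `sign_class`.
#' @export
ppi_edge_impacts <- function(model, ppi_terms, data, cut = 0.05) {
  terms <- ppi_terms[ppi_terms$term %in% model$features, , drop = FALSE]
  if (!nrow(terms)) stop("model contains no PPI terms", call. = FALSE)
  delta <- vapply(terms$term, function(tm)
    perturb_effect(model, tm, data)$delta, numeric(1))
  cls <- ifelse(delta >= cut, "positive",
         ifelse(delta <= -cut, "negative",
         ifelse(delta >= 0, "weak positive", "weak negative")))
  data.frame(gene_a = sub("^EXP_", "", terms$component_a),
             gene_b = sub("^EXP_", "", terms$component_b),
             term = terms$term, delta = unname(delta),
             sign_class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare two model families by paired signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test on paired per-group scores (e.g.
#' per-cancer-type R-squared of two pipelines).
#'
#' @param scores_a,scores_b Equal-length paired numeric vectors (>= 6
#'   pairs).
#' @return A list: `p_value`, `statistic`, `note` (non-empty when all
#'   differences are zero, in which case `p_value = 1`).
#' @export
compare_models <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 6L)
  if (all(scores_a == scores_b))
    return(list(p_value = 1, statistic = NA_real_,
                note = "all paired differences are zero"))
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                            paired = TRUE,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic), note = "")
}
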