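# Pipeline orchestration: cohort assembly -> feature engineering ->
# interaction screening -> VIF screening -> Lasso-BIC selection -> network
# training -> evaluation, per cancer group.

level_of_entity <- function(annotations) {
  u <- unique(annotations[c("entity", "level")])
  stats::setNames(u$level, u$entity)
}

# build the per-group design matrix (main effects only) plus metadata
build_group_design <- function(responses, bundle, config) {
  cells_id <- sort(unique(responses$cell_line_id))

  ## drug block: VIF screen at drug level in priority order
  drug_cols <- setdiff(names(bundle$drugs),
                       c("drug_id", "molecular_weight", "action_labels",
                         "kinomescan_control"))
  dmat <- as.matrix(bundle$drugs[drug_cols])
  rownames(dmat) <- bundle$drugs$drug_id
  dmat <- dmat[rownames(dmat) %in% unique(responses$drug_id), ,
               drop = FALSE]
  dscreen <- vif_stepwise_screen(dmat, rank_drug_features(drug_cols),
                                 vif_max = config$vif_max)
  drug_kept <- dscreen$kept

  ## cell-line block
  resmat <- residue_delta_features(bundle$mutations, cells_id)
  roll <- rollup_features(bundle$mutations, bundle$annotations, cells_id,
                          expression = bundle$expression,
                          cnv = bundle$cnv)
  cellmat <- cbind(resmat, roll$values)
  cell_levels <- c(rep("residue", ncol(resmat)), roll$levels)

  ## co-expression screen among expression columns
  exp_cols <- colnames(cellmat)[startsWith(colnames(cellmat), "EXP_")]
  if (length(exp_cols) >= 2L) {
    escreen <- vif_stepwise_screen(cellmat[, exp_cols, drop = FALSE],
                                   exp_cols, vif_max = config$vif_max)
    drop_exp <- setdiff(exp_cols, escreen$kept)
    keep <- !colnames(cellmat) %in% drop_exp
    cell_levels <- cell_levels[keep]
    cellmat <- cellmat[, keep, drop = FALSE]
  } else {
    escreen <- NULL
  }

  ## response-level assembly
  key <- paste(responses$drug_id, responses$cell_line_id,
               responses$source_flag, sep = "|")
  values <- cbind(
    dmat[responses$drug_id, drug_kept, drop = FALSE],
    cellmat[responses$cell_line_id, , drop = FALSE],
    source_flag = responses$source_flag
  )
  rownames(values) <- key
  levels <- c(rep("drug", length(drug_kept)), cell_levels, "sample")

  ## drop uninformative (zero-variance) columns within the group
  keep <- apply(values, 2, stats::var) > 0
  values <- values[, keep, drop = FALSE]
  levels <- levels[keep]

  list(values = values, levels = levels, y = responses$log_ic50,
       drug_screen = dscreen, expression_screen = escreen)
}

build_group_interactions <- function(design, bundle, config) {
  cn <- colnames(design$values)
  fingerprints <- cn[grepl("^Fingerprint_\\d+$", cn) &
                       design$levels == "drug"]
  residues <- cn[design$levels == "residue"]
  expressed <- sub("^EXP_", "", cn[startsWith(cn, "EXP_")])
  lvl <- level_of_entity(bundle$annotations)
  cand <- rbind(
    build_drug_mutation_terms(fingerprints, residues),
    build_ppi_terms(bundle$ppi, bundle$kinases, expressed,
                    score_min = config$ppi_score_min),
    do.call(rbind, lapply(c(reaction = "reaction", pathway = "pathway",
                            go_process = "go"), function(ns) {
      ents <- cn[cn %in% names(lvl)[lvl == ns]]
      hier <- bundle$hierarchy[bundle$hierarchy$namespace == ns, ,
                               drop = FALSE]
      type <- c(reaction = "reaction", pathway = "pathway",
                go = "go_process")[[ns]]
      build_setlevel_terms(ents, hier, type = type)
    }))
  )
  stats <- test_interaction_terms(design$values, design$y, cand,
                                  min_nonzero = config$min_nonzero)
  filter_terms(stats, alpha = config$fdr_alpha,
               min_nonzero = config$min_nonzero)
}

fit_group <- function(responses, bundle, config, fit_network = TRUE) {
  design <- build_group_design(responses, bundle, config)
  stats <- build_group_interactions(design, bundle, config)
  retained <- stats[stats$kept, , drop = FALSE]
  values <- design$values
  meta <- data.frame(feature = colnames(values), level = design$levels,
                     component_a = NA_character_,
                     component_b = NA_character_,
                     stringsAsFactors = FALSE)
  if (nrow(retained)) {
    values <- cbind(values, interaction_values(design$values, retained))
    meta <- rbind(meta, data.frame(
      feature = retained$term, level = "interaction",
      component_a = retained$component_a,
      component_b = retained$component_b, stringsAsFactors = FALSE))
  }
  fm <- feature_matrix(values, meta)
  y <- design$y

  selection <- lasso_bic_select(fm$values, y)
  selected <- selection$selected
  # the selection's least-squares refit is the model's linear view
  linear <- qsmart_linear(selection$coefficients)

  network <- NULL; schedule <- NULL
  if (fit_network && length(selected)) {
    sched <- escalation_schedule(
      fm$values[, selected, drop = FALSE], y,
      threshold = config$performance_threshold, seed = config$seed,
      folds = config$cv_folds, lambda_grid = config$lambda_grid)
    network <- sched$model
    schedule <- sched
  }

  report <- NULL
  if (!is.null(network)) {
    pred <- stats::predict(network, fm$values)
    sc <- score(pred, y)
    roc <- suppressMessages(multithreshold_roc(pred, y))
    attr_tab <- data.frame(
      feature = selected,
      delta = vapply(selected, function(f)
        perturb_effect(linear, f, fm$values)$delta, numeric(1)),
      row.names = NULL)
    ppi_sel <- retained[retained$type == "ppi" &
                          retained$term %in% selected, , drop = FALSE]
    ppi_table <- if (nrow(ppi_sel))
      ppi_edge_impacts(linear, ppi_sel, fm$values,
                       cut = config$edge_impact_cut) else NULL
    report <- list(r2_full = sc$r2, rmse = sc$rmse,
                   mean_cv_r2 = network$mean_cv_r2,
                   auc_by_threshold = roc$auc_by_threshold,
                   mean_auc = roc$mean_auc,
                   schedule_passed = schedule$passed,
                   attributions = attr_tab, ppi_impacts = ppi_table)
  }

  list(features = fm, interaction_stats = stats, selection = selection,
       linear = linear, network = network, schedule = schedule,
       report = report,
       screening = list(drug = design$drug_screen,
                        expression = design$expression_screen))
}

#' Run the full prediction pipeline
#'
#' Executes every stage in order on an input bundle: kinase-inhibitor
#' classification, duplicate-assay merging, cell-line filtering,
#' cancer-group assignment, per-group feature engineering, interaction
#' screening, Lasso-BIC selection, network training under the escalation
#' schedule, and evaluation. Deterministic given the config seed; the
#' result embeds the seed and a config hash.
#'
#' @param bundle A `qsmart_bundle` (see [simulate_bundle()]) or a list
#'   with the same elements read from files.
#' @param config A [qsmart_config()].
#' @param fit_network Set `FALSE` to stop after feature selection (used
#'   for selection-stability analyses).
#' @return An object of class `qsmart_result`: `groups` (named list of
#'   per-group fits), `cohort` (filtering/merging reports), `config`,
#'   `config_hash`, `seed`.
#' @export
run_pipeline <- function(bundle, config = qsmart_config(),
                         fit_network = TRUE) {
  required <- c("responses", "drugs", "cells", "mutations", "expression",
                "annotations", "hierarchy", "ppi", "kinases")
  miss <- setdiff(required, names(bundle))
  if (length(miss))
    stop("bundle is missing component(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  responses <- bundle$responses
  # stage: kinase-inhibitor classification
  pki_drugs <- bundle$drugs$drug_id
  if (all(c("molecular_weight", "action_labels") %in%
          names(bundle$drugs))) {
    ks <- if ("kinomescan_control" %in% names(bundle$drugs))
      bundle$drugs$kinomescan_control else NA_real_
    is_pki <- classify_pki(bundle$drugs$molecular_weight,
                           bundle$drugs$action_labels, ks,
                           mw_max = config$mw_max,
                           kinomescan_max = config$kinomescan_max)
    pki_drugs <- bundle$drugs$drug_id[is_pki]
    responses <- responses[responses$drug_id %in% pki_drugs, ,
                           drop = FALSE]
  }
  # stage: duplicate-assay merging
  merged <- merge_duplicate_assays(responses,
                                   r_min = config$duplicate_r_min)
  responses <- merged$responses
  # stage: cell-line filtering
  filt <- filter_cell_lines(bundle$cells, responses, bundle$mutations)
  responses <- responses[responses$cell_line_id %in% filt$retained, ,
                         drop = FALSE]
  # stage: cancer-group assignment
  grp <- assign_cancer_groups(bundle$cells, responses,
                              config$min_group_responses)
  responses$cancer_group <- grp$group
  responses <- responses[!is.na(responses$cancer_group), , drop = FALSE]

  groups <- list()
  if (!nrow(responses)) {
    warning("no cancer group meets the minimum response count; ",
            "empty model set")
  } else {
    for (g in sort(unique(responses$cancer_group))) {
      sub <- responses[responses$cancer_group == g, , drop = FALSE]
      groups[[g]] <- fit_group(sub, bundle, config,
                               fit_network = fit_network)
    }
  }
  structure(list(
    groups = groups,
    cohort = list(pki_drugs = pki_drugs, merge_report = merged$report,
                  cell_filter = filt, group_sizes = grp$group_sizes,
                  excluded_groups = grp$excluded),
    config = config, config_hash = config_hash(config),
    seed = config$seed
  ), class = "qsmart_result")
}

#' @export
print.qsmart_result <- function(x, ...) {
  cat(sprintf("<qsmart_result> %d group model(s); seed %d; config %s\n",
              length(x$groups), x$seed, x$config_hash))
  for (g in names(x$groups)) {
    rep <- x$groups[[g]]$report
    if (is.null(rep)) {
      cat(sprintf("  %s: %d features selected (no network)\n", g,
                  length(x$groups[[g]]$selection$selected)))
    } else {
      cat(sprintf(
        "  %s: k = %d, mean CV R^2 = %.3f, RMSE = %.3f, mean AUC = %.3f\n",
        g, x$groups[[g]]$selection$k, rep$mean_cv_r2, rep$rmse,
        rep$mean_auc))
    }
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Writes the per-group evaluation metrics, selection summaries, and
#' provenance (seed, config hash) as a JSON artifact.
#'
#' @param result A `qsmart_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  out <- list(
    seed = result$seed, config_hash = result$config_hash,
    groups = lapply(result$groups, function(g) {
      c(list(selected = g$selection$selected,
             k = g$selection$k, bic = g$selection$bic),
        if (!is.null(g$report))
          list(r2_full = g$report$r2_full, rmse = g$report$rmse,
               mean_cv_r2 = g$report$mean_cv_r2,
               mean_auc = g$report$mean_auc,
               auc_by_threshold = as.list(g$report$auc_by_threshold)))
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
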