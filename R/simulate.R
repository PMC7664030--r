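# Synthetic input bundles with planted ground truth: every pipeline stage
# is testable end-to-end without external downloads.

#' Specification of a synthetic input bundle
#'
#' Describes a complete simulated screen: drugs with Bernoulli fingerprint
#' bits, cell lines with kinase mutations placed at reference-PKA
#' positions, log-normal expression, annotation maps with a small ontology
#' hierarchy, a scored PPI edge list, and responses generated from the
#' model's own linear form: intercept + planted main effects + a
#' source-flag batch effect + planted product-interaction effects +
#' Gaussian noise. The noise is sized from the realized signal so
#' the signal-to-noise ratio equals `snr` (unless `sigma` is given
#' explicitly). A collinear block (a descriptor defined as the sum of two
#' fingerprint bits and an expression column defined as the sum of two
#' genes) exercises the VIF screen.
#'
#' Defaults emulate a mid-sized cancer-group training set: 40 drugs x 50
#' cell lines = 2000 responses, five planted effects (two main effects,
#' the batch effect, one drug-mutation interaction, one PPI interaction),
#' and SNR 10.
#'
#' @param n_drugs,n_cell_lines,n_fingerprint_bits,n_genes,n_go_terms
#'   Bundle dimensions.
#' @param main_effects Named numeric vector of planted main-effect
#'   coefficients (feature names in pipeline convention, e.g.
#'   `Fingerprint_30`, `EXP_G01`).
#' @param interaction_effects Data frame with `type`, `component_a`,
#'   `component_b`, `coefficient`.
#' @param batch_effect Coefficient on the source flag.
#' @param intercept Baseline log-IC50.
#' @param snr Target signal-to-noise ratio (variance ratio).
#' @param sigma Optional explicit noise standard deviation; overrides
#'   `snr`.
#' @param seed Integer seed.
#' @return An object of class `qsmart_simspec`.
#' @export
simulation_spec <- function(n_drugs = 40L, n_cell_lines = 50L,
                            n_fingerprint_bits = 32L, n_genes = 20L,
                            n_go_terms = 8L,
                            main_effects = c(Fingerprint_30 = 2.0,
                                             EXP_G01 = 1.2),
                            interaction_effects = data.frame(
                              type = c("drug_mutation", "ppi"),
                              component_a = c("PKA_187_CHA", "EXP_G02"),
                              component_b = c("Fingerprint_12", "EXP_G03"),
                              coefficient = c(1.5, 0.6),
                              stringsAsFactors = FALSE),
                            batch_effect = 0.65,
                            intercept = 2.0,
                            snr = 10,
                            sigma = NULL,
                            seed = 1L) {
  spec <- list(n_drugs = as.integer(n_drugs),
               n_cell_lines = as.integer(n_cell_lines),
               n_fingerprint_bits = as.integer(n_fingerprint_bits),
               n_genes = as.integer(n_genes),
               n_go_terms = as.integer(n_go_terms),
               main_effects = main_effects,
               interaction_effects = interaction_effects,
               batch_effect = batch_effect, intercept = intercept,
               snr = snr, sigma = sigma, seed = as.integer(seed))
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be positive")
  # planted fingerprint bits must exist in the generated schema
  feats <- c(names(main_effects), interaction_effects$component_a,
             interaction_effects$component_b)
  bits <- as.integer(sub("^Fingerprint_", "",
                         grep("^Fingerprint_", feats, value = TRUE)))
  if (length(bits) && any(bits > n_fingerprint_bits))
    stop("planted fingerprint bit beyond n_fingerprint_bits", call. = FALSE)
  genes <- sub("^EXP_", "", grep("^EXP_", feats, value = TRUE))
  if (length(genes) &&
      !all(genes %in% sprintf("G%02d", seq_len(n_genes))))
    stop("planted expression gene beyond n_genes", call. = FALSE)
  structure(spec, class = "qsmart_simspec")
}

#' Simulate a complete input bundle
#'
#' Generates every table the pipeline consumes (responses, drug features,
#' mutation profiles, expression and copy number, annotation maps, an
#' ontology hierarchy, a scored PPI edge list, cell-line records) together
#' with a ground-truth record sufficient to recompute every response value
#' from the generated features. Deterministic given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `qsmart_bundle` with elements `responses`,
#'   `drugs`, `cells`, `mutations`, `expression`, `cnv`, `annotations`,
#'   `hierarchy`, `ppi`, `kinases`, `ground_truth`.
#' @export
simulate_bundle <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "qsmart_simspec"))
  withr::with_seed(spec$seed, simulate_bundle_impl(spec))
}

simulate_bundle_impl <- function(spec) {
  drugs_id <- sprintf("D%03d", seq_len(spec$n_drugs))
  cells_id <- sprintf("CL%03d", seq_len(spec$n_cell_lines))
  genes <- sprintf("G%02d", seq_len(spec$n_genes))
  kinases <- genes[seq_len(min(10L, spec$n_genes))]

  # drug block: Bernoulli fingerprint bits + one collinear descriptor
  fp <- matrix(stats::rbinom(spec$n_drugs * spec$n_fingerprint_bits, 1, 0.3),
               spec$n_drugs, spec$n_fingerprint_bits,
               dimnames = list(NULL,
                 paste0("Fingerprint_", seq_len(spec$n_fingerprint_bits))))
  drugs <- data.frame(drug_id = drugs_id, fp, check.names = FALSE)
  drugs$Desc_BitSum <- fp[, "Fingerprint_1"] + fp[, "Fingerprint_2"]
  drugs$molecular_weight <- round(stats::runif(spec$n_drugs, 300, 600), 1)
  drugs$action_labels <- "inhibitor"

  # expression: log-normal; last gene is a collinear sum of two others
  expr <- matrix(stats::rlnorm(spec$n_cell_lines * spec$n_genes,
                               meanlog = 0, sdlog = 1),
                 spec$n_cell_lines, spec$n_genes,
                 dimnames = list(cells_id, genes))
  if (spec$n_genes >= 6L)
    expr[, spec$n_genes] <- expr[, 4L] + expr[, 5L]
  cnv <- matrix(stats::rbinom(spec$n_cell_lines * spec$n_genes, 4, 0.5),
                spec$n_cell_lines, spec$n_genes,
                dimnames = list(cells_id, genes))

  # mutations: a charge-varying hot spot at PKA_187 plus background
  # substitutions at other mapped positions; a few unmapped rows
  charge_pairs <- matrix(c("L", "R", "E", "K", "K", "E", "L", "K",
                           "R", "L", "D", "R"), ncol = 2, byrow = TRUE)
  bg_positions <- c(10L, 30L, 57L, 121L, 162L)
  aa <- aa_properties()$residue
  rows <- list()
  for (cl in cells_id) {
    if (stats::runif(1) < 0.4) {
      pr <- charge_pairs[sample.int(nrow(charge_pairs), 1L), ]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line_id = cl, gene = sample(kinases, 1L),
        wt = pr[1], position = 187L, mut = pr[2],
        stringsAsFactors = FALSE)
    }
    n_bg <- stats::rpois(1, 1.5)
    for (b in seq_len(n_bg)) {
      pos <- if (stats::runif(1) < 0.05) NA_integer_
             else sample(bg_positions, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line_id = cl, gene = sample(genes, 1L),
        wt = sample(aa, 1L), position = pos, mut = sample(aa, 1L),
        stringsAsFactors = FALSE)
    }
  }
  mutations <- do.call(rbind, rows)

  # annotations: GO terms, one parent-child pair in the hierarchy, plus
  # motif/domain/family/reaction/pathway maps
  go_terms <- sprintf("GO_%07d", seq_len(spec$n_go_terms))
  ann <- list()
  for (g in genes) {
    ann[[length(ann) + 1L]] <- data.frame(
      gene = g, entity = sample(go_terms, sample(1:2, 1)), level = "go",
      stringsAsFactors = FALSE)
    ann[[length(ann) + 1L]] <- data.frame(
      gene = g,
      entity = c(sample(sprintf("MOT_%02d", 1:5), 1),
                 sample(sprintf("DOM_%02d", 1:5), 1),
                 sample(sprintf("FAM_%s", LETTERS[1:4]), 1),
                 sample(sprintf("REC_%02d", 1:4), 1),
                 sample(sprintf("PWY_%02d", 1:4), 1)),
      level = c("motif", "domain", "family", "reaction", "pathway"),
      stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann)
  hierarchy <- data.frame(child = go_terms[2], parent = go_terms[1],
                          namespace = "go", stringsAsFactors = FALSE)

  # PPI edges: planted high-score kinase edge + background edges spanning
  # the score threshold, plus a self edge the filter must reject
  bg_a <- sample(genes, 12L, replace = TRUE)
  bg_b <- sample(genes, 12L, replace = TRUE)
  ppi <- data.frame(
    protein1 = c("G02", bg_a, "G05"),
    protein2 = c("G03", bg_b, "G05"),
    combined_score = c(950, round(stats::runif(12, 400, 999)), 980),
    stringsAsFactors = FALSE)

  cells <- data.frame(cell_line_id = cells_id, wgs_flag = 1L,
                      has_expression = 1L, primary_site = "synthetic_site",
                      primary_histology = "synthetic",
                      histology_subtype = "", stringsAsFactors = FALSE)

  responses <- expand.grid(drug_id = drugs_id, cell_line_id = cells_id,
                           stringsAsFactors = FALSE)
  responses$source_flag <- stats::rbinom(nrow(responses), 1, 0.5)

  # signal: the model's own linear form evaluated on the generated features
  resmat <- suppressMessages(
    residue_delta_features(mutations, cells_id))
  feat_value <- function(name) {
    if (grepl("^Fingerprint_", name))
      return(drugs[[name]][match(responses$drug_id, drugs$drug_id)])
    if (grepl("^EXP_", name))
      return(expr[responses$cell_line_id, sub("^EXP_", "", name)])
    if (name %in% colnames(resmat))
      return(resmat[responses$cell_line_id, name])
    stop("planted component absent from generated schema: ", name,
         call. = FALSE)
  }
  signal <- rep(spec$intercept, nrow(responses)) +
    spec$batch_effect * responses$source_flag
  for (nm in names(spec$main_effects))
    signal <- signal + spec$main_effects[[nm]] * feat_value(nm)
  planted_int <- spec$interaction_effects
  int_names <- character(0)
  if (nrow(planted_int)) {
    for (i in seq_len(nrow(planted_int))) {
      v <- feat_value(planted_int$component_a[i]) *
        feat_value(planted_int$component_b[i])
      signal <- signal + planted_int$coefficient[i] * v
    }
    int_names <- paste0(planted_int$component_a, "_X_",
                        planted_int$component_b)
  }
  signal <- unname(signal)
  sigma <- if (!is.null(spec$sigma)) spec$sigma
           else stats::sd(signal) / sqrt(spec$snr)
  responses$log_ic50 <- signal + stats::rnorm(nrow(responses), 0, sigma)

  planted <- data.frame(
    feature = c(names(spec$main_effects), "source_flag", int_names),
    coefficient = c(unname(spec$main_effects), spec$batch_effect,
                    planted_int$coefficient),
    type = c(rep("main", length(spec$main_effects)), "batch",
             planted_int$type),
    stringsAsFactors = FALSE)

  structure(list(
    responses = responses, drugs = drugs, cells = cells,
    mutations = mutations, expression = expr, cnv = cnv,
    annotations = annotations, hierarchy = hierarchy, ppi = ppi,
    kinases = kinases,
    ground_truth = list(planted = planted, intercept = spec$intercept,
                        sigma = sigma, signal = signal, seed = spec$seed)
  ), class = "qsmart_bundle")
}

#' Parameter-recovery harness
#'
#' Simulates a bundle, runs the full pipeline, and compares the selected
#' support and linear-view coefficients against the planted ground truth.
#'
#' @param spec A [simulation_spec()].
#' @param config A [qsmart_config()].
#' @return A list: `recall`, `precision`, `sign_agreement`,
#'   `coefficient_rmse` (over recovered features), `mean_cv_r2`,
#'   `selected`, `planted`.
#' @export
recovery_harness <- function(spec = simulation_spec(),
                             config = qsmart_config(seed = spec$seed)) {
  bundle <- simulate_bundle(spec)
  res <- run_pipeline(bundle, config)
  if (!length(res$groups)) {
    return(list(recall = NA_real_, precision = NA_real_,
                sign_agreement = NA_real_, coefficient_rmse = NA_real_,
                mean_cv_r2 = NA_real_, selected = character(0),
                planted = bundle$ground_truth$planted))
  }
  g <- res$groups[[1]]
  planted <- bundle$ground_truth$planted
  selected <- g$selection$selected
  hit <- planted$feature %in% selected
  recall <- mean(hit)
  precision <- if (length(selected))
    sum(selected %in% planted$feature) / length(selected) else NA_real_
  beta <- g$linear$beta
  rec <- planted[hit, , drop = FALSE]
  sign_agreement <- if (nrow(rec))
    mean(sign(beta[rec$feature]) == sign(rec$coefficient)) else NA_real_
  coefficient_rmse <- if (nrow(rec))
    sqrt(mean((beta[rec$feature] - rec$coefficient)^2)) else NA_real_
  list(recall = recall, precision = precision,
       sign_agreement = sign_agreement,
       coefficient_rmse = coefficient_rmse,
       mean_cv_r2 = if (!is.null(g$network)) g$network$mean_cv_r2
                    else NA_real_,
       selected = selected, planted = planted)
}

#' Feature-selection stability under sample reduction
#'
#' Runs feature selection on the full bundle and on a seeded random
#' subsample (default 90% of responses) and reports the fraction of
#' full-set features re-selected in the reduced set.
#'
#' @param bundle A `qsmart_bundle`.
#' @param config A [qsmart_config()].
#' @param fraction Fraction of responses retained (default 0.9).
#' @param seed Subsampling seed (defaults to the config seed).
#' @return A list: `overlap`, `full_selected`, `reduced_selected`.
#' @export
reduced_training_check <- function(bundle, config = qsmart_config(),
                                   fraction = 0.9, seed = config$seed) {
  full <- run_pipeline(bundle, config, fit_network = FALSE)
  sub_bundle <- bundle
  n <- nrow(bundle$responses)
  keep <- withr::with_seed(seed,
                           sort(sample.int(n, floor(fraction * n))))
  sub_bundle$responses <- bundle$responses[keep, , drop = FALSE]
  reduced <- run_pipeline(sub_bundle, config, fit_network = FALSE)
  fs <- if (length(full$groups)) full$groups[[1]]$selection$selected
        else character(0)
  rs <- if (length(reduced$groups)) reduced$groups[[1]]$selection$selected
        else character(0)
  overlap <- if (length(fs)) mean(fs %in% rs) else NA_real_
  list(overlap = overlap, full_selected = fs, reduced_selected = rs)
}
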