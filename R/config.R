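#' Pipeline configuration
#'
#' Bundles every tunable threshold of the modeling pipeline in one validated
#' object. Defaults follow standard practice for kinase-inhibitor response
#' modeling on GDSC-style data: interaction terms are retained at FDR < 0.05
#' with at least 30 non-zero supporting values, features are screened at
#' VIF <= 5, inhibitors are small molecules under 900 Da, STRING edges are
#' trusted above a combined score of 700, duplicate-assay drugs are merged
#' only when their cross-source Pearson r exceeds 0.7, cancer groups need at
#' least 1000 responses, and network training escalates while mean
#' cross-validated R-squared stays below 0.8.
#'
#' @param fdr_alpha False-discovery-rate cutoff for interaction terms.
#' @param min_nonzero Minimum number of non-zero values an interaction term
#'   must have to be retained.
#' @param vif_max Maximum tolerated variance inflation factor.
#' @param ppi_score_min Minimum STRING combined score (exclusive) for a
#'   protein-protein interaction edge.
#' @param duplicate_r_min Minimum cross-source Pearson correlation
#'   (exclusive) for merging a duplicate-assayed drug.
#' @param min_group_responses Minimum responses per cancer group.
#' @param performance_threshold Mean cross-validated R-squared at which the
#'   network escalation schedule stops.
#' @param mw_max Maximum molecular weight (Da, exclusive) for a small-molecule
#'   kinase inhibitor.
#' @param kinomescan_max KINOMEscan percent-of-control (exclusive) below which
#'   a compound qualifies as an inhibitor absent curated action labels.
#' @param cv_folds Number of cross-validation folds.
#' @param lambda_grid L1 penalty grid searched per fold during network
#'   training.
#' @param edge_impact_cut Absolute unit-perturbation effect separating strong
#'   from weak protein-protein-interaction edge impacts.
#' @param seed Integer seed recorded in every derived artifact.
#'
#' @return An object of class `qsmart_config` (a named list).
#' @examples
#' cfg <- qsmart_config(seed = 7)
#' cfg$vif_max
#' @export
qsmart_config <- function(fdr_alpha = 0.05,
                          min_nonzero = 30L,
                          vif_max = 5,
                          ppi_score_min = 700,
                          duplicate_r_min = 0.7,
                          min_group_responses = 1000L,
                          performance_threshold = 0.8,
                          mw_max = 900,
                          kinomescan_max = 5,
                          cv_folds = 10L,
                          lambda_grid = 10^c(-4, -3, -2),
                          edge_impact_cut = 0.05,
                          seed = 1L) {
  cfg <- list(
    fdr_alpha = fdr_alpha, min_nonzero = as.integer(min_nonzero),
    vif_max = vif_max, ppi_score_min = ppi_score_min,
    duplicate_r_min = duplicate_r_min,
    min_group_responses = as.integer(min_group_responses),
    performance_threshold = performance_threshold, mw_max = mw_max,
    kinomescan_max = kinomescan_max, cv_folds = as.integer(cv_folds),
    lambda_grid = lambda_grid, edge_impact_cut = edge_impact_cut,
    seed = as.integer(seed)
  )
  num <- c("fdr_alpha", "min_nonzero", "vif_max", "ppi_score_min",
           "duplicate_r_min", "min_group_responses", "performance_threshold",
           "mw_max", "kinomescan_max", "cv_folds", "edge_impact_cut")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (any(cfg$lambda_grid <= 0)) stop("lambda_grid must be positive")
  if (is.na(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "qsmart_config")
}

#' @export
print.qsmart_config <- function(x, ...) {
  cat("<qsmart_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# Stable hash of a config (recorded in output artifacts alongside the seed).
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "qsmart_config"))
  txt <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), sep = "=",
    collapse = ";")
  # 31-ary polynomial rolling hash mod 2^31; dependency-free and stable
  h <- 7
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
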