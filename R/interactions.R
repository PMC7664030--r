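# Interaction engine: construct candidate product terms of five classes
# (drug x mutation, expression-weighted PPI, reaction, pathway, GO process),
# test each individually by a nested-model F-test, and filter under FDR
# control with a minimum-support rule.

#' Candidate drug-by-mutation interaction terms
#'
#' Only residue-level features — the mutation status projected onto the
#' reference PKA structure — form interactions with drugs, and only with
#' substructure fingerprint bits; products of drugs with higher-level
#' cell-line features are not biologically interpretable and are never
#' generated. Names follow `<residue>_X_<fingerprint>`, e.g.
#' `PKA_187_CHA_X_Fingerprint_791`.
#'
#' @param fingerprints Character vector of fingerprint column names.
#' @param residue_features Character vector of residue-level column names.
#' @return Data frame of candidates: `term`, `type`, `component_a`,
#'   `component_b`.
#' @export
build_drug_mutation_terms <- function(fingerprints, residue_features) {
  if (!length(fingerprints) || !length(residue_features))
    return(empty_candidates())
  grid <- expand.grid(component_b = fingerprints,
                      component_a = residue_features,
                      stringsAsFactors = FALSE)
  data.frame(term = paste0(grid$component_a, "_X_", grid$component_b),
             type = "drug_mutation",
             component_a = grid$component_a,
             component_b = grid$component_b,
             stringsAsFactors = FALSE)
}

empty_candidates <- function() {
  data.frame(term = character(), type = character(),
             component_a = character(), component_b = character(),
             stringsAsFactors = FALSE)
}

#' Candidate expression-weighted protein-protein interaction terms
#'
#' Retains non-self STRING edges with combined score strictly above
#' `score_min` where at least one endpoint is a human protein kinase and
#' both endpoints have expression columns in the design. The term value is
#' the product of the two genes' expression levels, so the feature tracks
#' the abundance of the putative complex per cell line. Gene pairs are
#' ordered alphabetically for a canonical commutative name
#' `EXP_<A>_X_EXP_<B>`.
#'
#' @param edges Data frame with `protein1`, `protein2`, `combined_score`.
#' @param kinases Character vector of kinase gene symbols.
#' @param expressed_genes Genes with an expression column available; edges
#'   touching other genes are skipped.
#' @param score_min Score threshold (exclusive, default 700).
#' @return Candidate data frame as in [build_drug_mutation_terms()].
#' @export
build_ppi_terms <- function(edges, kinases, expressed_genes,
                            score_min = 700) {
  keep <- edges$combined_score > score_min &
    edges$protein1 != edges$protein2 &
    (edges$protein1 %in% kinases | edges$protein2 %in% kinases) &
    edges$protein1 %in% expressed_genes &
    edges$protein2 %in% expressed_genes
  e <- edges[keep, , drop = FALSE]
  if (!nrow(e)) return(empty_candidates())
  a <- pmin(e$protein1, e$protein2)
  b <- pmax(e$protein1, e$protein2)
  dup <- duplicated(paste(a, b))
  a <- a[!dup]; b <- b[!dup]
  data.frame(term = paste0("EXP_", a, "_X_EXP_", b),
             type = "ppi",
             component_a = paste0("EXP_", a),
             component_b = paste0("EXP_", b),
             stringsAsFactors = FALSE)
}

# all ancestor sets under a parent edge list (transitive closure);
# errors on cycles, naming one offending node
hierarchy_ancestors <- function(edges) {
  if (!nrow(edges)) return(list())
  g <- igraph::graph_from_data_frame(edges[c("child", "parent")])
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    stop("cycle in hierarchy involving: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  nodes <- igraph::V(g)$name
  anc <- lapply(nodes, function(v)
    setdiff(names(igraph::subcomponent(g, v, mode = "out")), v))
  stats::setNames(anc, nodes)
}

#' Candidate reaction/pathway/GO pairwise interaction terms
#'
#' Products of pairs of same-level perturbation-count features, excluding
#' pairs where one entity is an ancestor of the other anywhere in the
#' ontology hierarchy (transitive closure): the product of a term with its
#' own generalization, e.g. "lung cell differentiation" (GO:0060479) with
#' its parent "lung development" (GO:0030324), explains nothing beyond the
#' child count itself.
#'
#' @param entities Character vector of same-level entity feature names.
#' @param hierarchy Data frame with `child`, `parent` edges for this
#'   namespace (may be empty).
#' @param type Term type label: `"reaction"`, `"pathway"`, or
#'   `"go_process"`.
#' @return Candidate data frame as in [build_drug_mutation_terms()].
#' @export
build_setlevel_terms <- function(entities, hierarchy,
                                 type = "go_process") {
  entities <- sort(unique(entities))
  if (length(entities) < 2L) return(empty_candidates())
  anc <- hierarchy_ancestors(hierarchy)
  pairs <- utils::combn(entities, 2L)
  related <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    b %in% anc[[a]] || a %in% anc[[b]]
  }, logical(1))
  pairs <- pairs[, !related, drop = FALSE]
  if (!ncol(pairs)) return(empty_candidates())
  data.frame(term = paste0(pairs[1, ], "_X_", pairs[2, ]),
             type = type,
             component_a = pairs[1, ],
             component_b = pairs[2, ],
             stringsAsFactors = FALSE)
}

#' Nested-model F-test for one interaction term
#'
#' Tests whether the product `a * b` explains response variance beyond the
#' two main effects: full model `y ~ a + b + a:b`, reduced `y ~ a + b`,
#' F = ((RSS_reduced - RSS_full) / 1) / (RSS_full / (n - 4)), with the
#' p-value from F(1, n - 4). Returns `NA` statistics when the product is
#' constant or linearly dependent on the main effects.
#'
#' @param y Numeric response vector.
#' @param a,b Numeric component columns.
#' @return A list: `f_stat`, `p_value`, `df1`, `df2`.
#' @export
ftest_term <- function(y, a, b) {
  n <- length(y)
  stopifnot(length(a) == n, length(b) == n)
  ab <- a * b
  if (n <= 4L || stats::var(ab) == 0)
    return(list(f_stat = NA_real_, p_value = NA_real_, df1 = 1L,
                df2 = n - 4L))
  Xr <- cbind(1, a, b)
  Xf <- cbind(Xr, ab)
  fit_f <- stats::.lm.fit(Xf, y)
  if (fit_f$rank < 4L)
    return(list(f_stat = NA_real_, p_value = NA_real_, df1 = 1L,
                df2 = n - 4L))
  rss_f <- sum(fit_f$residuals^2)
  rss_r <- sum(stats::.lm.fit(Xr, y)$residuals^2)
  df2 <- n - 4L
  f <- (rss_r - rss_f) / (rss_f / df2)
  list(f_stat = f, p_value = stats::pf(f, 1, df2, lower.tail = FALSE),
       df1 = 1L, df2 = df2)
}

#' Test a candidate set of interaction terms
#'
#' Computes each candidate's product column against the design, skips terms
#' with fewer than `min_nonzero` non-zero values before testing (they could
#' never survive the support filter), and F-tests the rest individually
#' with [ftest_term()].
#'
#' @param design Numeric matrix of main-effect columns (rows = responses).
#' @param y Numeric response vector.
#' @param candidates Candidate data frame from the `build_*_terms`
#'   functions.
#' @param min_nonzero Support threshold used for pre-skipping (default 30).
#' @return A data frame: `term`, `type`, `component_a`, `component_b`,
#'   `nonzero_count`, `f_stat`, `p_value`, `tested` (logical), `reason`
#'   (why an untested term was skipped).
#' @export
test_interaction_terms <- function(design, y, candidates,
                                   min_nonzero = 30L) {
  n <- nrow(design)
  out <- candidates
  out$nonzero_count <- NA_integer_
  out$f_stat <- NA_real_
  out$p_value <- NA_real_
  out$tested <- FALSE
  out$reason <- ""
  for (i in seq_len(nrow(candidates))) {
    a <- design[, candidates$component_a[i]]
    b <- design[, candidates$component_b[i]]
    v <- a * b
    nz <- sum(v != 0)
    out$nonzero_count[i] <- nz
    if (nz < min_nonzero) {
      out$reason[i] <- "below min_nonzero"
      next
    }
    ft <- ftest_term(y, a, b)
    if (is.na(ft$p_value)) {
      out$reason[i] <- "degenerate term"
      next
    }
    out$f_stat[i] <- ft$f_stat
    out$p_value[i] <- ft$p_value
    out$tested[i] <- TRUE
  }
  out
}

#' Filter tested interaction terms
#'
#' Benjamini-Hochberg adjustment across all tested terms of a cancer group,
#' then retention of terms with adjusted FDR below `alpha` and at least
#' `min_nonzero` non-zero values.
#'
#' @param stats Output of [test_interaction_terms()].
#' @param alpha FDR level (default 0.05).
#' @param min_nonzero Minimum non-zero support (default 30).
#' @return `stats` with columns `fdr_q` and `kept` added.
#' @export
filter_terms <- function(stats, alpha = 0.05, min_nonzero = 30L) {
  stats$fdr_q <- NA_real_
  tested <- which(stats$tested)
  stats$fdr_q[tested] <- stats::p.adjust(stats$p_value[tested],
                                         method = "BH")
  stats$kept <- !is.na(stats$fdr_q) & stats$fdr_q < alpha &
    stats$nonzero_count >= min_nonzero
  stats
}

# product columns for a set of (retained) candidate rows
interaction_values <- function(design, candidates) {
  v <- design[, candidates$component_a, drop = FALSE] *
    design[, candidates$component_b, drop = FALSE]
  colnames(v) <- candidates$term
  v
}
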