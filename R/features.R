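# Feature engineering: the drug feature block and the seven-level
# multi-omics cell-line feature block of the design matrix.

residue_props <- c(CHA = "charge", POL = "polarity", HYD = "hydrophobicity",
                   ASA = "asa", VOL = "volume", ENE = "energy")

#' Residue-level mutation features
#'
#' For every mutated reference-PKA position carried by a cell line, eight
#' feature columns `PKA_<pos>_<PROP>` quantify the structural perturbation:
#' `MUT` counts mutations at the position; `CHA`, `POL`, `HYD`, `ASA`,
#' `VOL`, `ENE` sum the mutant-minus-wild-type property deltas (charge,
#' polarity class, hydrophobicity, accessible surface area, side-chain
#' volume, transfer energy); `BLO` sums the BLOSUM62 score of each
#' substitution. Multiple mutations at one position accumulate additively.
#' Mutations without a mapped PKA position or with a non-canonical residue
#' letter are skipped with a message.
#'
#' @param mutations Data frame with `cell_line_id`, `wt`, `position`, `mut`
#'   (one-letter residue codes; `position` is the reference-PKA position or
#'   `NA` when unmapped).
#' @param cell_lines Character vector fixing the row universe (cell lines
#'   with no usable mutation get all-zero rows).
#' @param props Property table from [aa_properties()].
#' @return Numeric matrix, rows = `cell_lines`, columns =
#'   `PKA_<pos>_<PROP>` sorted by position then property.
#' @examples
#' m <- data.frame(cell_line_id = "H3255", wt = "L", position = 187L,
#'                 mut = "R")
#' residue_delta_features(m, "H3255")[, "PKA_187_CHA"]  # +1
#' @export
residue_delta_features <- function(mutations, cell_lines,
                                   props = aa_properties()) {
  aa <- props$residue
  usable <- !is.na(mutations$position) &
    mutations$wt %in% aa & mutations$mut %in% aa
  n_skip <- sum(!usable)
  if (n_skip > 0)
    message("residue_delta_features: skipped ", n_skip,
            " unmapped or non-canonical mutation(s)")
  mut <- mutations[usable, , drop = FALSE]
  positions <- sort(unique(mut$position))
  prop_codes <- c("MUT", names(residue_props), "BLO")
  cols <- as.vector(t(outer(positions, prop_codes,
                            function(p, s) paste0("PKA_", p, "_", s))))
  out <- matrix(0, length(cell_lines), length(cols),
                dimnames = list(cell_lines, cols))
  if (nrow(mut) == 0L) return(out)
  blo <- blosum62()
  ri <- match(mut$cell_line_id, cell_lines)
  ok <- !is.na(ri)
  mut <- mut[ok, , drop = FALSE]; ri <- ri[ok]
  for (k in seq_len(nrow(mut))) {
    p <- mut$position[k]
    add <- function(code, v) {
      cn <- paste0("PKA_", p, "_", code)
      out[ri[k], cn] <<- out[ri[k], cn] + v
    }
    add("MUT", 1)
    for (code in names(residue_props)) {
      pr <- residue_props[[code]]
      add(code, props[mut$mut[k], pr] - props[mut$wt[k], pr])
    }
    add("BLO", blo[mut$wt[k], mut$mut[k]])
  }
  out
}

#' Annotation roll-up count features
#'
#' Per annotation entity (motif, domain, kinase family/group, reaction,
#' pathway, or Gene Ontology biological process), the feature value for a
#' cell line is the number of its kinase mutations in genes annotated to
#' that entity — the count of mutations perturbing the entity. Gene-level
#' features add the per-gene mutation count plus expression and copy-number
#' passthrough columns (missing values zero-filled with a message).
#'
#' @param mutations Data frame with `cell_line_id` and `gene`.
#' @param annotations Data frame with `gene`, `entity`, `level`; `level`
#'   one of `motif`, `domain`, `family`, `reaction`, `pathway`, `go`.
#' @param cell_lines Character vector fixing the row universe.
#' @param expression,cnv Optional numeric matrices (cell lines x genes) for
#'   gene-level passthrough columns `EXP_<gene>` / `CNV_<gene>`.
#' @return A list: `values` (numeric matrix, rows = `cell_lines`) and
#'   `levels` (character vector tagging each column's feature level).
#' @export
rollup_features <- function(mutations, annotations, cell_lines,
                            expression = NULL, cnv = NULL) {
  level_tag <- c(motif = "motif", domain = "domain", family = "family",
                 reaction = "pathway", pathway = "pathway", go = "pathway")
  bad <- setdiff(unique(annotations$level), names(level_tag))
  if (length(bad))
    stop("unknown annotation level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  blocks <- list(); levels <- character()
  # entity counts: one column per entity, mutations in annotated genes
  ann_split <- split(annotations, annotations$entity)
  ents <- names(ann_split)
  if (length(ents)) {
    cnt <- matrix(0, length(cell_lines), length(ents),
                  dimnames = list(cell_lines, ents))
    mut_tab <- table(factor(mutations$cell_line_id, levels = cell_lines),
                     mutations$gene)
    for (e in ents) {
      genes <- intersect(unique(ann_split[[e]]$gene), colnames(mut_tab))
      if (length(genes))
        cnt[, e] <- rowSums(mut_tab[, genes, drop = FALSE])
    }
    blocks$counts <- cnt
    levels <- c(levels, unname(level_tag[vapply(ann_split, function(a)
      a$level[1], "")]))
  }
  # gene level: mutation count per gene + expression/CNV passthrough
  genes <- sort(unique(mutations$gene))
  if (length(genes)) {
    gm <- table(factor(mutations$cell_line_id, levels = cell_lines),
                factor(mutations$gene, levels = genes))
    gm <- matrix(as.numeric(gm), nrow(gm), ncol(gm),
                 dimnames = list(cell_lines, paste0("MUTCOUNT_", genes)))
    blocks$genemut <- gm
    levels <- c(levels, rep("gene", ncol(gm)))
  }
  for (nm in c("expression", "cnv")) {
    m <- if (nm == "expression") expression else cnv
    if (is.null(m)) next
    pre <- if (nm == "expression") "EXP_" else "CNV_"
    full <- matrix(0, length(cell_lines), ncol(m),
                   dimnames = list(cell_lines, paste0(pre, colnames(m))))
    hit <- intersect(cell_lines, rownames(m))
    full[hit, ] <- m[hit, , drop = FALSE]
    if (anyNA(full)) {
      message("rollup_features: zero-filled ", sum(is.na(full)),
              " missing ", nm, " value(s)")
      full[is.na(full)] <- 0
    }
    if (length(hit) < length(cell_lines))
      message("rollup_features: zero-filled ", nm, " for ",
              length(cell_lines) - length(hit), " absent cell line(s)")
    blocks[[nm]] <- full
    levels <- c(levels, rep("gene", ncol(full)))
  }
  values <- do.call(cbind, blocks)
  if (is.null(values))
    values <- matrix(numeric(0), length(cell_lines), 0,
                     dimnames = list(cell_lines, NULL))
  list(values = values, levels = levels)
}

#' Dummy-code categorical sample-level columns
#'
#' Each k-level categorical becomes k-1 binary indicator columns with the
#' lexicographically first level as the reference; single-level columns are
#' dropped with a message. The level-to-column mapping is returned so the
#' coding is invertible.
#'
#' @param df Data frame of character/factor columns.
#' @return A list: `values` (numeric indicator matrix named
#'   `<column>.<level>`), `mapping` (per input column: ordered levels, the
#'   first being the reference).
#' @export
dummy_code <- function(df) {
  mats <- list(); mapping <- list()
  for (cl in names(df)) {
    lev <- sort(unique(as.character(df[[cl]])))
    if (length(lev) < 2L) {
      message("dummy_code: dropped single-level column '", cl, "'")
      next
    }
    f <- factor(as.character(df[[cl]]), levels = lev)
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(cl, ".", lev[-1])
    rownames(mm) <- rownames(df)
    mats[[cl]] <- mm
    mapping[[cl]] <- lev
  }
  values <- do.call(cbind, mats)
  if (is.null(values))
    values <- matrix(numeric(0), nrow(df), 0)
  list(values = values, mapping = mapping)
}

#' Recover categorical labels from dummy-coded columns
#'
#' Inverse of [dummy_code()] for one column.
#'
#' @param values Indicator matrix from [dummy_code()].
#' @param mapping The `mapping` entry for the column.
#' @param column Column name used at coding time.
#' @return Character vector of original labels.
#' @export
dummy_decode <- function(values, mapping, column) {
  cols <- paste0(column, ".", mapping[-1])
  sub <- values[, cols, drop = FALSE]
  idx <- apply(sub, 1, function(r) {
    j <- which(r == 1)
    if (length(j) == 0L) 0L else j
  })
  mapping[idx + 1L]
}

#' Priority order for drug features
#'
#' Under collinearity screening, substructure fingerprints outrank computed
#' chemical descriptors (a fingerprint bit maps to one substructure, so it
#' stays interpretable in interaction terms), and later fingerprint bit
#' positions (complex patterns) outrank earlier ones (simple element
#' counts). Descriptors keep their input order.
#'
#' @param feature_names Character vector of drug feature names; fingerprint
#'   bits must be named `Fingerprint_<bit>`.
#' @return `feature_names` reordered from highest to lowest priority.
#' @examples
#' rank_drug_features(c("Fingerprint_10", "Fingerprint_800", "ALogP"))
#' @export
rank_drug_features <- function(feature_names) {
  bit <- suppressWarnings(
    as.integer(sub("^Fingerprint_(\\d+)$", "\\1", feature_names)))
  is_fp <- grepl("^Fingerprint_\\d+$", feature_names)
  fp <- feature_names[is_fp][order(bit[is_fp], decreasing = TRUE)]
  c(fp, feature_names[!is_fp])
}
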