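# Cohort assembly: define small-molecule kinase inhibitors, merge duplicate
# assays across the two contributing centers, filter cell lines, and split
# responses into cancer-type-centric groups.

# canonical form for site/histology strings: lowercase, non-alnum -> "_"
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Classify a compound as a protein kinase inhibitor
#'
#' A compound qualifies as a small-molecule protein kinase inhibitor (PKI)
#' when its molecular weight is below 900 Da and either a curated
#' drug-kinase association labels it an inhibitor, antagonist, or
#' suppressor, or its KINOMEscan percent-of-control is below 5.
#'
#' @param molecular_weight Numeric vector of molecular weights (Da).
#' @param action_labels Character vector; each element the compound's
#'   curated action labels separated by `";"` (empty string for none).
#' @param kinomescan_control Numeric vector of KINOMEscan percent-of-control
#'   values; `NA` when unassayed.
#' @param mw_max,kinomescan_max Thresholds (exclusive); defaults 900 and 5.
#' @return Logical vector.
#' @examples
#' classify_pki(500, "inhibitor")              # TRUE
#' classify_pki(901, "inhibitor")              # FALSE: too heavy
#' classify_pki(500, "", kinomescan_control = 4.9)  # TRUE
#' @export
classify_pki <- function(molecular_weight, action_labels,
                         kinomescan_control = NA_real_,
                         mw_max = 900, kinomescan_max = 5) {
  n <- max(length(molecular_weight), length(action_labels),
           length(kinomescan_control))
  molecular_weight <- rep_len(molecular_weight, n)
  action_labels <- rep_len(action_labels, n)
  kinomescan_control <- rep_len(kinomescan_control, n)
  if (any(molecular_weight <= 0, na.rm = TRUE))
    stop("molecular weight must be positive", call. = FALSE)
  pki_labels <- c("inhibitor", "antagonist", "suppressor")
  has_label <- vapply(strsplit(tolower(action_labels), ";", fixed = TRUE),
                      function(l) any(trimws(l) %in% pki_labels), logical(1))
  low_control <- !is.na(kinomescan_control) &
    kinomescan_control < kinomescan_max
  molecular_weight < mw_max & (has_label | low_control)
}

#' Merge duplicate-assayed drugs across sources
#'
#' Some drugs were assayed by both contributing centers, yielding two
#' responses per (drug, cell line) pair. Per duplicate drug the Pearson
#' correlation of its paired log-IC50 values is computed across shared cell
#' lines; drugs correlating above `r_min` have each pair merged by a
#' weighted mean (weights from a `weight` column when present, otherwise
#' equal), while poorly correlated drugs are excluded entirely. Merged rows
#' carry the source flag of the higher-weight measurement (the Wellcome
#' Sanger assay on ties). The operation is idempotent.
#'
#' @param responses Data frame with `drug_id`, `cell_line_id`, `log_ic50`,
#'   `source_flag` and optionally `weight` (replicate count).
#' @param r_min Pearson correlation threshold (exclusive, default 0.7).
#' @return A list: `responses` (merged data frame), `report` (one row per
#'   duplicate drug: `drug_id`, `n_shared`, `r`, `action` of "merged" or
#'   "excluded", `reason`).
#' @export
merge_duplicate_assays <- function(responses, r_min = 0.7) {
  stopifnot(all(c("drug_id", "cell_line_id", "log_ic50", "source_flag")
                %in% names(responses)))
  w <- if ("weight" %in% names(responses)) responses$weight
       else rep(1, nrow(responses))
  key <- paste(responses$drug_id, responses$cell_line_id, sep = "\r")
  dup_pairs <- key[duplicated(key)]
  dup_drugs <- unique(responses$drug_id[key %in% dup_pairs])
  report <- data.frame(drug_id = character(), n_shared = integer(),
                       r = numeric(), action = character(),
                       reason = character(), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(responses))
  merged_rows <- list()
  for (d in dup_drugs) {
    idx <- which(responses$drug_id == d)
    sub <- responses[idx, ]
    shared <- names(which(table(sub$cell_line_id) >= 2L))
    if (length(shared) < 3L) {
      keep[idx] <- FALSE
      report <- rbind(report, data.frame(
        drug_id = d, n_shared = length(shared), r = NA_real_,
        action = "excluded", reason = "insufficient overlap"))
      next
    }
    a <- sub[sub$source_flag == 1 & sub$cell_line_id %in% shared, ]
    b <- sub[sub$source_flag == 0 & sub$cell_line_id %in% shared, ]
    a <- a[!duplicated(a$cell_line_id), ]
    b <- b[!duplicated(b$cell_line_id), ]
    b <- b[match(a$cell_line_id, b$cell_line_id), ]
    r <- stats::cor(a$log_ic50, b$log_ic50)
    if (is.na(r) || r <= r_min) {
      keep[idx] <- FALSE
      report <- rbind(report, data.frame(
        drug_id = d, n_shared = length(shared), r = r, action = "excluded",
        reason = sprintf("cross-source r <= %.2f", r_min)))
      next
    }
    # merge each duplicated pair by weighted mean
    for (cl in shared) {
      j <- idx[responses$cell_line_id[idx] == cl]
      wj <- w[j]
      row <- responses[j[which.max(wj + 1e-9 * responses$source_flag[j])], ]
      row$log_ic50 <- sum(responses$log_ic50[j] * wj) / sum(wj)
      if ("weight" %in% names(row)) row$weight <- sum(wj)
      keep[j] <- FALSE
      merged_rows[[length(merged_rows) + 1L]] <- row
    }
    report <- rbind(report, data.frame(
      drug_id = d, n_shared = length(shared), r = r, action = "merged",
      reason = ""))
  }
  out <- rbind(responses[keep, , drop = FALSE],
               do.call(rbind, merged_rows))
  rownames(out) <- NULL
  list(responses = out, report = report)
}

#' Filter cancer cell lines
#'
#' Retains cell lines whose mutation profiles come from whole-genome
#' sequencing, that have at least `min_responses` drug-response entries and
#' an expression profile, and that carry at least one mutation mapping to a
#' reference protein kinase A (PKA) position.
#'
#' @param cells Data frame with `cell_line_id`, `wgs_flag`,
#'   `has_expression` (0/1 each), plus site/histology columns.
#' @param responses Response data frame (for per-line entry counts).
#' @param mutations Mutation data frame with `cell_line_id` and `position`
#'   (reference-PKA position; `NA` = unmapped).
#' @param min_responses Minimum response entries (default 30).
#' @return A list: `retained` (character vector of cell-line ids) and
#'   `removal_counts` (named integer vector: lines failing each criterion;
#'   a line may fail several).
#' @export
filter_cell_lines <- function(cells, responses, mutations,
                              min_responses = 30L) {
  n_resp <- table(responses$cell_line_id)
  resp_ok <- as.integer(n_resp[cells$cell_line_id]) >= min_responses
  resp_ok[is.na(resp_ok)] <- FALSE
  mapped <- unique(mutations$cell_line_id[!is.na(mutations$position)])
  crit <- cbind(
    no_wgs = cells$wgs_flag != 1L,
    few_responses = !resp_ok,
    no_expression = cells$has_expression != 1L,
    no_mapped_mutation = !cells$cell_line_id %in% mapped
  )
  list(retained = cells$cell_line_id[rowSums(crit) == 0L],
       removal_counts = colSums(crit))
}

# histology subtypes defining non-small cell lung cancer
nsclc_subtypes <- function() {
  c("adenocarcinoma", "non_small_cell_carcinoma", "squamous_cell_carcinoma",
    "large_cell_carcinoma", "giant_cell_carcinoma",
    "mixed_adenosquamous_carcinoma")
}

#' Assign cancer-group labels to responses
#'
#' Groups are primary cancer sites, with two refinements: the
#' haematopoietic-and-lymphoid tissue group is split by primary histology,
#' and lung is split into non-small cell lung cancer (NSCLC; histology
#' subtypes adenocarcinoma, non-small cell carcinoma, squamous cell
#' carcinoma, large cell carcinoma, giant cell carcinoma, or mixed
#' adenosquamous carcinoma) versus "lung (others)". Groups with fewer than
#' `min_group_responses` responses are excluded for low statistical power.
#'
#' @param cells Data frame with `cell_line_id`, `primary_site`,
#'   `primary_histology`, `histology_subtype`.
#' @param responses Response data frame with `cell_line_id`.
#' @param min_group_responses Minimum responses per retained group.
#' @return A list: `group` (character vector aligned to `responses` rows;
#'   `NA` for responses of excluded groups or unknown cell lines),
#'   `group_sizes` (named counts of retained groups), `excluded`
#'   (named counts of excluded groups).
#' @export
assign_cancer_groups <- function(cells, responses,
                                 min_group_responses = 1000L) {
  site <- normalize_label(cells$primary_site)
  hist <- normalize_label(cells$primary_histology)
  sub <- normalize_label(cells$histology_subtype)
  grp <- site
  hl <- site == "haematopoietic_and_lymphoid_tissue"
  grp[hl] <- ifelse(grepl("lymphoid", hist[hl]), "lymphoid_neoplasm",
                    "haematopoietic_neoplasm")
  lung <- site == "lung"
  grp[lung] <- ifelse(sub[lung] %in% nsclc_subtypes(),
                      "lung_nsclc", "lung_others")
  by_cell <- stats::setNames(grp, cells$cell_line_id)
  g <- unname(by_cell[responses$cell_line_id])
  sizes <- table(g)
  small <- names(sizes)[sizes < min_group_responses]
  excluded <- sizes[small]
  g[g %in% small] <- NA_character_
  list(group = g,
       group_sizes = table(g),
       excluded = excluded)
}
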