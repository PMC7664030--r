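test_that("kinase-inhibitor classification applies weight and label rules", {
  expect_true(classify_pki(500, "inhibitor"))
  expect_true(classify_pki(500, "antagonist;other"))
  expect_false(classify_pki(901, "inhibitor"))
  expect_false(classify_pki(900, "inhibitor"))       # strict < 900
  expect_false(classify_pki(500, "agonist"))
  expect_true(classify_pki(500, "", kinomescan_control = 4.9))
  expect_false(classify_pki(500, "", kinomescan_control = 5.0))  # strict < 5
  expect_error(classify_pki(-10, "inhibitor"), "positive")
})

make_dup_responses <- function(sanger, mgh, drug = "dup") {
  cl <- sprintf("C%02d", seq_along(sanger))
  rbind(
    data.frame(drug_id = drug, cell_line_id = cl, log_ic50 = sanger,
               source_flag = 1L),
    data.frame(drug_id = drug, cell_line_id = cl, log_ic50 = mgh,
               source_flag = 0L)
  )
}

test_that("duplicate assays merge when correlated, drop otherwise", {
  # identical values across sources: r = 1, merged values equal originals
  v <- c(-2, 0, 1, 3)
  m <- merge_duplicate_assays(make_dup_responses(v, v))
  expect_equal(m$report$action, "merged")
  expect_equal(sort(m$responses$log_ic50), sort(v))
  expect_equal(nrow(m$responses), 4L)

  # equal weights: pair (-2, -1) merges to the arithmetic mean -1.5
  m2 <- merge_duplicate_assays(make_dup_responses(c(-2, 0, 2),
                                                  c(-1, 1, 3)))
  expect_equal(sort(m2$responses$log_ic50), c(-1.5, 0.5, 2.5))

  # weakly correlated pairs (r = 0.6, below threshold): drug excluded
  a <- c(1, 2, 3, 4)
  b <- c(2, 1, 4, 3)
  expect_equal(cor(a, b), 0.6)
  m3 <- merge_duplicate_assays(make_dup_responses(a, b))
  expect_equal(m3$report$action, "excluded")
  expect_equal(nrow(m3$responses), 0L)

  # fewer than 3 shared lines: excluded with the overlap reason
  m4 <- merge_duplicate_assays(make_dup_responses(c(1, 2), c(1, 2)))
  expect_match(m4$report$reason, "insufficient overlap")
})

test_that("merging is idempotent and respects replicate weights", {
  resp <- make_dup_responses(c(0, 1, 2, 4), c(1, 2, 3, 4))
  resp$weight <- c(3, 3, 3, 3, 1, 1, 1, 1)  # Sanger triple-weighted
  m <- merge_duplicate_assays(resp)
  expect_equal(sort(m$responses$log_ic50),
               sort((3 * c(0, 1, 2, 4) + 1 * c(1, 2, 3, 4)) / 4))
  expect_true(all(m$responses$source_flag == 1L))
  m_again <- merge_duplicate_assays(m$responses)
  expect_equal(m_again$responses[order(m_again$responses$cell_line_id), ],
               m$responses[order(m$responses$cell_line_id), ],
               ignore_attr = TRUE)
  expect_equal(nrow(m_again$report), 0L)
})

test_that("cell-line filter applies all four criteria with counts", {
  cells <- data.frame(
    cell_line_id = sprintf("C%02d", 1:10),
    wgs_flag = c(0L, rep(1L, 9)),           # C01 fails WGS
    has_expression = c(1L, 1L, 0L, rep(1L, 7)),  # C03 fails expression
    primary_site = "lung", primary_histology = "x",
    histology_subtype = "adenocarcinoma")
  responses <- do.call(rbind, lapply(1:10, function(i) {
    n <- if (i == 2) 29 else 30              # C02 fails the count
    data.frame(drug_id = sprintf("D%03d", seq_len(n)),
               cell_line_id = sprintf("C%02d", i),
               log_ic50 = 0, source_flag = 1L)
  }))
  mutations <- data.frame(cell_line_id = sprintf("C%02d", 1:10),
                          gene = "G1", wt = "L",
                          position = c(rep(187L, 10)), mut = "R")
  out <- filter_cell_lines(cells, responses, mutations)
  expect_setequal(out$retained, sprintf("C%02d", c(4:10)))
  expect_equal(unname(out$removal_counts),
               c(1, 1, 1, 0))  # one line per violated criterion

  # unmapped-only mutations fail the PKA-position criterion
  mutations$position[4] <- NA_integer_
  out2 <- filter_cell_lines(cells, responses, mutations)
  expect_false("C04" %in% out2$retained)
})

test_that("cancer groups split lung and haematopoietic tissue correctly", {
  cells <- data.frame(
    cell_line_id = c("A", "B", "C", "D", "E"),
    primary_site = c("lung", "lung", "haematopoietic_and_lymphoid_tissue",
                     "haematopoietic_and_lymphoid_tissue", "skin"),
    primary_histology = c("carcinoma", "carcinoma", "lymphoid_neoplasm",
                          "haematopoietic_neoplasm", "melanoma"),
    histology_subtype = c("adenocarcinoma", "small_cell_carcinoma",
                          "", "", ""))
  responses <- data.frame(drug_id = "D1",
                          cell_line_id = c("A", "B", "C", "D", "E"),
                          log_ic50 = 0, source_flag = 1L)
  g <- assign_cancer_groups(cells, responses, min_group_responses = 1L)
  expect_equal(g$group, c("lung_nsclc", "lung_others", "lymphoid_neoplasm",
                          "haematopoietic_neoplasm", "skin"))

  # a group one short of the minimum is excluded; sizes sum to retained
  responses2 <- data.frame(drug_id = sprintf("D%03d", 1:999),
                           cell_line_id = "E", log_ic50 = 0,
                           source_flag = 1L)
  g2 <- assign_cancer_groups(cells, responses2,
                             min_group_responses = 1000L)
  expect_true(all(is.na(g2$group)))
  expect_equal(unname(g2$excluded["skin"]), 999)
  expect_equal(sum(g2$group_sizes), sum(!is.na(g2$group)))
})
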