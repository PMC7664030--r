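test_that("residue deltas quantify the physicochemical change", {
  m <- data.frame(cell_line_id = "H3255", gene = "EGFR", wt = "L",
                  position = 187L, mut = "R")
  f <- residue_delta_features(m, c("H3255", "OTHER"))
  expect_equal(unname(f["H3255", "PKA_187_CHA"]), 1)  # L -> R gains +1
  expect_equal(unname(f["H3255", "PKA_187_MUT"]), 1)
  expect_equal(unname(f["H3255", "PKA_187_BLO"]), -2)  # BLOSUM62 L/R
  expect_true(all(f["OTHER", ] == 0))

  # identity substitution leaves every delta at zero except the count
  # and the (positive) self-substitution score
  m2 <- data.frame(cell_line_id = "X", gene = "G", wt = "L",
                   position = 10L, mut = "L")
  f2 <- residue_delta_features(m2, "X")
  expect_equal(unname(f2[1, c("PKA_10_CHA", "PKA_10_POL", "PKA_10_HYD",
                              "PKA_10_ASA", "PKA_10_VOL", "PKA_10_ENE")]),
               rep(0, 6))
  expect_equal(unname(f2[1, "PKA_10_BLO"]), 4)

  # unmapped or non-canonical mutations are skipped with a message
  m3 <- rbind(m, data.frame(cell_line_id = "H3255", gene = "X", wt = "B",
                            position = 2L, mut = "R"),
              data.frame(cell_line_id = "H3255", gene = "X", wt = "L",
                         position = NA_integer_, mut = "R"))
  expect_message(f3 <- residue_delta_features(m3, "H3255"), "skipped 2")
  expect_equal(colnames(f3), colnames(residue_delta_features(m, "H3255")))
})

test_that("property deltas are antisymmetric and additive", {
  aa <- aa_properties()$residue
  set.seed(11)
  for (i in 1:20) {
    wt <- sample(aa, 1); mu <- sample(aa, 1)
    fwd <- residue_delta_features(
      data.frame(cell_line_id = "C", gene = "G", wt = wt,
                 position = 5L, mut = mu), "C")
    rev <- residue_delta_features(
      data.frame(cell_line_id = "C", gene = "G", wt = mu,
                 position = 5L, mut = wt), "C")
    props <- paste0("PKA_5_", c("CHA", "POL", "HYD", "ASA", "VOL", "ENE"))
    expect_equal(unname(fwd[1, props]), -unname(rev[1, props]))
  }
  # two mutations at one position accumulate
  m <- data.frame(cell_line_id = "C", gene = "G", wt = c("L", "E"),
                  position = 7L, mut = c("R", "K"))
  f <- residue_delta_features(m, "C")
  expect_equal(unname(f[1, "PKA_7_MUT"]), 2)
  expect_equal(unname(f[1, "PKA_7_CHA"]), 1 + 2)  # (R-L) + (K-E)
})

test_that("annotation roll-ups match a brute-force recount", {
  set.seed(21)
  genes <- paste0("G", 1:6)
  cells <- paste0("C", 1:4)
  mutations <- data.frame(
    cell_line_id = sample(cells, 25, replace = TRUE),
    gene = sample(genes, 25, replace = TRUE))
  annotations <- data.frame(
    gene = sample(genes, 12, replace = TRUE),
    entity = sample(c("GO_1", "GO_2", "PWY_1"), 12, replace = TRUE),
    level = "go")
  annotations$level[startsWith(annotations$entity, "PWY")] <- "pathway"
  annotations <- unique(annotations)
  out <- rollup_features(mutations, annotations, cells)
  for (e in unique(annotations$entity)) {
    gset <- annotations$gene[annotations$entity == e]
    for (cl in cells) {
      oracle <- sum(mutations$cell_line_id == cl & mutations$gene %in% gset)
      expect_equal(unname(out$values[cl, e]), oracle)
    }
  }
  # per-gene counts also match, cell line without mutations is all zero
  for (g in genes) {
    cnt <- unname(out$values[, paste0("MUTCOUNT_", g)])
    expect_equal(cnt, as.vector(table(factor(
      mutations$cell_line_id[mutations$gene == g], levels = cells))))
  }
  out2 <- rollup_features(mutations[0, ], annotations, cells)
  expect_true(all(out2$values == 0))
})

test_that("expression passthrough zero-fills missing values", {
  expr <- matrix(c(1, NA, 3, 4), 2, 2,
                 dimnames = list(c("C1", "C2"), c("G1", "G2")))
  expect_message(
    out <- rollup_features(data.frame(cell_line_id = "C1", gene = "G1"),
                           data.frame(gene = character(),
                                      entity = character(),
                                      level = character()),
                           c("C1", "C2", "C3"), expression = expr),
    "zero-filled")
  expect_equal(unname(out$values["C2", "EXP_G1"]), 0)
  expect_equal(unname(out$values["C3", "EXP_G2"]), 0)
})

test_that("dummy coding uses k-1 indicators and decodes back", {
  df <- data.frame(tissue = c("lung", "skin", "lung"),
                   hist = c("a", "b", "c"),
                   flat = c("x", "x", "x"))
  expect_message(out <- dummy_code(df), "single-level")
  expect_equal(colnames(out$values),
               c("tissue.skin", "hist.b", "hist.c"))
  expect_true(all(rowSums(out$values[, c("hist.b", "hist.c")]) <= 1))
  expect_equal(dummy_decode(out$values, out$mapping$hist, "hist"),
               df$hist)
  expect_equal(dummy_decode(out$values, out$mapping$tissue, "tissue"),
               df$tissue)
})

test_that("drug feature priority ranks complex fingerprints first", {
  expect_equal(rank_drug_features(c("Fingerprint_10", "Fingerprint_800",
                                    "ALogP")),
               c("Fingerprint_800", "Fingerprint_10", "ALogP"))
  # descriptor-only input keeps its order
  expect_equal(rank_drug_features(c("b", "a", "c")), c("b", "a", "c"))
  # full 881-bit panel is strictly decreasing in bit index
  bits <- sample(paste0("Fingerprint_", 1:881))
  ranked <- rank_drug_features(c(bits, "ALogP", "TPSA"))
  idx <- as.integer(sub("Fingerprint_", "", head(ranked, 881)))
  expect_true(all(diff(idx) < 0))
  expect_equal(ranked[882:883], c("ALogP", "TPSA"))
})
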