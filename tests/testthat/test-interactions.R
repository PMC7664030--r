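test_that("drug-mutation candidates are the fingerprint-residue product set", {
  cand <- build_drug_mutation_terms(
    c("Fingerprint_791", "Fingerprint_826"),
    c("PKA_187_CHA", "PKA_187_VOL", "PKA_30_MUT"))
  expect_equal(nrow(cand), 6L)
  expect_true("PKA_187_CHA_X_Fingerprint_791" %in% cand$term)
  expect_true(all(cand$type == "drug_mutation"))
  expect_equal(nrow(build_drug_mutation_terms(character(0), "PKA_1_CHA")),
               0L)
})

test_that("PPI candidates respect score, self-edge and kinase rules", {
  edges <- data.frame(
    protein1 = c("KIN1", "KIN1", "KIN2", "OTH1", "KIN3"),
    protein2 = c("OTH1", "KIN1", "OTH2", "OTH2", "OTH3"),
    combined_score = c(900, 950, 700, 900, 800))
  cand <- build_ppi_terms(edges, kinases = c("KIN1", "KIN2", "KIN3"),
                          expressed_genes = c("KIN1", "KIN2", "OTH1",
                                              "OTH2", "OTH3"))
  # self edge rejected; score exactly 700 rejected (strict >);
  # non-kinase pair rejected; KIN3 edge lacks expression for KIN3
  expect_equal(cand$term, "EXP_KIN1_X_EXP_OTH1")
  expect_equal(cand$component_a, "EXP_KIN1")

  # term value is the expression product
  design <- cbind(EXP_KIN1 = c(2, 1), EXP_OTH1 = c(3, 5))
  v <- interaction_values(design, cand)
  expect_equal(unname(v[, 1]), c(6, 5))
})

test_that("hierarchy-related pairs are excluded transitively", {
  ents <- c("GO_0060479", "GO_0030324", "GO_0048675", "GO_0009888")
  # lung cell differentiation -> lung development -> (grand)parent tissue
  # development; axon extension unrelated
  hier <- data.frame(child = c("GO_0060479", "GO_0030324"),
                     parent = c("GO_0030324", "GO_0009888"),
                     namespace = "go")
  cand <- build_setlevel_terms(ents, hier, type = "go_process")
  expect_false(any(grepl("GO_0060479.*GO_0030324|GO_0030324.*GO_0060479",
                         cand$term)))
  # grandparent pair excluded too (transitive closure)
  expect_false(any(cand$component_a == "GO_0009888" &
                     cand$component_b == "GO_0060479" |
                   cand$component_a == "GO_0060479" &
                     cand$component_b == "GO_0009888"))
  expect_true("GO_0030324_X_GO_0048675" %in% cand$term)

  # four unrelated entities give all C(4,2) = 6 pairs
  cand2 <- build_setlevel_terms(paste0("GO_", 1:4),
                                hier[0, ], type = "go_process")
  expect_equal(nrow(cand2), 6L)

  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                    namespace = "go")
  expect_error(build_setlevel_terms(c("A", "B"), cyc), "cycle")
})

test_that("nested F-test matches the anova oracle and finds signal", {
  # 5-point fixture checked against R's own nested-model anova
  y <- c(1.0, 2.1, 0.4, 3.3, 2.2)
  a <- c(0, 1, 0, 1, 1)
  b <- c(0.5, -1, 2, 1.5, 0)
  ft <- ftest_term(y, a, b)
  oracle <- anova(lm(y ~ a + b), lm(y ~ a + b + a:b))
  expect_equal(ft$f_stat, oracle$F[2])
  expect_equal(ft$p_value, oracle$`Pr(>F)`[2])

  # pure product signal is overwhelmingly significant
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  ft2 <- ftest_term(a * b, a, b)
  expect_lt(ft2$p_value, 1e-10)

  # constant product is degenerate
  ft3 <- ftest_term(rnorm(20), rep(0, 20), rnorm(20))
  expect_true(is.na(ft3$p_value))
})

test_that("term filtering applies BH and the support bound", {
  stats <- data.frame(
    term = c("t1", "t2", "t3", "t4"),
    type = "ppi", component_a = "x", component_b = "y",
    nonzero_count = c(100L, 29L, 30L, 100L),
    f_stat = 1, p_value = c(0.01, 0.001, 0.02, 0.04),
    tested = TRUE, reason = "")
  out <- filter_terms(stats[-2, ], alpha = 0.05, min_nonzero = 30L)
  # BH on (0.01, 0.02, 0.04) with m = 3 gives (0.03, 0.03, 0.04)
  expect_equal(out$fdr_q, c(0.03, 0.03, 0.04))
  expect_true(all(out$kept))

  # a 29-support term is rejected no matter how significant
  out2 <- filter_terms(stats, alpha = 0.05, min_nonzero = 30L)
  expect_false(out2$kept[out2$term == "t2"])
  # BH invariants: q >= p, q <= 1
  expect_true(all(out2$fdr_q >= out2$p_value & out2$fdr_q <= 1))
})

test_that("candidate testing skips weak support and degenerate terms", {
  set.seed(9)
  design <- cbind(a = c(rep(1, 5), rep(0, 45)), b = rnorm(50),
                  z = rep(0, 50))
  y <- rnorm(50)
  cand <- data.frame(term = c("a_X_b", "z_X_b"), type = "drug_mutation",
                     component_a = c("a", "z"), component_b = "b")
  out <- test_interaction_terms(design, y, cand, min_nonzero = 30L)
  expect_false(any(out$tested))
  expect_equal(out$reason, c("below min_nonzero", "below min_nonzero"))
  expect_equal(out$nonzero_count, c(5L, 0L))

  # with the bound relaxed, products match a naive loop recomputation
  out2 <- test_interaction_terms(design, y, cand, min_nonzero = 1L)
  expect_true(out2$tested[1])
  naive <- vapply(seq_len(50), function(i) design[i, "a"] * design[i, "b"],
                  numeric(1))
  expect_equal(unname(interaction_values(design, cand)[, "a_X_b"]), naive)
})
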