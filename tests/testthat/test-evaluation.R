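test_that("regression scores match hand-computed values", {
  expect_equal(score(c(1, 2, 3), c(1, 2, 3)), list(r2 = 1, rmse = 0))
  act <- c(2, 2, 4, 3)
  expect_equal(score(rep(mean(act), 4), act)$r2, 0)
  # 4-point fixture: RSS = 3, TSS = 2.75
  sc <- score(c(1, 2, 3, 4), act)
  expect_equal(sc$r2, 1 - 3 / 2.75)
  expect_equal(sc$rmse, sqrt(3 / 4))
  expect_warning(score(c(1, 2), c(5, 5)), "undefined")
})

test_that("multi-threshold ROC averages AUCs and skips degenerate cuts", {
  # a perfect ranker scores AUC 1 at every populated threshold
  act <- seq(-5, 1, length.out = 120)
  roc <- multithreshold_roc(act, act)
  expect_equal(unname(roc$auc_by_threshold), rep(1, 5))
  expect_equal(roc$mean_auc, 1)

  # thresholds outside the actual range are skipped and recorded
  act2 <- seq(-1.5, 1, length.out = 60)
  expect_message(roc2 <- multithreshold_roc(act2, act2), "skipped")
  expect_setequal(roc2$skipped, c(-4, -3, -2))
  expect_equal(unname(roc2$auc_by_threshold[4:5]), c(1, 1))

  # random scores sit near 0.5 on average
  set.seed(8)
  act3 <- rnorm(2000, mean = -1.5, sd = 1.5)
  pred3 <- rnorm(2000)
  expect_lt(abs(multithreshold_roc(pred3, act3)$mean_auc - 0.5), 0.05)
})

test_that("AUC agrees with a brute-force pairwise oracle and is
           monotone-invariant", {
  set.seed(14)
  act <- rnorm(40, mean = -1)
  pred <- act + rnorm(40)
  roc <- multithreshold_roc(pred, act, thresholds = c(-1, 0))
  for (t in c(-1, 0)) {
    oracle <- brute_auc(-pred, act < t)
    expect_equal(unname(roc$auc_by_threshold[as.character(t)]), oracle)
  }
  # monotone transform of the score leaves AUC unchanged
  roc2 <- multithreshold_roc(qnorm(pnorm(pred)) * 3 + 1, act,
                             thresholds = c(-1, 0))
  expect_equal(roc2$auc_by_threshold, roc$auc_by_threshold)
})

test_that("unit perturbation equals the coefficient on the linear view", {
  lin <- qsmart_linear(c(`(Intercept)` = 2, f = 0.45, g = -1.2))
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f", "g")))
  expect_equal(perturb_effect(lin, "f", x)$delta, 0.45)
  expect_equal(perturb_effect(lin, "g", x)$delta, -1.2)
  expect_equal(perturb_effect(lin, "f", x, delta = 3)$delta, 0.45)
  expect_error(perturb_effect(lin, "h", x), "not in model")
})

test_that("network perturbation matches direct forward differencing", {
  net <- structure(list(
    layers = list(list(W = matrix(c(0.7, -0.4), 1, 2), b = c(0, 0.1)),
                  list(W = matrix(c(1, 0), 2, 1), b = 0)),
    hidden = 2L, lambda = 0, features = "f",
    x_center = c(f = 0), x_scale = c(f = 1), y_center = 0, y_scale = 1,
    cv = NULL, mean_cv_r2 = NA_real_, seed = 1L, iterations = 0L
  ), class = "qsmart_network")
  x <- matrix(c(-1, 0, 2), 3, 1, dimnames = list(NULL, "f"))
  pe <- perturb_effect(net, "f", x)
  manual <- mean(tanh(0.7 * (x + 1))) - mean(tanh(0.7 * x))
  expect_equal(pe$delta, manual)
  # the second hidden unit has zero weight into the output: changing only
  # its path leaves predictions unchanged
  net0 <- net
  net0$layers[[1]]$W[1, 2] <- 99
  expect_equal(predict(net0, x), predict(net, x))
})

test_that("interaction analysis reproduces the engine F-test with cell
           means", {
  set.seed(23)
  bit <- rbinom(300, 1, 0.4)
  res <- rnorm(300) * (runif(300) < 0.5)  # residue delta, often zero
  y <- 1 + 0.5 * bit - 0.8 * bit * res + rnorm(300, sd = 0.3)
  ia <- interaction_analysis(y, bit, res)
  ft <- ftest_term(y, bit, res)
  expect_equal(ia$f_stat, ft$f_stat)
  expect_lt(ia$p_value, 0.01)
  expect_equal(nrow(ia$cell_means), 4L)
  expect_equal(sum(ia$cell_means$n), 300L)

  # additive data: no interaction detected
  y2 <- 1 + 0.5 * bit + 0.7 * res + rnorm(300, sd = 0.3)
  expect_gt(interaction_analysis(y2, bit, res)$p_value, 0.01)
})

test_that("PPI edge impacts carry exact deltas and sign classes", {
  lin <- qsmart_linear(c(`(Intercept)` = 0,
                         EXP_MAP4K4_X_EXP_TP53 = -0.089,
                         EXP_A_X_EXP_B = 0.061,
                         EXP_C_X_EXP_D = 0))
  terms <- data.frame(
    term = c("EXP_MAP4K4_X_EXP_TP53", "EXP_A_X_EXP_B", "EXP_C_X_EXP_D"),
    component_a = c("EXP_MAP4K4", "EXP_A", "EXP_C"),
    component_b = c("EXP_TP53", "EXP_B", "EXP_D"))
  x <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, terms$term))
  tab <- ppi_edge_impacts(lin, terms, x, cut = 0.05)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$delta, c(-0.089, 0.061, 0))
  expect_equal(tab$sign_class, c("negative", "positive", "weak positive"))
  expect_equal(tab$gene_a[1], "MAP4K4")
  expect_error(ppi_edge_impacts(lin, terms[0, ], x), "no PPI terms")
})

test_that("paired signed-rank comparison behaves at the boundaries", {
  a <- seq(0.5, 0.9, length.out = 23)
  expect_equal(compare_models(a, a)$p_value, 1)
  out <- compare_models(a + 0.1, a)
  expect_lt(out$p_value, 0.01)
  # two-sided symmetry under swapping the inputs
  expect_equal(compare_models(a, a + 0.1)$p_value, out$p_value)
  expect_error(compare_models(a[1:3], a[1:3]), "6")
})
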