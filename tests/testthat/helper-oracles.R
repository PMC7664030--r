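# Independent brute-force oracles used across the suite.

# Mann-Whitney AUC by pairwise comparison (ties count 1/2)
brute_auc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# smallest integer m with m^den >= n^num, by direct search from 1
oracle_root_ceiling <- function(n, num, den) {
  m <- 1
  while (m^den < n^num) m <- m + 1
  m
}

# least-squares BIC of an explicit support (Gaussian likelihood, var RSS/n)
ls_bic <- function(x, y, support) {
  X <- cbind(1, x[, support, drop = FALSE])
  rss <- sum(stats::.lm.fit(X, y)$residuals^2)
  n <- length(y)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  length(support) * log(n) - 2 * ll
}

# design matrix where column `f` has exactly R^2 = 0.8 against the rest:
# f = 2 * x1 + e with e orthogonal to [1, x1] and equal sums of squares
r2_point8_design <- function() {
  x1 <- c(-1, 1, -1, 1)
  e <- c(-1, -1, 1, 1)
  cbind(x1 = x1, f = 2 * x1 + e)
}

# tiny deterministic response fixture (3 drugs x 2 cell lines)
tiny_responses <- function() {
  data.frame(
    drug_id = rep(c("D1", "D2", "D3"), each = 2),
    cell_line_id = rep(c("C1", "C2"), 3),
    log_ic50 = c(-1.2, 0.4, 2.2, 3.0, 0.0, 1.1),
    source_flag = c(1L, 0L, 1L, 1L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

write_tiny_csv <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
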