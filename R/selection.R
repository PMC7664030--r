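# Feature selection: VIF-controlled prioritized screening, Lasso with BIC
# model selection, and an ensemble average-rank alternative.

#' Variance inflation factor of one feature
#'
#' Regresses feature `i` on the remaining columns (with intercept) and
#' returns `1 / (1 - R^2_i)`. `R^2_i = 0.8` therefore maps exactly to
#' VIF = 5, the conventional high-collinearity cut. A fit with `R^2_i = 1`
#' within tolerance returns `Inf`; a constant feature is undefined and
#' returns `NA` with a message.
#'
#' @param x Numeric design matrix (>= 2 columns).
#' @param i Column index or name.
#' @return A single VIF value (>= 1, possibly `Inf` or `NA`).
#' @export
compute_vif <- function(x, i) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  xi <- x[, i]
  if (stats::var(xi) == 0) {
    message("compute_vif: constant feature, VIF undefined")
    return(NA_real_)
  }
  others <- if (is.character(i)) setdiff(colnames(x), i)
            else setdiff(seq_len(ncol(x)), i)
  fit <- stats::.lm.fit(cbind(1, x[, others, drop = FALSE]), xi)
  r2 <- 1 - sum(fit$residuals^2) / sum((xi - mean(xi))^2)
  if (r2 >= 1 - 1e-10) return(Inf)
  1 / (1 - max(r2, 0))
}

# VIFs of every column of x (vector; NA for constants, Inf for exact
# collinearity)
vif_all <- function(x) {
  if (ncol(x) < 2L) return(stats::setNames(rep(1, ncol(x)), colnames(x)))
  vapply(seq_len(ncol(x)), function(i) suppressMessages(compute_vif(x, i)),
         numeric(1)) |> stats::setNames(colnames(x))
}

#' Stepwise feature screening under VIF control
#'
#' Walks the features in the supplied priority order and greedily accepts a
#' candidate only if, after adding it, every feature kept so far (candidate
#' included) still has VIF at most `vif_max` — an exact greedy recomputation
#' rather than a one-shot batch screen. Constant columns are never kept.
#' The result is deterministic and independent of the row order of `x`.
#'
#' @param x Numeric design matrix with named columns.
#' @param priority Character vector: column names from highest to lowest
#'   priority (see [rank_drug_features()] for the drug block).
#' @param vif_max Maximum tolerated VIF (default 5).
#' @return A list: `kept` (accepted names, priority order) and `report`
#'   (per candidate: `feature`, `step`, `kept`, `vif` at decision time,
#'   `r2` implied by the VIF).
#' @export
vif_stepwise_screen <- function(x, priority = colnames(x), vif_max = 5) {
  stopifnot(all(priority %in% colnames(x)))
  kept <- character(0)
  report <- data.frame(feature = priority, step = seq_along(priority),
                       kept = FALSE, vif = NA_real_, r2 = NA_real_,
                       stringsAsFactors = FALSE)
  for (s in seq_along(priority)) {
    f <- priority[s]
    if (stats::var(x[, f]) == 0) next
    trial <- x[, c(kept, f), drop = FALSE]
    v <- if (ncol(trial) == 1L) 1 else vif_all(trial)
    report$vif[s] <- unname(v[f])
    report$r2[s] <- 1 - 1 / unname(v[f])
    if (all(is.finite(v)) && all(v <= vif_max)) {
      kept <- c(kept, f)
      report$kept[s] <- TRUE
    }
  }
  list(kept = kept, report = report)
}

#' Bayesian Information Criterion
#'
#' `BIC = k * ln(n) - 2 * ln(L-hat)`: the fit is rewarded through the
#' maximized likelihood and penalized per selected feature.
#'
#' @param k Number of selected features.
#' @param n Number of observations.
#' @param loglik Maximized log-likelihood.
#' @return BIC value.
#' @examples
#' bic_value(0, 10, -5)  # 10
#' @export
bic_value <- function(k, n, loglik) k * log(n) - 2 * loglik

# Gaussian maximum log-likelihood with plug-in variance RSS/n
gaussian_loglik <- function(rss, n) -n / 2 * (log(2 * pi) + log(rss / n) + 1)

#' Lasso selection with BIC control
#'
#' Fits the full Lasso regularization path (glmnet; columns standardized
#' internally) and scores every distinct support along the path by
#' `BIC = k * ln(n) - 2 * ln(L-hat)`, where `k` is the support size and
#' `L-hat` is the model's maximum Gaussian likelihood — the least-squares
#' refit of that support (variance RSS/n) — so the shrinkage used to
#' search the support space does not leak into the criterion. Returns the
#' support minimizing BIC with its refit coefficients on the original
#' scale; ties go to the sparser end of the path.
#'
#' @param x Numeric design matrix (named columns).
#' @param y Numeric response, `length(y) >= 10`.
#' @return A list of class `qsmart_selection`: `selected` (feature names),
#'   `coefficients` (named, least-squares refit, including `(Intercept)`),
#'   `k`, `n`, `loglik`, `bic`, `lambda`, and `trace` (per distinct path
#'   support: `lambda`, `k`, `bic`).
#' @export
lasso_bic_select <- function(x, y) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(y) < 10L) stop("need at least 10 observations", call. = FALSE)
  if (stats::var(y) == 0) stop("response has zero variance", call. = FALSE)
  fit <- glmnet::glmnet(x, y, family = "gaussian", standardize = TRUE)
  n <- length(y)
  beta <- as.matrix(fit$beta)
  supports <- apply(beta != 0, 2, which, simplify = FALSE)
  sig <- vapply(supports, paste, "", collapse = ",")
  first <- !duplicated(sig)
  idx <- which(first & vapply(supports, length, 0L) < n - 1L)
  refit <- function(sup) {
    X <- cbind(`(Intercept)` = 1, x[, sup, drop = FALSE])
    f <- stats::lm.fit(X, y)
    list(rss = sum(f$residuals^2), coef = f$coefficients)
  }
  fits <- lapply(idx, function(j) refit(supports[[j]]))
  k <- vapply(idx, function(j) length(supports[[j]]), 0L)
  ll <- vapply(fits, function(f) gaussian_loglik(f$rss, n), numeric(1))
  bic <- bic_value(k, n, ll)
  best <- which.min(bic)  # first minimum = sparsest on the glmnet path
  selected <- colnames(x)[supports[[idx[best]]]]
  structure(list(
    selected = selected,
    coefficients = fits[[best]]$coef,
    k = k[best], n = n, loglik = ll[best],
    bic = bic[best], lambda = fit$lambda[idx[best]],
    trace = data.frame(lambda = fit$lambda[idx], k = k, bic = bic)
  ), class = "qsmart_selection")
}

#' @export
print.qsmart_selection <- function(x, ...) {
  cat(sprintf("<qsmart_selection> %d of %d path points: k = %d, BIC = %.2f\n",
              which.min(x$trace$bic), nrow(x$trace), x$k, x$bic))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# RReliefF-style relevance weights for regression: features whose local
# differences track response differences among nearest neighbors score high
relief_scores <- function(x, y, k_neighbors = 5L, sample_cap = 200L,
                          seed = 1L) {
  n <- nrow(x)
  xs <- scale(x)
  xs[is.nan(xs)] <- 0
  rngx <- apply(x, 2, function(v) max(v) - min(v))
  rngx[rngx == 0] <- 1
  rngy <- max(y) - min(y)
  if (rngy == 0) rngy <- 1
  idx <- if (n > sample_cap)
    withr::with_seed(seed, sample.int(n, sample_cap)) else seq_len(n)
  ndc <- 0; nda <- numeric(ncol(x)); ndcda <- numeric(ncol(x))
  for (i in idx) {
    d2 <- colSums((t(xs) - xs[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(min(k_neighbors, n - 1L))]
    for (j in nb) {
      dy <- abs(y[i] - y[j]) / rngy
      df <- abs(x[i, ] - x[j, ]) / rngx
      ndc <- ndc + dy
      nda <- nda + df
      ndcda <- ndcda + dy * df
    }
  }
  m <- length(idx) * min(k_neighbors, n - 1L)
  w <- if (ndc > 0 && ndc < m) ndcda / ndc - (nda - ndcda) / (m - ndc)
       else rep(0, ncol(x))
  stats::setNames(w, colnames(x))
}

# permutation importance of a plug-in regressor: MSE increase after
# permuting each column once (seeded)
permutation_importance <- function(x, y, regressor, seed = 1L) {
  model <- regressor(x, y)
  base_mse <- mean((y - model(x))^2)
  perm <- withr::with_seed(seed, sample.int(nrow(x)))
  imp <- vapply(seq_len(ncol(x)), function(j) {
    xp <- x
    xp[, j] <- xp[perm, j]
    mean((y - model(xp))^2) - base_mse
  }, numeric(1))
  stats::setNames(imp, colnames(x))
}

# default plug-in regressor: ridge-stabilized least squares
default_regressor <- function(x, y) {
  xs <- cbind(1, x)
  b <- solve(crossprod(xs) + diag(1e-6, ncol(xs)), crossprod(xs, y))
  function(newx) drop(cbind(1, newx) %*% b)
}

#' Ensemble average-rank feature selection
#'
#' Ranks every feature by four criteria with different assumptions —
#' absolute correlation with the response, a relief-style nearest-neighbor
#' relevance score, permutation importance of a plug-in regressor, and
#' Lasso path entry order — averages the four ranks, and returns the top
#' `k_target` features (the same count the Lasso-BIC route selected, so
#' the two routes are comparable). Ties break by feature name.
#'
#' @param x Numeric design matrix (named columns).
#' @param y Numeric response.
#' @param k_target Number of features to select.
#' @param regressor Plug-in regressor factory `function(x, y)` returning a
#'   prediction `function(newx)`; default is ridge-stabilized least
#'   squares.
#' @param seed Seed for the permutation and any subsampling.
#' @return A list: `selected` (feature names), `ranks` (per feature: the
#'   four ranks and their average).
#' @export
ensemble_rank_select <- function(x, y, k_target,
                                 regressor = default_regressor,
                                 seed = 1L) {
  stopifnot(k_target >= 1L, k_target <= ncol(x))
  nm <- colnames(x)
  r_cor <- rank(-abs(suppressWarnings(stats::cor(x, y))[, 1]),
                ties.method = "average")
  r_relief <- rank(-relief_scores(x, y, seed = seed),
                   ties.method = "average")
  r_perm <- rank(-permutation_importance(x, y, regressor, seed = seed),
                 ties.method = "average")
  fit <- glmnet::glmnet(x, y, family = "gaussian", standardize = TRUE)
  beta <- as.matrix(fit$beta)
  entry <- apply(beta != 0, 1, function(r)
    if (any(r)) which(r)[1] else ncol(beta) + 1L)
  r_lasso <- rank(entry, ties.method = "average")
  avg <- (r_cor + r_relief + r_perm + r_lasso) / 4
  ord <- order(avg, nm)
  list(selected = nm[ord][seq_len(k_target)],
       ranks = data.frame(feature = nm, correlation = r_cor,
                          relief = r_relief, permutation = r_perm,
                          lasso_entry = r_lasso, average = avg,
                          row.names = NULL))
}
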