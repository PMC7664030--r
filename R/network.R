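# Pyramid-rule feed-forward networks: TanH hidden layers sized by the
# geometric pyramid rule, L1 weight penalty, BFGS optimization, 10-fold
# cross-validation with early stopping, and the architecture/iteration
# escalation schedule.

# smallest integer m with m^den >= n^num, in exact integer arithmetic
# (avoids e.g. 27^(1/3) = 3.0000000000000004 ceiling to 4)
root_ceiling <- function(n, num, den) {
  target <- n^num
  m <- max(1, ceiling(target^(1 / den)))
  while (m^den >= target && (m - 1) >= 1 && (m - 1)^den >= target) m <- m - 1
  while (m^den < target) m <- m + 1
  as.integer(m)
}

#' Hidden-layer sizes from the geometric pyramid rule
#'
#' For `N` input nodes: a single-layer network gets `ceil(N^(1/2))` hidden
#' nodes; a double-layer network gets `ceil(N^(2/3))` and `ceil(N^(1/3))`;
#' a complex-double-layer network gets `N` and `ceil(N^(1/2))`. Ceilings
#' are computed in exact integer arithmetic.
#'
#' @param n Number of input nodes (positive integer).
#' @param variant `"single"`, `"double"`, or `"complex_double"`.
#' @return Integer vector of hidden-layer sizes (nonincreasing).
#' @examples
#' pyramid_sizes(10, "double")  # 5 3
#' @export
pyramid_sizes <- function(n, variant = c("single", "double",
                                         "complex_double")) {
  variant <- match.arg(variant)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  switch(variant,
    single = root_ceiling(n, 1, 2),
    double = c(root_ceiling(n, 2, 3), root_ceiling(n, 1, 3)),
    complex_double = c(n, root_ceiling(n, 1, 2))
  )
}

## ---- parameter packing and forward/backward pass -------------------------

mlp_shapes <- function(d, hidden) {
  sizes <- c(d, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l)
    c(inp = sizes[l], out = sizes[l + 1L]))
}

mlp_npar <- function(shapes) sum(vapply(shapes, function(s)
  (s["inp"] + 1L) * s["out"], numeric(1)))

mlp_unpack <- function(par, shapes) {
  out <- list(); pos <- 0L
  for (s in shapes) {
    nw <- s[["inp"]] * s[["out"]]
    out[[length(out) + 1L]] <- list(
      W = matrix(par[pos + seq_len(nw)], s[["inp"]], s[["out"]]),
      b = par[pos + nw + seq_len(s[["out"]])])
    pos <- pos + nw + s[["out"]]
  }
  out
}

mlp_forward <- function(layers, x) {
  a <- x
  acts <- list()
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- a %*% layers[[l]]$W + rep(layers[[l]]$b, each = nrow(a))
    a <- if (l < nl) tanh(z) else z  # linear output node
    acts[[l]] <- a
  }
  list(pred = drop(a), acts = acts)
}

# objective = mean squared error / 2 + lambda * smooth-L1(weights);
# returns value and packed gradient via backprop
mlp_obj <- function(par, shapes, x, y, lambda, eps = 1e-8) {
  layers <- mlp_unpack(par, shapes)
  fw <- mlp_forward(layers, x)
  n <- length(y)
  resid <- fw$pred - y
  value <- sum(resid^2) / (2 * n) +
    lambda * sum(vapply(layers, function(l)
      sum(sqrt(l$W^2 + eps)), numeric(1)))
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- matrix(resid / n, ncol = 1)
  for (l in rev(seq_len(nl))) {
    a_prev <- if (l == 1L) x else fw$acts[[l - 1L]]
    gW <- crossprod(a_prev, delta) +
      lambda * layers[[l]]$W / sqrt(layers[[l]]$W^2 + eps)
    gb <- colSums(delta)
    grads[[l]] <- list(W = gW, b = gb)
    if (l > 1L)
      delta <- (delta %*% t(layers[[l]]$W)) * (1 - fw$acts[[l - 1L]]^2)
  }
  gvec <- unlist(lapply(grads, function(g) c(as.vector(g$W), g$b)))
  list(value = value, grad = gvec)
}

mlp_init <- function(shapes, seed) {
  withr::with_seed(seed, {
    unlist(lapply(shapes, function(s) {
      c(stats::rnorm(s[["inp"]] * s[["out"]], sd = 1 / sqrt(s[["inp"]])),
        rep(0, s[["out"]]))
    }))
  })
}

# BFGS in chunks of `check_every` iterations; stops early when the monitor
# loss fails to improve by `tol` between consecutive checks
mlp_fit <- function(x, y, hidden, lambda, iterations, seed,
                    monitor = NULL, check_every = 10L, tol = 1e-6) {
  shapes <- mlp_shapes(ncol(x), hidden)
  par <- mlp_init(shapes, seed)
  fn <- function(p) mlp_obj(p, shapes, x, y, lambda)$value
  gr <- function(p) mlp_obj(p, shapes, x, y, lambda)$grad
  monitor_loss <- function(p) {
    layers <- mlp_unpack(p, shapes)
    mean((mlp_forward(layers, monitor$x)$pred - monitor$y)^2)
  }
  best_par <- par
  best_loss <- if (is.null(monitor)) fn(par) else monitor_loss(par)
  used <- 0L
  converged <- FALSE
  while (used < iterations) {
    step <- min(check_every, iterations - used)
    res <- stats::optim(par, fn, gr, method = "BFGS",
                        control = list(maxit = step))
    par <- res$par
    used <- used + step
    loss <- if (is.null(monitor)) res$value else monitor_loss(par)
    if (loss < best_loss - tol) {
      best_loss <- loss
      best_par <- par
    } else {
      converged <- TRUE
      break
    }
    if (res$convergence == 0L) {  # optimizer itself converged
      best_par <- if (loss < best_loss) par else best_par
      best_loss <- min(loss, best_loss)
      converged <- TRUE
      break
    }
  }
  list(par = best_par, layers = mlp_unpack(best_par, shapes),
       shapes = shapes, monitor_loss = best_loss, iterations_used = used,
       converged = converged)
}

make_folds <- function(n, k, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Train a pyramid feed-forward network with cross-validation
#'
#' Fits a fully connected TanH network (linear output node, biases at
#' every layer, smooth L1 penalty on weights) by BFGS under k-fold
#' cross-validation: per fold, the penalty is chosen from `lambda_grid` by
#' held-out loss, training stops early when held-out loss stalls, and the
#' fold's validation R-squared is recorded. The reported model is refit on
#' all data with the penalty that won the most folds. Inputs and response
#' are standardized internally; predictions are returned on the original
#' scale. Everything is deterministic given `seed`.
#'
#' @param x Numeric design matrix (named columns).
#' @param y Numeric response.
#' @param hidden Integer vector of hidden-layer sizes (see
#'   [pyramid_sizes()]).
#' @param iterations Maximum optimizer iterations (default 200).
#' @param seed Integer seed.
#' @param folds Number of cross-validation folds (default 10).
#' @param lambda_grid L1 penalty grid (default `10^c(-4, -3, -2)`).
#' @return An object of class `qsmart_network`: `layers` (weights),
#'   `hidden`, `lambda`, `features`, standardization constants, `cv` (per
#'   fold: `fold`, `lambda`, `r2`, `converged`), `mean_cv_r2`, `seed`,
#'   `iterations`.
#' @export
train_network <- function(x, y, hidden, iterations = 200L, seed = 1L,
                          folds = 10L, lambda_grid = 10^c(-4, -3, -2)) {
  stopifnot(is.matrix(x), length(y) == nrow(x), nrow(x) >= folds)
  xc <- colMeans(x)
  xs <- apply(x, 2, stats::sd); xs[xs == 0] <- 1
  yc <- mean(y); ys <- stats::sd(y)
  if (ys == 0) stop("response has zero variance", call. = FALSE)
  xz <- sweep(sweep(x, 2, xc), 2, xs, "/")
  yz <- (y - yc) / ys
  fold_id <- make_folds(length(y), folds, seed)
  cv <- data.frame(fold = seq_len(folds), lambda = NA_real_, r2 = NA_real_,
                   converged = NA)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    best <- NULL
    for (li in seq_along(lambda_grid)) {
      fit <- mlp_fit(xz[tr, , drop = FALSE], yz[tr], hidden,
                     lambda_grid[li], iterations, seed = seed + f,
                     monitor = list(x = xz[!tr, , drop = FALSE],
                                    y = yz[!tr]))
      if (is.null(best) || fit$monitor_loss < best$loss)
        best <- list(loss = fit$monitor_loss, lambda = lambda_grid[li],
                     fit = fit)
    }
    pred <- mlp_forward(best$fit$layers, xz[!tr, , drop = FALSE])$pred
    yv <- yz[!tr]
    cv$r2[f] <- 1 - sum((yv - pred)^2) / sum((yv - mean(yv))^2)
    cv$lambda[f] <- best$lambda
    cv$converged[f] <- best$fit$converged
  }
  # penalty winning the most folds (ties -> smaller lambda) for the refit
  tab <- table(cv$lambda)
  lambda_star <- min(as.numeric(names(tab)[tab == max(tab)]))
  final <- mlp_fit(xz, yz, hidden, lambda_star, iterations, seed = seed)
  structure(list(
    layers = final$layers, hidden = as.integer(hidden),
    lambda = lambda_star, features = colnames(x),
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    cv = cv, mean_cv_r2 = mean(cv$r2), seed = as.integer(seed),
    iterations = as.integer(iterations)
  ), class = "qsmart_network")
}

#' @export
print.qsmart_network <- function(x, ...) {
  cat(sprintf(
    "<qsmart_network> %d-%s-1 TanH, lambda = %g, mean CV R^2 = %.3f\n",
    length(x$features), paste(x$hidden, collapse = "-"), x$lambda,
    x$mean_cv_r2))
  invisible(x)
}

# align a prediction matrix to a model's feature ordering, erroring on the
# first missing feature (never imputed)
align_features <- function(newx, features) {
  miss <- setdiff(features, colnames(newx))
  if (length(miss))
    stop("missing model feature in prediction rows: ", miss[1],
         call. = FALSE)
  newx[, features, drop = FALSE]
}

#' Predict from a fitted network
#'
#' @param object A `qsmart_network`.
#' @param newx Numeric matrix whose named columns are a superset of the
#'   model's features; missing features are an error, never imputed.
#' @param ... Unused.
#' @return Numeric vector of predicted log-IC50 on the original scale.
#' @export
predict.qsmart_network <- function(object, newx, ...) {
  newx <- align_features(newx, object$features)
  xz <- sweep(sweep(newx, 2, object$x_center), 2, object$x_scale, "/")
  drop(mlp_forward(object$layers, xz)$pred) * object$y_scale +
    object$y_center
}

#' Linear view of the fitted model
#'
#' The interpretable companion of the network: an exact affine model
#' `intercept + sum(beta * x)` over named features, used for
#' coefficient-level effect attribution.
#'
#' @param coefficients Named numeric vector including `(Intercept)`.
#' @return An object of class `qsmart_linear`.
#' @export
qsmart_linear <- function(coefficients) {
  stopifnot("(Intercept)" %in% names(coefficients))
  structure(list(
    intercept = unname(coefficients[["(Intercept)"]]),
    beta = coefficients[setdiff(names(coefficients), "(Intercept)")],
    features = setdiff(names(coefficients), "(Intercept)")
  ), class = "qsmart_linear")
}

#' @export
predict.qsmart_linear <- function(object, newx, ...) {
  newx <- align_features(newx, object$features)
  drop(object$intercept + newx %*% object$beta)
}

#' @export
print.qsmart_linear <- function(x, ...) {
  cat(sprintf("<qsmart_linear> intercept %.4g + %d features\n",
              x$intercept, length(x$features)))
  invisible(x)
}

#' Architecture/iteration escalation schedule
#'
#' Trains networks of increasing capacity until the mean cross-validated
#' R-squared reaches `threshold`: (single, 200 iterations), (single, 300),
#' (double, 200), (double, 300), (complex double, 200), (complex double,
#' 300). Stops at the first passing stage; if none passes, the best-seen
#' model is returned with `passed = FALSE`.
#'
#' @param x,y Design matrix and response as in [train_network()].
#' @param threshold Mean CV R-squared target (default 0.8).
#' @param seed Integer seed.
#' @param folds,lambda_grid Passed to [train_network()].
#' @return A list: `model` (a `qsmart_network`), `passed` (logical),
#'   `trace` (per stage: `stage`, `variant`, `iterations`, `mean_cv_r2`).
#' @export
escalation_schedule <- function(x, y, threshold = 0.8, seed = 1L,
                                folds = 10L,
                                lambda_grid = 10^c(-4, -3, -2)) {
  stages <- list(
    list(variant = "single", iterations = 200L),
    list(variant = "single", iterations = 300L),
    list(variant = "double", iterations = 200L),
    list(variant = "double", iterations = 300L),
    list(variant = "complex_double", iterations = 200L),
    list(variant = "complex_double", iterations = 300L)
  )
  trace <- data.frame(stage = integer(), variant = character(),
                      iterations = integer(), mean_cv_r2 = numeric())
  best <- NULL
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    hidden <- pyramid_sizes(ncol(x), st$variant)
    model <- train_network(x, y, hidden, iterations = st$iterations,
                           seed = seed, folds = folds,
                           lambda_grid = lambda_grid)
    trace <- rbind(trace, data.frame(
      stage = s, variant = st$variant, iterations = st$iterations,
      mean_cv_r2 = model$mean_cv_r2))
    if (is.null(best) || model$mean_cv_r2 > best$mean_cv_r2) best <- model
    if (model$mean_cv_r2 >= threshold)
      return(list(model = model, passed = TRUE, trace = trace))
  }
  list(model = best, passed = FALSE, trace = trace)
}

#' Serialize a model specification to JSON
#'
#' Writes the network weights (or linear coefficients), architecture,
#' feature ordering, and training metadata as JSON so a fitted model is a
#' portable text artifact.
#'
#' @param model A `qsmart_network` or `qsmart_linear`.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields embedded in the
#'   artifact.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path, seed = NULL, config_hash = NULL) {
  spec <- if (inherits(model, "qsmart_network")) {
    list(kind = "network", hidden = model$hidden, lambda = model$lambda,
         features = model$features,
         layers = lapply(model$layers, function(l)
           list(W = l$W, b = l$b)),
         x_center = model$x_center, x_scale = model$x_scale,
         y_center = model$y_center, y_scale = model$y_scale,
         mean_cv_r2 = model$mean_cv_r2, seed = model$seed,
         iterations = model$iterations)
  } else if (inherits(model, "qsmart_linear")) {
    list(kind = "linear", intercept = model$intercept,
         beta = as.list(model$beta), features = model$features)
  } else stop("unsupported model class", call. = FALSE)
  spec$provenance <- list(seed = seed, config_hash = config_hash)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
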