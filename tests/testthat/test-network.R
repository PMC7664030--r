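test_that("pyramid rule sizes match exact ceiling arithmetic", {
  expect_equal(pyramid_sizes(4, "single"), 2L)
  expect_equal(pyramid_sizes(10, "double"), c(5L, 3L))
  expect_equal(pyramid_sizes(9, "complex_double"), c(9L, 3L))
  expect_error(pyramid_sizes(0, "single"), "positive")

  # property: sampled N up to 1e6 against an independent search oracle,
  # plus perfect powers where naive floating ceilings go wrong
  set.seed(13)
  ns <- unique(c(1:40, 27, 64, 125, 1000, 8^3, 10^6,
                 sample.int(1e6, 60)))
  for (n in ns) {
    expect_equal(pyramid_sizes(n, "single"),
                 oracle_root_ceiling(n, 1, 2))
    expect_equal(pyramid_sizes(n, "double"),
                 c(oracle_root_ceiling(n, 2, 3),
                   oracle_root_ceiling(n, 1, 3)))
    expect_equal(pyramid_sizes(n, "complex_double"),
                 c(n, oracle_root_ceiling(n, 1, 2)))
  }
})

# hand-built 2-2-1 TanH network for forward-pass oracles
toy_network <- function() {
  structure(list(
    layers = list(
      list(W = matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2), b = c(0.1, -0.2)),
      list(W = matrix(c(1.5, -2.0), 2, 1), b = 0.25)),
    hidden = 2L, lambda = 0, features = c("u", "v"),
    x_center = c(u = 0, v = 0), x_scale = c(u = 1, v = 1),
    y_center = 0, y_scale = 1,
    cv = NULL, mean_cv_r2 = NA_real_, seed = 1L, iterations = 0L
  ), class = "qsmart_network")
}

test_that("forward pass matches hand computation", {
  net <- toy_network()
  x <- matrix(c(1, -1, 0.5, 2), 2, 2, dimnames = list(NULL, c("u", "v")))
  h <- tanh(cbind(1 * 0.5 + 0.5 * (-0.3) + 0.1,
                  1 * 0.2 + 0.5 * 0.8 - 0.2))
  manual1 <- drop(h %*% c(1.5, -2.0)) + 0.25
  expect_equal(predict(net, x)[1], manual1)
  # extra columns are ignored, missing ones are an error naming the first
  x2 <- cbind(x, w = c(9, 9))
  expect_equal(predict(net, x2), predict(net, x))
  expect_error(predict(net, x[, "u", drop = FALSE]), "v")
})

test_that("linear view predicts exact affine combinations", {
  lin <- qsmart_linear(c(`(Intercept)` = 1, x = 2))
  expect_equal(predict(lin, matrix(3, 1, 1, dimnames = list(NULL, "x"))),
               7)
  expect_equal(predict(lin, matrix(0, 1, 1, dimnames = list(NULL, "x"))),
               1)
  # affinity: predict(a x1 + (1-a) x2) = a predict(x1) + (1-a) predict(x2)
  lin2 <- qsmart_linear(c(`(Intercept)` = -0.5, a = 1.2, b = -3))
  x1 <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  x2 <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  al <- 0.3
  expect_equal(predict(lin2, al * x1 + (1 - al) * x2),
               al * predict(lin2, x1) + (1 - al) * predict(lin2, x2))
})

test_that("cross-validated training recovers an easy linear target", {
  set.seed(2)
  x <- matrix(rnorm(300), 300, 1, dimnames = list(NULL, "x"))
  y <- 2 * x[, 1] + rnorm(300, sd = 0.05)
  net <- train_network(x, y, hidden = 2L, iterations = 200L, seed = 4L,
                       folds = 5L, lambda_grid = 1e-4)
  expect_gt(net$mean_cv_r2, 0.95)
  # determinism: identical seed gives identical weights and CV record
  net2 <- train_network(x, y, hidden = 2L, iterations = 200L, seed = 4L,
                        folds = 5L, lambda_grid = 1e-4)
  expect_identical(net$layers, net2$layers)
  expect_identical(net$cv, net2$cv)
})

test_that("folds partition the data reproducibly", {
  f1 <- qsmart:::make_folds(103, 10, seed = 9)
  f2 <- qsmart:::make_folds(103, 10, seed = 9)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  expect_equal(length(f1), 103L)
  expect_true(max(table(f1)) - min(table(f1)) <= 1)
})

test_that("pure-noise training reports near-zero validation R^2", {
  r2 <- vapply(1:5, function(s) {
    set.seed(s)
    x <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "x"))
    y <- rnorm(200)
    train_network(x, y, hidden = 1L, iterations = 100L, seed = s,
                  folds = 5L, lambda_grid = 1e-3)$mean_cv_r2
  }, numeric(1))
  expect_lt(abs(mean(r2)), 0.1)
})

test_that("escalation stops early on solvable data, traverses on noise", {
  set.seed(6)
  x <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  y <- x[, 1] - 2 * x[, 2] + rnorm(200, sd = 0.05)
  sched <- escalation_schedule(x, y, threshold = 0.8, seed = 3L,
                               folds = 5L, lambda_grid = 1e-4)
  expect_true(sched$passed)
  expect_equal(nrow(sched$trace), 1L)
  expect_equal(sched$trace$variant[1], "single")

  noise <- rnorm(80)
  xs <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("a", "b")))
  sched2 <- escalation_schedule(xs, noise, threshold = 0.8, seed = 3L,
                                folds = 5L, lambda_grid = 1e-3)
  expect_false(sched2$passed)
  expect_equal(nrow(sched2$trace), 6L)
  expect_equal(sched2$trace$variant,
               rep(c("single", "double", "complex_double"), each = 2))
  expect_true(all(sched2$trace$iterations == c(200L, 300L)))
})

test_that("model specs serialize to JSON with provenance", {
  net <- toy_network()
  p <- tempfile(fileext = ".json")
  write_model_spec(net, p, seed = 7L, config_hash = "abc")
  spec <- jsonlite::read_json(p)
  expect_equal(spec$kind, "network")
  expect_equal(spec$provenance$seed, 7L)
  expect_equal(unlist(spec$features), c("u", "v"))
  lin <- qsmart_linear(c(`(Intercept)` = 1, x = 2))
  write_model_spec(lin, p)
  expect_equal(jsonlite::read_json(p)$kind, "linear")
})
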