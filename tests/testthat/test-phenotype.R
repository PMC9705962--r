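# Symbolic classifier evolution, classification threshold, MCC, and
# stratified splitting.

test_that("trivial label structures are solved exactly", {
  X <- cbind(a = c(0, 1, 0, 1, 1, 0, 1, 0), b = c(1, 1, 0, 0, 1, 0, 0, 1))

  # all-one labels: the constant 1 at complexity 1
  expect_warning(
    ev1 <- evolve_classifier(X, rep(1, 8), pop_size = 40, generations = 10,
      seed = 1),
    "single-class")
  expect_equal(ev1$model$train_error, 0)
  expect_equal(ev1$model$complexity, 1)
  expect_equal(eval_expression(ev1$model$expr, X), rep(1, 8))

  # labels equal to a 0/1 feature: the brute-force depth-1 optimum is 0
  # and the evolved expression reproduces the feature's values
  y <- X[, "a"]
  expect_equal(depth1_best_mse(X, y), 0)
  ev <- evolve_classifier(X, y, pop_size = 40, generations = 10, seed = 1)
  expect_equal(ev$model$train_error, depth1_best_mse(X, y))
  expect_equal(eval_expression(ev$model$expr, X), unname(y))

  # determinism: identical seed and config give an identical expression
  ev2 <- evolve_classifier(X, y, pop_size = 40, generations = 10, seed = 1)
  expect_identical(ev$model$expression, ev2$model$expression)
})

test_that("the Pareto front is non-dominated and the best error shrinks", {
  set.seed(31)
  x <- rnorm(40)
  X <- cbind(f1 = x, f2 = rnorm(40))
  y <- as.integer(x + 0.4 * rnorm(40) > 0)
  ev <- evolve_classifier(X, y, pop_size = 80, generations = 40, seed = 9)
  fr <- ev$report$front
  expect_false(is.unsorted(fr$complexity))
  expect_true(all(diff(fr$error) < 0))       # strictly better with complexity
  expect_lte(ev$model$train_error, min(fr$error) * 1.01 + 1e-12)
  expect_true(ev$report$stability >= 0 && ev$report$stability <= 100)
  expect_true(ev$report$convergence >= 0 && ev$report$convergence <= 100)
  expect_error(evolve_classifier(X, c(y[-1], NA), pop_size = 10,
    generations = 2, seed = 1), "binary")
})

test_that("classification thresholds the function value at 0.5", {
  X <- cbind(x = c(0, 1, 0, 1))
  const <- function(v) {
    structure(list(expr = list(type = "const", value = v),
      features = "x", target = "OBESITY", complexity = 1, train_error = 0,
      expression = as.character(v)), class = "phenotype_model")
  }
  expect_equal(classify(const(0.7), X), rep(1L, 4))
  expect_equal(classify(const(0.5), X), rep(0L, 4))  # boundary -> class 0

  feat <- structure(list(expr = list(type = "var", name = "x"),
    features = "x", target = "OBESITY", complexity = 1, train_error = 0,
    expression = "x"), class = "phenotype_model")
  expect_equal(classify(feat, X), c(0L, 1L, 0L, 1L))
  expect_error(classify(feat, cbind(z = 1:4)), "missing feature")
})

test_that("protected division keeps expressions finite", {
  X <- cbind(x = c(-1, 0, 2))
  e <- list(type = "op", op = "/",
    l = list(type = "const", value = 3), r = list(type = "var", name = "x"))
  v <- eval_expression(e, X)
  expect_true(all(is.finite(v)))
  expect_equal(v[2], 1)  # near-zero denominator convention
})

test_that("MCC matches the closed form and its conventions", {
  expect_equal(mcc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # TP=3, TN=4, FP=1, FN=2 -> 10 / sqrt(600)
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  obs <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  expect_equal(mcc(pred, obs), 10 / sqrt(600))
  # all-one predictions against mixed labels: zero-denominator convention
  expect_equal(mcc(rep(1, 6), c(1, 0, 1, 0, 1, 1)), 0)
  expect_error(mcc(c(1, 0), c(1)), "equal length")

  # MCC equals the Pearson correlation of the two binary vectors
  set.seed(12)
  for (i in 1:10) {
    a <- rbinom(30, 1, 0.5)
    b <- rbinom(30, 1, 0.5)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(mcc(a, b), cor(a, b), tolerance = 1e-12)
  }
})

test_that("stratified splitting preserves classes deterministically", {
  labels <- rep(c(0, 1), each = 5)
  sp <- train_test_split(labels, 0.2, seed = 3)
  expect_equal(length(sp$train), 8)
  expect_equal(length(sp$test), 2)
  expect_equal(sum(labels[sp$test]), 1)  # one per class in the test set
  expect_identical(sp, train_test_split(labels, 0.2, seed = 3))
  expect_error(train_test_split(labels, 0, seed = 1), "test_fraction")
  expect_error(train_test_split(labels, 1, seed = 1), "test_fraction")
})

test_that("phenotype models survive a JSON round trip", {
  X <- cbind(a = c(0, 1, 1, 0, 1, 0), b = rnorm(6))
  ev <- evolve_classifier(X, X[, "a"], pop_size = 30, generations = 5,
    seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_phenotype_model(ev$model, path)
  back <- load_phenotype_model(path)
  expect_equal(back$expression, ev$model$expression)
  expect_equal(eval_expression(back$expr, X), eval_expression(ev$model$expr, X))
})
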