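test_that("an uninformative predictor gets a null slope", {
  set.seed(1)
  n <- 4000
  y <- rep(0:1, n / 2)
  X <- cbind(noise = rnorm(n))
  fit <- fit_logistic(X, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients["noise"]), 0.1)
  expect_lt(abs(fit$intercept - log(mean(y) / (1 - mean(y)))), 0.1)

  # a constant column is aliased with the intercept: slope exactly 0
  fitc <- fit_logistic(cbind(const = rep(1, n)), y)
  expect_equal(unname(fitc$coefficients["const"]), 0)
  expect_equal(fitc$intercept, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("parameters are recovered at large n", {
  set.seed(2)
  n <- 20000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 + 2 * x))
  fit <- fit_logistic(cbind(x = x), y)
  expect_lt(abs(fit$intercept - 0.5), 0.1)
  expect_lt(abs(fit$coefficients["x"] - 2), 0.1)
  tests <- coefficient_tests(fit)
  expect_lt(tests$p[tests$term == "x"], 1e-10)
})

test_that("complete separation is flagged, not thrown", {
  x <- c(-(5:1), 1:5) / 2
  y <- as.integer(x > 0)
  fit <- fit_logistic(cbind(x = x), y)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
  expect_error(coefficient_tests(fit), "converged")
})

test_that("label flip mirrors coefficients and preserves p-values", {
  set.seed(3)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
  a <- fit_logistic(cbind(x = x), y)
  b <- fit_logistic(cbind(x = x), 1L - y)
  expect_equal(unname(a$coefficients), -unname(b$coefficients),
               tolerance = 1e-6)
  expect_equal(coefficient_tests(a)$p, coefficient_tests(b)$p,
               tolerance = 1e-6)
})

test_that("predicted probabilities are consistent and monotone", {
  set.seed(4)
  X <- cbind(a = rnorm(100), b = rnorm(100))
  y <- rbinom(100, 1, plogis(X[, 1]))
  fit <- fit_logistic(X, y)
  expect_equal(predict_prob(fit, X), fit$fitted, tolerance = 1e-12)
  # eta = 0 maps to 0.5
  x0 <- cbind(a = -fit$intercept / fit$coefficients["a"], b = 0)
  expect_equal(predict_prob(fit, x0), 0.5, tolerance = 1e-10)
  # monotone in a positive-coefficient predictor
  stopifnot(fit$coefficients["a"] > 0)
  lo <- predict_prob(fit, cbind(a = 0, b = 1))
  hi <- predict_prob(fit, cbind(a = 1, b = 1))
  expect_gt(hi, lo)
  expect_error(predict_prob(fit, cbind(a = 1)), "missing predictor")
})

test_that("affine rescaling of a predictor leaves fit and AUC unchanged", {
  set.seed(5)
  n <- 250
  X <- cbind(u = rnorm(n), v = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 * X[, 1] - 0.3 * X[, 2]))
  f1 <- fit_logistic(X, y)
  X2 <- X
  X2[, "u"] <- 10 * X[, "u"] + 7
  f2 <- fit_logistic(X2, y)
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-6)
  expect_equal(unname(f2$coefficients["u"]),
               unname(f1$coefficients["u"]) / 10, tolerance = 1e-6)
  expect_equal(auc(f2$fitted, y), auc(f1$fitted, y), tolerance = 1e-9)
})

test_that("forward selection enters everything when the cutoff never binds", {
  set.seed(6)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("r", 1:5)))
  y <- rbinom(n, 1, 0.4)
  fs <- forward_select(X, y, entry_p = 1.0)
  expect_setequal(fs$selected, colnames(X))
  expect_true(all(fs$trace$p_value <= 1))
})

test_that("step-1 choice matches brute-force single-predictor enumeration", {
  set.seed(7)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("r", 1:4)))
  y <- rbinom(n, 1, plogis(0.7 * X[, 3]))
  fs <- forward_select(X, y, max_steps = 1)
  # oracle: maximize the likelihood over all single-predictor fits
  lls <- vapply(colnames(X), function(nm) {
    fit_logistic(X[, nm, drop = FALSE], y)$log_likelihood
  }, numeric(1))
  expect_equal(fs$selected[1], names(which.max(lls)))
})

test_that("selection is deterministic and respects the entry cutoff", {
  set.seed(8)
  n <- 140
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("r", 1:8)))
  y <- rbinom(n, 1, plogis(0.8 * X[, 2]))
  a <- forward_select(X, y, entry_p = 0.25)
  b <- forward_select(X, y, entry_p = 0.25)
  expect_identical(a$selected, b$selected)
  expect_identical(a$trace, b$trace)
  expect_true(all(a$trace$p_value <= 0.25))
})

test_that("score and LRT entry tests agree on a strong first predictor", {
  set.seed(9)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  y <- rbinom(n, 1, plogis(1.2 * X[, 4]))
  a <- forward_select(X, y, max_steps = 1, method = "lrt")
  b <- forward_select(X, y, max_steps = 1, method = "score")
  expect_identical(a$selected, b$selected)
})

test_that("a separating candidate halts the selection path stably", {
  set.seed(10)
  n <- 60
  sep <- c(rep(-1, 30), rep(1, 30)) + rnorm(n, sd = 0.01)
  X <- cbind(perfect = sep, noise = rnorm(n))
  y <- as.integer(sep > 0)
  fs <- forward_select(X, y)
  expect_true(fs$separation_stop)
  expect_false("perfect" %in% fs$selected)
  expect_false(fs$model$separation)
})

test_that("forced-in covariates stay in the model and are not selected", {
  set.seed(11)
  n <- 180
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("r", 1:5)))
  cv <- cbind(age = rnorm(n, 75, 3))
  y <- rbinom(n, 1, plogis(0.9 * X[, 1]))
  fs <- forward_select(X, y, covariates = cv)
  expect_true("age" %in% names(fs$model$coefficients))
  expect_false("age" %in% fs$selected)
})
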