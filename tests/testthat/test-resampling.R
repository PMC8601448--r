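# Cheap model builder for permutation tests: fixed scores, ignoring labels.
fixed_score_builder <- function(X, y) X[, 1]

test_that("permutation alpha follows the add-one formula exactly", {
  set.seed(1)
  n <- 40
  X <- cbind(score = rnorm(n))
  y <- rep(c(0L, 1L), n / 2)
  pr <- permutation_alpha(X, y, fixed_score_builder, K = 99, seed = 5)
  expect_length(pr$null_aucs, 99)
  r <- sum(pr$null_aucs >= pr$observed_auc, na.rm = TRUE)
  expect_equal(pr$alpha, (1 + r) / (99 - pr$failed_iterations + 1))
  expect_gt(pr$alpha, 0)

  # identical seed reproduces the null sample
  pr2 <- permutation_alpha(X, y, fixed_score_builder, K = 99, seed = 5)
  expect_identical(pr$null_aucs, pr2$null_aucs)
})

test_that("an unbeatable observed AUC floors alpha at 1/(K+1)", {
  n <- 40
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(score = y)  # scores equal to the unshuffled labels
  pr <- permutation_alpha(X, y, fixed_score_builder, K = 99, seed = 2)
  expect_equal(pr$observed_auc, 1)
  expect_equal(pr$alpha, 1 / 100)
})

test_that("degenerate constant scores give alpha 1", {
  n <- 30
  y <- rep(c(0L, 1L), 15)
  X <- cbind(score = rep(1, n))
  pr <- permutation_alpha(X, y, fixed_score_builder, K = 49, seed = 3)
  expect_equal(pr$observed_auc, 0.5)
  expect_equal(pr$alpha, 1)
})

test_that("alpha is roughly uniform under the null", {
  set.seed(4)
  alphas <- vapply(1:30, function(i) {
    n <- 30
    X <- cbind(score = rnorm(n))
    y <- rep(c(0L, 1L), n / 2)[sample(n)]
    permutation_alpha(X, y, fixed_score_builder, K = 99, seed = i)$alpha
  }, numeric(1))
  expect_gt(mean(alphas), 0.38)
  expect_lt(mean(alphas), 0.62)
})

test_that("failed permutation iterations are excluded from the denominator", {
  n <- 30
  y <- rep(c(0L, 1L), 15)
  X <- cbind(score = rnorm(n))
  flaky <- local({
    calls <- 0
    function(X, y) {
      calls <<- calls + 1
      if (calls %% 4 == 0) stop("fit failed")
      X[, 1]
    }
  })
  pr <- permutation_alpha(X, y, flaky, K = 40, seed = 6)
  expect_gt(pr$failed_iterations, 0)
  r <- sum(pr$null_aucs >= pr$observed_auc, na.rm = TRUE)
  expect_equal(pr$alpha, (1 + r) / (40 - pr$failed_iterations + 1))
})

test_that("a single bootstrap iteration yields 0/1 indicator frequencies", {
  set.seed(7)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("r", 1:6)))
  y <- rbinom(n, 1, plogis(1.2 * X[, 2]))
  bs <- bootstrap_selection_frequency(X, y, B = 1, seed = 9)
  expect_true(all(bs$profile$frequency %in% c(0, 1)))
})

test_that("bootstrap frequencies find a planted predictor", {
  coh <- small_cohort(n = 250, seed = 12, signal = "L_entorhinal",
                      effect = 1.0)
  X <- thickness_matrix(coh)[, 1:12]  # planted ROI among 11 null ROIs
  y <- as.integer(coh$subjects$is_tcp)
  bs <- bootstrap_selection_frequency(X, y, B = 25, seed = 13)
  prof <- bs$profile
  planted <- prof$frequency[prof$roi == "L_entorhinal"]
  expect_gte(planted, 0.9)
  expect_gt(planted, median(prof$frequency[prof$roi != "L_entorhinal"]))
  expect_equal(prof$frequency,
               prof$selected_count / (bs$B - bs$failed_iterations))
})

test_that("chance baseline collapses and saturates with the entry cutoff", {
  set.seed(14)
  n <- 90
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("r", 1:5)))
  y <- rbinom(n, 1, 0.35)
  tight <- chance_selection_baseline(X, y, B = 15, entry_p = 1e-6, seed = 1)
  expect_true(all(tight == 0))
  loose <- chance_selection_baseline(X, y, B = 15, entry_p = 1.0, seed = 1)
  expect_true(all(loose == 1))
})

test_that("chance frequencies are exchangeable across ROI groups", {
  coh <- small_cohort(n = 200, seed = 15)
  X <- thickness_matrix(coh)
  y <- as.integer(coh$subjects$is_tcp)
  ch <- chance_selection_baseline(X, y, B = 40, seed = 16)
  expect_true(all(ch >= 0 & ch <= 1))
  ks <- suppressWarnings(ks.test(ch[1:31], ch[32:62]))
  expect_gt(ks$p.value, 0.01)
})

test_that("bootstrap frequencies stabilize as B grows", {
  set.seed(17)
  n <- 150
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("r", 1:8)))
  y <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 5]))
  a <- bootstrap_selection_frequency(X, y, B = 150, seed = 18)
  b <- bootstrap_selection_frequency(X, y, B = 150, seed = 19)
  expect_lt(max(abs(a$profile$frequency - b$profile$frequency)), 0.15)
})

test_that("profile shapes are classified by least-squares AIC", {
  chance <- 0.25
  set.seed(20)
  jitter <- function(x) pmin(pmax(x + rnorm(length(x), sd = 0.015), 0), 1)

  # flat hypotheses are exact level sets (sorting noisy flat frequencies
  # manufactures an apparent ramp; see the methods vignette)
  expect_equal(classify_frequency_profile(rep(chance, 62), chance)$label,
               "flat_null")
  expect_equal(classify_frequency_profile(rep(0.6, 62), chance)$label,
               "flat_uniform_signal")

  step <- jitter(c(rep(0.95, 5), rep(chance, 57)))
  expect_equal(classify_frequency_profile(step, chance)$label, "step")

  ramp <- jitter(seq(1.0, chance, length.out = 62))
  expect_equal(classify_frequency_profile(ramp, chance)$label, "gradient")
})
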