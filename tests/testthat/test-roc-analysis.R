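test_that("AUC handles perfect ranking, hand-counted pairs, and ties", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  # positives {0.9, 0.7}, negatives {0.6, 0.8}: 3 wins of 4 pairs
  expect_equal(auc(c(0.9, 0.7, 0.6, 0.8), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals brute-force pairwise counting on small instances", {
  set.seed(1)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(auc(scores, labels), brute_force_auc(scores, labels))
  }
})

test_that("ROC curves are valid and their trapezoid area equals the AUC", {
  r <- roc_curve(c(0.2, 0.9), c(0, 1))
  expect_equal(r$fpr, c(0, 0, 1))
  expect_equal(r$tpr, c(0, 1, 1))
  expect_equal(r$auc, 1)

  set.seed(2)
  scores <- round(rnorm(100), 1)  # ties present
  labels <- rbinom(100, 1, 0.3)
  r <- roc_curve(scores, labels)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(r$auc, auc(scores, labels), tolerance = 1e-12)

  flipped <- roc_curve(-scores, labels)
  expect_equal(flipped$auc, 1 - r$auc, tolerance = 1e-12)
})

test_that("AUC is invariant to monotone transforms and flips with labels", {
  set.seed(3)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.4)
  a <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(auc(qlogis(plogis(scores)), labels), a, tolerance = 1e-9)
  expect_equal(auc(scores, 1 - labels), 1 - a, tolerance = 1e-12)
})

test_that("identical score sets give a unit p-value contrast", {
  set.seed(4)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.4)
  ct <- delong_contrast(scores, scores, labels)
  expect_equal(ct$z, 0)
  expect_equal(ct$p, 1)
  # zero placement variance with unequal AUCs is degenerate
  expect_error(delong_contrast(as.numeric(labels), rep(1, 50), labels),
               "degenerate")
})

test_that("DeLong variance matches explicit placement enumeration", {
  set.seed(5)
  for (rep in 1:10) {
    scores <- rnorm(8)
    labels <- c(1, 1, 1, 0, 0, 0, 0, 0)
    # independent oracle: placements by explicit double loop
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    v10 <- vapply(pos, function(a) {
      mean(vapply(neg, function(b) (a > b) + 0.5 * (a == b), numeric(1)))
    }, numeric(1))
    v01 <- vapply(neg, function(b) {
      mean(vapply(pos, function(a) (a > b) + 0.5 * (a == b), numeric(1)))
    }, numeric(1))
    oracle <- var(v10) / length(pos) + var(v01) / length(neg)
    expect_equal(delong_auc_variance(scores, labels), oracle,
                 tolerance = 1e-12)
  }
})

test_that("DeLong agrees with pROC on variance and paired contrast", {
  skip_if_not_installed("pROC")
  set.seed(6)
  n <- 120
  labels <- rbinom(n, 1, 0.35)
  sa <- rnorm(n) + labels
  sb <- rnorm(n) + 0.5 * labels
  expect_equal(delong_auc_variance(sa, labels),
               as.numeric(pROC::var(pROC::roc(labels, sa, quiet = TRUE))),
               tolerance = 1e-9)
  ct <- delong_contrast(sa, sb, labels)
  pr <- pROC::roc.test(pROC::roc(labels, sa, quiet = TRUE),
                       pROC::roc(labels, sb, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(ct$p, pr$p.value, tolerance = 1e-9)
  expect_equal(abs(ct$z), abs(as.numeric(pr$statistic)), tolerance = 1e-9)
})

test_that("DeLong variance shrinks with sample size", {
  var_at <- function(n, seed) {
    set.seed(seed)
    labels <- rep(c(0, 1), n / 2)
    scores <- rnorm(n) + 0.8 * labels
    delong_auc_variance(scores, labels)
  }
  expect_gt(var_at(50, 1), var_at(5000, 1))
})
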