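#' Permutation-derived significance for an apparent AUC
#'
#' Apparent (in-sample) AUCs of models fit to the same subjects they are
#' evaluated on are optimistic, and more so when predictors are selected
#' from a large pool, so 0.5 is not a valid null. This procedure derives
#' the empirical alpha instead: the TCP labels are shuffled K times and
#' the *entire* model-building procedure (including forward selection,
#' when testing the whole-brain model) is re-run on each shuffle, giving a
#' null distribution of apparent AUCs with the same optimism as the
#' observed one. The reported alpha uses the add-one (Phipson-Smyth)
#' formula `(1 + #[null >= observed]) / (K_ok + 1)` and is never exactly
#' zero.
#'
#' @param X predictor matrix handed to the builder.
#' @param y binary labels.
#' @param model_builder function `(X, y) -> scores` implementing the full
#'   pipeline from data to per-subject scores.
#' @param K number of label permutations.
#' @param seed integer seed; one child seed is drawn per iteration.
#' @return object of class `perm_result`: `observed_auc`, `null_aucs`
#'   (length K, `NA` for failed iterations), `alpha`, `K`,
#'   `failed_iterations`, `seed`.
#' @export
permutation_alpha <- function(X, y, model_builder, K, seed = 1L) {
  stopifnot(K >= 1)
  y <- as.integer(y)
  observed <- auc(model_builder(X, y), y)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, K)
  null_aucs <- rep(NA_real_, K)
  for (i in seq_len(K)) {
    set.seed(iter_seeds[i])
    yp <- sample(y)  # uniform permutation; class counts preserved
    null_aucs[i] <- tryCatch(auc(model_builder(X, yp), yp),
                             error = function(e) NA_real_)
  }
  failed <- sum(is.na(null_aucs))
  k_ok <- K - failed
  if (k_ok == 0L) stop("every permutation iteration failed")
  alpha <- (1 + sum(null_aucs >= observed, na.rm = TRUE)) / (k_ok + 1)
  structure(list(observed_auc = observed, null_aucs = null_aucs,
                 alpha = alpha, K = K, failed_iterations = failed,
                 seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> observed AUC = %.4f, alpha = %.4g (K = %d%s)\n",
              x$observed_auc, x$alpha, x$K,
              if (x$failed_iterations)
                paste0(", ", x$failed_iterations, " failed") else ""))
  invisible(x)
}

# Stratified resample with replacement: n_TCP from the TCP stratum,
# n_non from the rest, preserving the observed class counts.
stratified_indices <- function(y) {
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  c(pos[sample.int(length(pos), length(pos), replace = TRUE)],
    neg[sample.int(length(neg), length(neg), replace = TRUE)])
}

selection_frequency_engine <- function(X, y, B, entry_p, seed, method,
                                       shuffle_labels) {
  stopifnot(B >= 1)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, B)
  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(iter_seeds[b])
    yb <- if (shuffle_labels) sample(y) else y
    idx <- stratified_indices(yb)
    sel <- tryCatch(
      forward_select(X[idx, , drop = FALSE], yb[idx], entry_p = entry_p,
                     method = method),
      error = function(e) NULL
    )
    if (is.null(sel) || sel$separation_stop) {
      failed <- failed + 1L
    } else {
      counts[sel$selected] <- counts[sel$selected] + 1
    }
  }
  if (failed == B) stop("every bootstrap iteration failed")
  list(counts = counts, B = B, failed = failed,
       frequency = counts / (B - failed))
}

#' Bootstrap region-selection frequencies
#'
#' Draws B stratified bootstrap samples (the observed number of TCP and
#' non-TCP subjects, each resampled with replacement within its stratum),
#' re-runs the full forward selection over all ROIs on each sample, and
#' records how often each ROI is entered. Frequencies are normalized by
#' the number of successful iterations; iterations ending in separation
#' or a fit failure are counted as failed and excluded from the
#' denominator.
#'
#' @param X ROI predictor matrix (canonical column order).
#' @param y binary TCP labels.
#' @param B number of bootstrap iterations.
#' @param entry_p forward-selection entry cutoff.
#' @param seed integer seed; one child seed per iteration.
#' @param method entry-test statistic passed to [forward_select()].
#' @return object of class `selection_profile`: data.frame `profile`
#'   (roi, selected_count, frequency, and chance_frequency once
#'   [chance_selection_baseline()] has been attached), plus `B`,
#'   `failed_iterations`, `entry_p`, `seed`.
#' @export
bootstrap_selection_frequency <- function(X, y, B = 1000L, entry_p = 0.25,
                                          seed = 1L, method = "lrt") {
  eng <- selection_frequency_engine(X, y, B, entry_p, seed, method,
                                    shuffle_labels = FALSE)
  structure(list(
    profile = data.frame(roi = colnames(X),
                         selected_count = unname(eng$counts),
                         frequency = unname(eng$frequency),
                         chance_frequency = NA_real_,
                         stringsAsFactors = FALSE),
    B = eng$B, failed_iterations = eng$failed, entry_p = entry_p,
    seed = seed
  ), class = "selection_profile")
}

#' Chance baseline for region-selection frequencies
#'
#' The base rate at which forward selection enters each ROI when the
#' labels carry no information: each iteration shuffles the TCP labels,
#' then repeats the identical stratified-resample + forward-selection
#' procedure. The mean across ROIs is the "horizontal line" a selection
#' profile is judged against.
#'
#' @inheritParams bootstrap_selection_frequency
#' @return named numeric vector of per-ROI chance frequencies, with
#'   attributes `B` and `failed_iterations`.
#' @export
chance_selection_baseline <- function(X, y, B = 1000L, entry_p = 0.25,
                                      seed = 1L, method = "lrt") {
  eng <- selection_frequency_engine(X, y, B, entry_p, seed, method,
                                    shuffle_labels = TRUE)
  structure(eng$frequency, B = eng$B, failed_iterations = eng$failed)
}

#' Attach a chance baseline to a selection profile
#' @param profile a `selection_profile`.
#' @param chance named chance-frequency vector from
#'   [chance_selection_baseline()].
#' @return the profile with `chance_frequency` filled in.
#' @export
attach_chance_baseline <- function(profile, chance) {
  stopifnot(inherits(profile, "selection_profile"))
  profile$profile$chance_frequency <-
    as.numeric(chance[profile$profile$roi])
  profile
}

#' @export
print.selection_profile <- function(x, ...) {
  top <- x$profile[order(-x$profile$frequency), ][1:5, ]
  cat("<selection_profile> B =", x$B,
      if (x$failed_iterations) paste0("(", x$failed_iterations, " failed)"),
      "\n  top ROIs:",
      paste(sprintf("%s %.2f", top$roi, top$frequency), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify the shape of a sorted selection-frequency profile
#'
#' Distinguishes the competing accounts of where predictive value lives:
#' a flat profile at the chance rate (no region informative), a flat
#' profile above chance (all regions equally informative), a two-level
#' step (a localist subset of key regions), or a linear ramp (a smooth
#' gradient of informativeness). Each shape is fit to the
#' descending-sorted frequencies by least squares and the smallest-AIC
#' shape is returned.
#'
#' @param profile a `selection_profile` with a chance baseline attached,
#'   or a numeric frequency vector.
#' @param chance_level chance frequency (scalar); defaults to the mean of
#'   the profile's per-ROI chance baseline.
#' @return object of class `profile_shape`: `label` (one of `flat_null`,
#'   `flat_uniform_signal`, `step`, `gradient`), `aic` (named vector),
#'   `fits` (fitted level parameters), `chance_level`.
#' @export
classify_frequency_profile <- function(profile, chance_level = NULL) {
  if (inherits(profile, "selection_profile")) {
    f <- profile$profile$frequency
    if (is.null(chance_level)) {
      cf <- profile$profile$chance_frequency
      if (all(is.na(cf))) stop("no chance baseline attached; supply chance_level")
      chance_level <- mean(cf, na.rm = TRUE)
    }
  } else {
    f <- as.numeric(profile)
    if (is.null(chance_level)) stop("chance_level required for a bare vector")
  }
  n <- length(f)
  if (n < 4L) stop("profile too short to classify")
  f <- sort(f, decreasing = TRUE)
  i <- seq_len(n)

  rss <- function(resid) max(sum(resid^2), 1e-12)
  aic_of <- function(rss_val, k) n * log(rss_val / n) + 2 * k

  # (a) constant at chance: no free parameters
  aic <- c(flat_null = aic_of(rss(f - chance_level), 0))
  fits <- list(flat_null = chance_level)

  # (b) constant above (or away from) chance: one free level
  aic["flat_uniform_signal"] <- aic_of(rss(f - mean(f)), 1)
  fits$flat_uniform_signal <- mean(f)

  # (c) two-level step: scan the breakpoint
  best <- Inf
  best_fit <- NULL
  for (b in seq_len(n - 1L)) {
    hi <- mean(f[1:b])
    lo <- mean(f[(b + 1):n])
    r <- rss(c(f[1:b] - hi, f[(b + 1):n] - lo))
    if (r < best) {
      best <- r
      best_fit <- c(high = hi, low = lo, breakpoint = b)
    }
  }
  aic["step"] <- aic_of(best, 3)
  fits$step <- best_fit

  # (d) linear ramp
  lin <- stats::lm.fit(cbind(1, i), f)
  aic["gradient"] <- aic_of(rss(lin$residuals), 2)
  fits$gradient <- stats::setNames(lin$coefficients,
                                   c("intercept", "slope"))

  structure(list(label = names(which.min(aic)), aic = aic, fits = fits,
                 chance_level = chance_level),
            class = "profile_shape")
}

#' @export
print.profile_shape <- function(x, ...) {
  cat("<profile_shape>", x$label, "\n  AIC:",
      paste(sprintf("%s %.1f", names(x$aic), x$aic), collapse = ", "), "\n")
  invisible(x)
}
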