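#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The fraction of (positive, negative) subject pairs where the positive
#' scores higher, ties counted 1/2 — identical to the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (logical or 0/1).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties counted 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (plus the two
#' endpoints): at threshold t, TPR and FPR are the fractions of positives
#' and negatives scoring at or above t. The trapezoidal area under the
#' resulting curve equals the Mann-Whitney [auc()] exactly.
#'
#' @inheritParams auc
#' @return object of class `tcp_roc`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n_neg, numeric(1))
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = area,
                 n_pos = n_pos, n_neg = n_neg), class = "tcp_roc")
}

#' @export
print.tcp_roc <- function(x, ...) {
  cat("<tcp_roc> AUC =", format(x$auc, digits = 4),
      "(", x$n_pos, "pos /", x$n_neg, "neg )\n")
  invisible(x)
}

# DeLong placement values: for each positive, the mean of psi against all
# negatives (V10); for each negative, against all positives (V01), where
# psi is 1 / 0.5 / 0 for win / tie / loss of the positive.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi))
}

#' DeLong variance of a single AUC
#'
#' `var(V10)/m + var(V01)/n` from the placement values, with m positives
#' and n negatives.
#'
#' @inheritParams auc
#' @return estimated variance of the AUC.
#' @export
delong_auc_variance <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pl <- delong_placements(scores, labels)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' DeLong contrast of two correlated AUCs
#'
#' Compares the AUCs of two score sets over the same subjects (e.g. the
#' cingulate and whole-brain models' fitted probabilities) using the
#' DeLong placement-value covariance for paired ROC curves:
#' `z = (auc_a - auc_b) / SE(diff)` against a two-sided normal reference.
#'
#' @param scores_a,scores_b two score vectors over the same subjects.
#' @param labels shared binary labels.
#' @return object of class `auc_contrast`: `auc_a`, `auc_b`, `var_diff`,
#'   `z`, `p`.
#' @export
delong_contrast <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (var_diff <= 1e-16) {
    if (abs(diff) <= 1e-12) {
      return(structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = 0,
                            z = 0, p = 1), class = "auc_contrast"))
    }
    stop("degenerate scores: zero variance of the AUC difference")
  }
  z <- diff / sqrt(var_diff)
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "auc_contrast")
}

#' @export
print.auc_contrast <- function(x, ...) {
  cat(sprintf("<auc_contrast> %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}
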