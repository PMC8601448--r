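#' Maximum-likelihood logistic regression
#'
#' Fits `logit P(y = 1) = b0 + X b` by iteratively reweighted least
#' squares (via [stats::glm.fit()]), with a log-likelihood convergence
#' tolerance of 1e-8 and at most 100 iterations. Complete or
#' quasi-complete separation is detected (boundary fitted probabilities /
#' vanishing deviance / non-convergence) and flagged rather than thrown:
#' the model is returned with `separation = TRUE`, `converged = FALSE`
#' and coefficients capped at +/- 1000 on the input scale.
#'
#' @param X predictor matrix (subjects x predictors) with column names,
#'   or `NULL` for an intercept-only model.
#' @param y binary outcome (logical or 0/1); both classes must be present.
#' @return object of class `tcp_logit`: `predictor_names`, `intercept`,
#'   `coefficients` (named, input scale), `log_likelihood`, `deviance`,
#'   `converged`, `separation`, `n_used`, `fitted`, `vcov` (observed
#'   information inverse, intercept first), and the outcome `y`.
#' @export
fit_logistic <- function(X, y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != length(y)) stop("X and y sizes differ")
    if (length(y) < ncol(X) + 2L) stop("too few rows for ", ncol(X),
                                       " predictors")
  }
  Xa <- cbind(`(intercept)` = rep(1, length(y)), X)

  warns <- character(0)
  fit <- withCallingHandlers(
    stats::glm.fit(Xa, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  separation <- isTRUE(fit$boundary) || !fit$converged ||
    any(grepl("numerically 0 or 1", warns)) || fit$deviance < 1e-7

  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # aliased columns in a rank-deficient design
  if (separation) beta <- sign(beta) * pmin(abs(beta), 1000)
  mu <- as.numeric(stats::plogis(drop(Xa %*% beta)))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))

  w <- mu * (1 - mu)
  info <- crossprod(Xa * w, Xa)
  vcov <- tryCatch(solve(info), error = function(e) NULL)

  structure(list(
    predictor_names = colnames(X),
    intercept = unname(beta[1]),
    coefficients = beta[-1],
    log_likelihood = ll,
    deviance = -2 * ll,
    converged = fit$converged && !separation,
    separation = separation,
    n_used = length(y),
    fitted = mu,
    vcov = vcov,
    y = y
  ), class = "tcp_logit")
}

#' @export
print.tcp_logit <- function(x, ...) {
  cat(model_equation(x), "\n")
  cat("n =", x$n_used, "| logLik =", format(x$log_likelihood, digits = 6))
  if (x$separation) cat(" | SEPARATION FLAGGED")
  cat("\n")
  invisible(x)
}

#' Report a fitted model as a logit equation string
#' @param model a `tcp_logit`.
#' @return character, e.g. `"Logit(TCP) = -4.13 + 0.48 x_L_...\"`.
#' @export
model_equation <- function(model) {
  terms <- sprintf("%s %.2f x_%s",
                   ifelse(model$coefficients < 0, "-", "+"),
                   abs(model$coefficients), names(model$coefficients))
  paste(c(sprintf("Logit(TCP) = %.2f", model$intercept), terms),
        collapse = " ")
}

#' Wald tests of logistic coefficients
#'
#' z = beta / SE with SEs from the inverse observed information;
#' two-sided normal p-values.
#'
#' @param model a converged `tcp_logit`.
#' @return data.frame with `term`, `estimate`, `se`, `z`, `p` (intercept
#'   first).
#' @export
coefficient_tests <- function(model) {
  stopifnot(inherits(model, "tcp_logit"))
  if (!model$converged) stop("coefficient tests need a converged model")
  if (is.null(model$vcov)) stop("singular information matrix")
  est <- c(model$intercept, model$coefficients)
  se <- sqrt(diag(model$vcov))
  z <- est / se
  data.frame(term = c("(intercept)", model$predictor_names),
             estimate = unname(est), se = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Predicted probabilities from a fitted model
#'
#' @param model a `tcp_logit`.
#' @param X new predictor matrix whose columns match
#'   `model$predictor_names` (any order; matched by name).
#' @return fitted probabilities in (0, 1).
#' @export
predict_prob <- function(model, X = NULL) {
  if (is.null(model$predictor_names)) {
    n <- if (is.null(X)) 1L else nrow(X)
    return(rep(stats::plogis(model$intercept), n))
  }
  X <- as.matrix(X)
  if (!all(model$predictor_names %in% colnames(X))) {
    stop("X is missing predictor column(s): ",
         paste(setdiff(model$predictor_names, colnames(X)), collapse = ", "))
  }
  X <- X[, model$predictor_names, drop = FALSE]
  as.numeric(stats::plogis(model$intercept + drop(X %*% model$coefficients)))
}

# Lean deviance-only refit used inside selection scans. `start` warm-starts
# IRLS from the current model's coefficients (new column at 0).
logit_deviance <- function(Xa, y, start = NULL) {
  fit <- suppressWarnings(
    stats::glm.fit(Xa, y, family = stats::binomial(), start = start,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  fit$deviance
}

# Vectorized Rao score test p-values for adding each candidate column to
# the current fit. Z is the current design (with intercept), mu its
# fitted values, Xc the candidate columns.
score_test_p <- function(Z, mu, y, Xc) {
  w <- mu * (1 - mu)
  U <- colSums(Xc * (y - mu))
  WZ <- Z * w
  B <- crossprod(WZ, Xc)                      # Z'W Xc
  V <- colSums(Xc * Xc * w) - colSums(B * solve(crossprod(Z, WZ), B))
  stat <- U^2 / pmax(V, 1e-300)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Forward-selection logistic regression
#'
#' Starts from the intercept-only model (plus any forced-in covariates)
#' and, at each step, tests every excluded predictor for entry. The
#' default entry statistic is the likelihood-ratio chi-square for adding
#' the predictor (`method = "score"` uses the Rao score test, the classic
#' stepwise-software criterion, without refitting per candidate). The
#' candidate with the smallest p-value enters if p <= `entry_p`; ties are
#' broken by canonical column order. Selection stops when no candidate
#' qualifies; entered predictors are never removed. If the best
#' candidate's fit hits separation the path stops at the last stable
#' model with `separation_stop = TRUE`.
#'
#' @param X predictor matrix (e.g. subjects x 62 ROI thicknesses), columns
#'   in canonical order.
#' @param y binary outcome.
#' @param entry_p entry cutoff for the addition test p-value; default 0.25.
#' @param covariates optional matrix of forced-in (unselected) covariates.
#' @param method `"lrt"` (default) or `"score"`.
#' @param max_steps optional cap on the number of predictors entered.
#' @return object of class `forward_selection`: `model` (final
#'   `tcp_logit` over covariates + selected ROIs), `selected` (in entry
#'   order), `trace` (data.frame: step, chosen, p_value, n_candidates),
#'   `candidate_p` (list of per-step named p-value vectors), `entry_p`,
#'   `separation_stop`.
#' @export
forward_select <- function(X, y, entry_p = 0.25, covariates = NULL,
                           method = c("lrt", "score"), max_steps = Inf) {
  method <- match.arg(method)
  stopifnot(entry_p > 0, entry_p <= 1)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)

  build <- function(sel) {
    cols <- cbind(covariates, X[, sel, drop = FALSE])
    if (ncol(cols) == 0L) cols <- NULL
    fit_logistic(cols, y)
  }

  selected <- character(0)
  current <- build(selected)
  trace <- list()
  candidate_p <- list()
  separation_stop <- FALSE

  if (current$separation) {
    separation_stop <- TRUE
  } else {
    repeat {
      candidates <- setdiff(colnames(X), selected)
      if (length(candidates) == 0L || length(selected) >= max_steps) break
      dev0 <- current$deviance
      if (method == "lrt") {
        warm <- unname(c(current$intercept, current$coefficients, 0))
        pvals <- vapply(candidates, function(nm) {
          Xa <- cbind(1, covariates, X[, c(selected, nm), drop = FALSE])
          dev1 <- logit_deviance(Xa, y, start = warm)
          stats::pchisq(max(dev0 - dev1, 0), df = 1, lower.tail = FALSE)
        }, numeric(1))
      } else {
        Z <- cbind(1, covariates, X[, selected, drop = FALSE])
        pvals <- score_test_p(Z, current$fitted, y,
                              X[, candidates, drop = FALSE])
        names(pvals) <- candidates
      }
      best <- candidates[which.min(pvals)]  # tie: first in canonical order
      step_i <- length(selected) + 1L
      candidate_p[[step_i]] <- pvals
      if (pvals[best] > entry_p) break
      candidate_fit <- build(c(selected, best))
      if (candidate_fit$separation) {
        separation_stop <- TRUE
        break
      }
      selected <- c(selected, best)
      current <- candidate_fit
      trace[[step_i]] <- data.frame(step = step_i, chosen = best,
                                    p_value = unname(pvals[best]),
                                    n_candidates = length(candidates),
                                    stringsAsFactors = FALSE)
    }
  }

  structure(list(
    model = current,
    selected = selected,
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(step = integer(0), chosen = character(0),
                 p_value = numeric(0), n_candidates = integer(0)),
    candidate_p = candidate_p,
    entry_p = entry_p,
    method = method,
    separation_stop = separation_stop
  ), class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("<forward_selection> ", length(x$selected), " predictor(s) entered",
      if (x$separation_stop) " [stopped at separation]", "\n", sep = "")
  if (length(x$selected)) {
    cat(paste(sprintf("  %d. %s (p = %.3g)", x$trace$step, x$trace$chosen,
                      x$trace$p_value), collapse = "\n"), "\n")
  }
  invisible(x)
}
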