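#' Pooled two-sample t-test from summary statistics
#'
#' Student's unpaired t-test with pooled variance, computed directly from
#' per-group mean, SD and n — the form whose degrees of freedom are
#' `n_a + n_b - 2`. This is the path for recomputing published
#' demographic comparisons from table summaries.
#'
#' @param mean_a,sd_a,n_a group A summary.
#' @param mean_b,sd_b,n_b group B summary.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
pooled_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (sp2 == 0) {
    if (mean_a == mean_b) stop("undefined t: zero variance and equal means")
    stop("undefined t: zero pooled variance with unequal means")
  }
  t_stat <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  df <- n_a + n_b - 2
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Pooled two-sample t-test from raw data
#'
#' Identical to [pooled_t_from_summary()] applied to the computed group
#' summaries (and therefore to `t.test(..., var.equal = TRUE)`).
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
t_from_raw <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  pooled_t_from_summary(mean(values_a), stats::sd(values_a), length(values_a),
                        mean(values_b), stats::sd(values_b), length(values_b))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass method: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more
#' probable than the observed one. A table with a zero margin carries no
#' information about association; by convention p = 1, with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: Fisher's exact p set to 1 by convention")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Pearson chi-square test for an r x c table
#'
#' Uncorrected Pearson statistic with expected counts from the margins;
#' df = (r-1)(c-1). Used for multi-level categorical demographics such as
#' a 3-level education variable.
#'
#' @param table r x c matrix of non-negative counts (r, c >= 2).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_rxc <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: chi-square expected counts undefined")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Demographic comparison of TCP vs non-TCP groups
#'
#' Builds the standard cohort-description report: per-group mean (SD) for
#' continuous variables with a pooled t-test, and counts (%) for sex with
#' Fisher's exact test. For categorical education (90+ style) a chi-square
#' test is used; for years of education, a t-test.
#'
#' @param cohort a labeled `tcp_cohort` (see [label_cohort()]).
#' @return data.frame with one row per variable: group summaries, test
#'   name, statistic, df (where defined) and p-value.
#' @export
demographics_table <- function(cohort) {
  subj <- cohort$subjects
  if (is.null(subj$is_tcp)) stop("cohort is not labeled; run label_cohort()")
  tcp <- subj[subj$is_tcp, ]
  non <- subj[!subj$is_tcp, ]
  msd <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  rows <- list()

  tt <- t_from_raw(tcp$age, non$age)
  rows$age <- data.frame(variable = "age", tcp = msd(tcp$age),
                         non_tcp = msd(non$age), test = "pooled t",
                         statistic = tt$t, df = tt$df, p = tt$p)

  sex_tab <- rbind(tcp = table(factor(tcp$sex, c("F", "M"))),
                   non_tcp = table(factor(non$sex, c("F", "M"))))
  pf <- fisher_exact_2x2(sex_tab)
  pct <- function(d) sprintf("%d (%.1f%%)", sum(d$sex == "F"),
                             100 * mean(d$sex == "F"))
  rows$sex <- data.frame(variable = "female", tcp = pct(tcp),
                         non_tcp = pct(non), test = "Fisher exact",
                         statistic = NA_real_, df = NA_real_, p = pf)

  if (is.numeric(subj$education)) {
    te <- t_from_raw(tcp$education, non$education)
    rows$edu <- data.frame(variable = "education_years",
                           tcp = msd(tcp$education),
                           non_tcp = msd(non$education), test = "pooled t",
                           statistic = te$t, df = te$df, p = te$p)
  } else {
    lv <- sort(unique(subj$education))
    tab <- rbind(table(factor(tcp$education, lv)),
                 table(factor(non$education, lv)))
    ce <- chi_square_rxc(tab)
    rows$edu <- data.frame(variable = "education_level",
                           tcp = paste(table(factor(tcp$education, lv)),
                                       collapse = "/"),
                           non_tcp = paste(table(factor(non$education, lv)),
                                           collapse = "/"),
                           test = "chi-square", statistic = ce$statistic,
                           df = ce$df, p = ce$p)
  }

  gt <- cohort_global_thickness(cohort)
  tg <- t_from_raw(gt[subj$is_tcp], gt[!subj$is_tcp])
  rows$glob <- data.frame(variable = "global_thickness",
                          tcp = msd(gt[subj$is_tcp]),
                          non_tcp = msd(gt[!subj$is_tcp]), test = "pooled t",
                          statistic = tg$t, df = tg$df, p = tg$p)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
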