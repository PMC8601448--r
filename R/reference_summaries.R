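#' Published demographic summaries of the two aging cohorts
#'
#' Per-group summary statistics (mean, SD, n for continuous variables;
#' counts per level for categorical ones) of the TCP and non-TCP groups
#' in the NACC 70-89 analysis sample and The 90+ Study sample, as
#' published in the cohorts' demographic tables. These summaries are the
#' inputs for recomputing the reported group comparisons (pooled t,
#' Fisher's exact, chi-square) without access to the restricted
#' subject-level data.
#'
#' @return list with data.frames `continuous` (cohort, age_group,
#'   variable, group, mean, sd, n) and `categorical` (cohort, age_group,
#'   variable, level, tcp, non_tcp).
#' @export
reference_demographics <- function() {
  path <- function(f) system.file("extdata", f, package = "tcpthick",
                                  mustWork = TRUE)
  list(
    continuous = utils::read.csv(path("cohort_summary_continuous.csv"),
                                 stringsAsFactors = FALSE),
    categorical = utils::read.csv(path("cohort_summary_categorical.csv"),
                                  stringsAsFactors = FALSE)
  )
}

#' Recompute the published group comparisons from summary statistics
#'
#' Runs the pooled t-test on every continuous summary pair, Fisher's
#' exact test on every 2x2 sex table and the uncorrected chi-square on
#' the 3-level education table from [reference_demographics()].
#'
#' @return data.frame: cohort, age_group, variable, test, statistic, df, p.
#' @export
reference_group_tests <- function() {
  ref <- reference_demographics()
  rows <- list()
  cont <- ref$continuous
  keys <- unique(cont[, c("cohort", "age_group", "variable")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- merge(k, cont)
    a <- sub[sub$group == "TCP", ]
    b <- sub[sub$group == "non-TCP", ]
    tt <- pooled_t_from_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
    rows[[length(rows) + 1L]] <-
      data.frame(k, test = "pooled t", statistic = tt$t, df = tt$df,
                 p = tt$p)
  }
  cat_ <- ref$categorical
  keys <- unique(cat_[, c("cohort", "age_group", "variable")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- merge(k, cat_)
    tab <- t(as.matrix(sub[, c("tcp", "non_tcp")]))
    if (nrow(sub) == 2L) {
      rows[[length(rows) + 1L]] <-
        data.frame(k, test = "Fisher exact", statistic = NA_real_,
                   df = NA_real_, p = fisher_exact_2x2(tab))
    } else {
      cs <- chi_square_rxc(tab)
      rows[[length(rows) + 1L]] <-
        data.frame(k, test = "chi-square", statistic = cs$statistic,
                   df = cs$df, p = cs$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
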