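#' TCP labeling criteria
#'
#' Top Cognitive Performers are subjects at or above the 50th percentile
#' on both a delayed-recall memory score (higher is better) and Trails-B
#' completion time (lower is better). Percentiles are computed within the
#' analyzed sample, either against the whole cohort or within the
#' subject's age decade. For cohorts with repeated visits, the basis score
#' can be the median over up to `max_visits` visits closest to the scan
#' date instead of the single baseline score.
#'
#' @param percentile_cutoff passing percentile; 50 for the TCP definition,
#'   parameterized for sensitivity analyses.
#' @param reference `"within_cohort"` or `"within_age_group"` (decade bins).
#' @param use_visit_median if `TRUE`, basis scores are medians of the
#'   visits closest to the scan date.
#' @param max_visits maximum visits entering the median.
#' @return object of class `tcp_criteria`.
#' @export
tcp_criteria <- function(percentile_cutoff = 50,
                         reference = c("within_cohort", "within_age_group"),
                         use_visit_median = FALSE,
                         max_visits = 4L) {
  reference <- match.arg(reference)
  stopifnot(percentile_cutoff > 0, percentile_cutoff <= 100, max_visits >= 1)
  structure(list(percentile_cutoff = percentile_cutoff, reference = reference,
                 use_visit_median = use_visit_median,
                 max_visits = as.integer(max_visits)),
            class = "tcp_criteria")
}

#' Median score over the visits closest to the scan date
#'
#' Selects up to `max_visits` visits with the smallest absolute day offset
#' from the scan date and returns the median of their scores (mean of the
#' middle two for an even count). Offset ties competing for the last slot
#' are resolved in favor of the earlier visit date.
#'
#' @param dates visit dates (`Date` or coercible).
#' @param scores numeric scores, same length as `dates`.
#' @param scan_date scan date.
#' @param max_visits maximum number of visits used.
#' @return the median basis score.
#' @export
median_score_near_scan <- function(dates, scores, scan_date, max_visits = 4L) {
  if (length(dates) == 0L) stop("no visits available")
  stopifnot(length(dates) == length(scores))
  dates <- as.Date(dates)
  offset <- abs(as.numeric(dates - as.Date(scan_date)))
  ord <- order(offset, dates)  # tie on |offset|: earlier date wins
  keep <- ord[seq_len(min(max_visits, length(ord)))]
  stats::median(scores[keep])
}

#' Percentile rank of a score within a reference sample
#'
#' The fraction of reference scores the value performs at-or-better-than,
#' times 100. "Better" is `>=` for `higher_better` scores (memory) and
#' `<=` for `lower_better` scores (Trails-B completion time).
#'
#' @param reference_scores numeric reference sample (non-empty).
#' @param value score to rank.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return percentile in \[0, 100\].
#' @export
percentile_rank <- function(reference_scores, value,
                            direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (length(reference_scores) == 0L) stop("reference sample is empty")
  at_or_better <- if (direction == "higher_better") {
    value >= reference_scores
  } else {
    value <= reference_scores
  }
  100 * mean(at_or_better)
}

basis_scores <- function(cohort, criteria) {
  subj <- cohort$subjects
  if (!criteria$use_visit_median) {
    return(data.frame(subject_id = subj$subject_id,
                      memory = subj$memory_score,
                      trails = subj$trails_b_time,
                      stringsAsFactors = FALSE))
  }
  if (is.null(cohort$visits) || nrow(cohort$visits) == 0L) {
    stop("visit-median basis scores requested but the cohort has no visits")
  }
  vs <- split(cohort$visits, cohort$visits$subject_id)
  mem <- trl <- numeric(nrow(subj))
  for (i in seq_len(nrow(subj))) {
    v <- vs[[subj$subject_id[i]]]
    if (is.null(v)) stop("no visits for subject ", subj$subject_id[i])
    mem[i] <- median_score_near_scan(v$visit_date, v$memory_score,
                                     subj$scan_date[i], criteria$max_visits)
    trl[i] <- median_score_near_scan(v$visit_date, v$trails_b_time,
                                     subj$scan_date[i], criteria$max_visits)
  }
  data.frame(subject_id = subj$subject_id, memory = mem, trails = trl,
             stringsAsFactors = FALSE)
}

#' Label each subject TCP / non-TCP
#'
#' A subject is a Top Cognitive Performer iff both the memory percentile
#' and the Trails-B percentile (against the designated reference group,
#' self included) are at or above the cutoff. Subjects failing either
#' criterion are non-TCP.
#'
#' @param cohort a `tcp_cohort`.
#' @param criteria a [tcp_criteria()].
#' @return data.frame with `subject_id`, `is_tcp`, `memory_percentile`,
#'   `trails_percentile`, and the basis scores used (`memory_basis`,
#'   `trails_basis`).
#' @export
classify_tcp <- function(cohort, criteria = tcp_criteria()) {
  basis <- basis_scores(cohort, criteria)
  if (anyNA(basis$memory) || anyNA(basis$trails)) {
    stop("criteria variables contain missing values; apply exclusions first")
  }
  group <- if (criteria$reference == "within_age_group") {
    paste0(floor(cohort$subjects$age / 10) * 10, "s")
  } else {
    rep("cohort", nrow(basis))
  }
  mem_pct <- trl_pct <- numeric(nrow(basis))
  for (g in unique(group)) {
    sel <- group == g
    if (sum(sel) < 2L) {
      stop("reference group '", g, "' has fewer than 2 subjects")
    }
    mem_ref <- basis$memory[sel]
    trl_ref <- basis$trails[sel]
    mem_pct[sel] <- vapply(basis$memory[sel], percentile_rank,
                           numeric(1), reference_scores = mem_ref,
                           direction = "higher_better")
    trl_pct[sel] <- vapply(basis$trails[sel], percentile_rank,
                           numeric(1), reference_scores = trl_ref,
                           direction = "lower_better")
  }
  data.frame(
    subject_id = basis$subject_id,
    is_tcp = mem_pct >= criteria$percentile_cutoff &
      trl_pct >= criteria$percentile_cutoff,
    memory_percentile = mem_pct,
    trails_percentile = trl_pct,
    memory_basis = basis$memory,
    trails_basis = basis$trails,
    stringsAsFactors = FALSE
  )
}

#' Attach TCP labels to a cohort
#'
#' Runs [classify_tcp()] and stores the result: adds an `is_tcp` column to
#' `cohort$subjects` and keeps the full label table as `cohort$tcp_labels`.
#' Errors if labeling is degenerate (all or no subjects TCP).
#'
#' @inheritParams classify_tcp
#' @return the cohort with labels attached.
#' @export
label_cohort <- function(cohort, criteria = tcp_criteria()) {
  labels <- classify_tcp(cohort, criteria)
  n_tcp <- sum(labels$is_tcp)
  if (n_tcp == 0L || n_tcp == nrow(labels)) {
    stop("degenerate labeling: ", n_tcp, " of ", nrow(labels),
         " subjects TCP")
  }
  cohort$subjects$is_tcp <- labels$is_tcp
  cohort$tcp_labels <- labels
  cohort
}
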