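#' Analysis run configuration
#'
#' Bundles the tunable parameters of a full TCP analysis run. Defaults
#' are the headline analysis settings: the six bilateral a priori
#' cingulate ROIs, a forward-selection entry cutoff of p = 0.25, 10,000
#' label permutations and 1,000 bootstrap iterations.
#'
#' @param cingulate_rois the a priori ROI set (6 labels).
#' @param entry_p forward-selection entry cutoff in (0, 1].
#' @param n_permutations permutation count for the AUC null.
#' @param n_bootstrap bootstrap count for selection frequencies.
#' @param seed integer seed for all resampling.
#' @param age_group optional decade filter (`"70s"`, `"80s"`, `"90s"`).
#' @param covariates covariate flags, subset of
#'   `c("age", "sex", "education")`, appended post hoc to selected models.
#' @return object of class `run_config`.
#' @export
run_config <- function(cingulate_rois = cingulate_roi_set(),
                       entry_p = 0.25,
                       n_permutations = 10000L,
                       n_bootstrap = 1000L,
                       seed = 1L,
                       age_group = NULL,
                       covariates = character(0)) {
  stopifnot(entry_p > 0, entry_p <= 1, n_permutations >= 1, n_bootstrap >= 1,
            length(cingulate_rois) == 6L,
            all(covariates %in% c("age", "sex", "education")))
  if (!is.null(age_group)) {
    age_group <- match.arg(age_group, c("70s", "80s", "90s"))
  }
  structure(list(cingulate_rois = cingulate_rois, entry_p = entry_p,
                 n_permutations = as.integer(n_permutations),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), age_group = age_group,
                 covariates = covariates),
            class = "run_config")
}

#' Write a run configuration as JSON
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(cingulate_rois = x$cingulate_rois, entry_p = x$entry_p,
             n_permutations = x$n_permutations,
             n_bootstrap = x$n_bootstrap, seed = x$seed,
             age_group = x$age_group,
             covariates = if (length(x$covariates)) x$covariates
                          else character(0))
}

#' Write a cohort to disk
#'
#' Emits `cohort.csv` (one row per subject: demographics, basis cognitive
#' scores, scan date, one thickness column per ROI named by DKT label
#' with an `L_`/`R_` prefix, and `vol_`-prefixed volume columns),
#' `visits.csv`, and a JSON snapshot of the generating configuration when
#' the cohort carries one.
#'
#' @param cohort a `tcp_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             visits = file.path(dir, "visits.csv"),
             config = file.path(dir, "config.json"))
  utils::write.csv(cohort$subjects, paths["cohort"], row.names = FALSE)
  if (!is.null(cohort$visits)) {
    utils::write.csv(cohort$visits, paths["visits"], row.names = FALSE)
  }
  if (inherits(cohort$config, "synthetic_config")) {
    cfg <- unclass(cohort$config)
    cfg$mean_thickness <- as.list(cfg$mean_thickness)
    jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(paths)
}

required_subject_columns <- c("subject_id", "age", "sex", "education",
                              "memory_score", "trails_b_time", "scan_date")
criteria_variables <- c("memory_score", "trails_b_time")

#' Read a cohort from CSV
#'
#' Validates the schema strictly: every required demographic/score column
#' and all 62 ROI thickness columns must be present (a missing column is
#' a schema error naming it), thickness columns must parse as numeric (a
#' parse error reports the offending row), and ROI columns are reordered
#' to the canonical label order so model coefficients are order-stable.
#' Rows with missing criteria variables (memory score, Trails-B time) or
#' missing thickness are flagged in the returned cohort's `flags` table,
#' not dropped — see [apply_exclusions()].
#'
#' @param path cohort CSV path.
#' @param visits_path optional visits CSV path.
#' @param roi_names canonical ROI label set.
#' @return a `tcp_cohort` with a `flags` data.frame
#'   (`subject_id`, `reason`) listing rows with missing data.
#' @export
read_cohort <- function(path, visits_path = NULL,
                        roi_names = dkt_roi_names()) {
  subj <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  missing_cols <- setdiff(c(required_subject_columns, roi_names),
                          names(subj))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (rc in roi_names) {
    col <- subj[[rc]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      stop("parse error: non-numeric thickness in column ", rc,
           " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  # canonical column order: metadata, thickness, volumes, rest
  vol_cols <- intersect(paste0("vol_", roi_names), names(subj))
  rest <- setdiff(names(subj),
                  c(required_subject_columns, roi_names, vol_cols))
  subj <- subj[, c(required_subject_columns, roi_names, vol_cols, rest)]
  subj$scan_date <- as.Date(subj$scan_date)

  miss_crit <- rowSums(is.na(subj[, criteria_variables])) > 0
  miss_thk <- rowSums(is.na(subj[, roi_names])) > 0
  flagged <- miss_crit | miss_thk
  flags <- data.frame(
    subject_id = subj$subject_id[flagged],
    reason = ifelse(miss_crit[flagged], "missing criteria variable",
                    "missing ROI thickness"),
    stringsAsFactors = FALSE
  )

  visits <- NULL
  if (!is.null(visits_path)) {
    visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                              na.strings = c("", "NA"))
    visits$visit_date <- as.Date(visits$visit_date)
  }

  structure(list(subjects = subj, visits = visits, roi_names = roi_names,
                 config = list(source = path), flags = flags),
            class = "tcp_cohort")
}

#' Apply listwise exclusions
#'
#' Drops subjects flagged for missing data in any criteria variable (or
#' missing thickness) and records an exclusion log. Errors if no subjects
#' survive.
#'
#' @param cohort a `tcp_cohort` (flags as produced by [read_cohort()];
#'   a cohort without a `flags` table is returned unchanged).
#' @return the cohort restricted to complete rows, with the exclusion log
#'   in `cohort$exclusions`.
#' @export
apply_exclusions <- function(cohort) {
  flags <- cohort$flags
  if (is.null(flags) || nrow(flags) == 0L) {
    cohort$exclusions <- data.frame(subject_id = character(0),
                                    reason = character(0))
    return(cohort)
  }
  keep <- !(cohort$subjects$subject_id %in% flags$subject_id)
  if (!any(keep)) stop("all subjects excluded: no complete rows remain")
  cohort$subjects <- cohort$subjects[keep, , drop = FALSE]
  rownames(cohort$subjects) <- NULL
  if (!is.null(cohort$visits)) {
    cohort$visits <-
      cohort$visits[cohort$visits$subject_id %in%
                      cohort$subjects$subject_id, , drop = FALSE]
  }
  cohort$exclusions <- flags
  cohort$flags <- NULL
  cohort
}
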