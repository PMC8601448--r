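#' Covariate design matrix for augmented models
#'
#' Builds the covariate columns appended (post hoc, unselected) to ROI
#' models: `age` in years, `sex` as a female indicator, and education
#' either as years (when numeric) or as two dummy columns for a 3-level
#' category.
#'
#' @param cohort a `tcp_cohort`.
#' @param which subset of `c("age", "sex", "education")`.
#' @return numeric matrix (possibly 0 columns).
#' @export
covariate_matrix <- function(cohort, which) {
  subj <- cohort$subjects
  cols <- list()
  if ("age" %in% which) cols$age <- subj$age
  if ("sex" %in% which) cols$sex_female <- as.numeric(subj$sex == "F")
  if ("education" %in% which) {
    if (is.numeric(subj$education)) {
      cols$education_years <- subj$education
    } else {
      lv <- sort(unique(subj$education))
      for (l in lv[-1]) {
        cols[[paste0("education_", gsub("[^A-Za-z]+", "_", l))]] <-
          as.numeric(subj$education == l)
      }
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow(subj), 0))
  }
  do.call(cbind, cols)
}

filter_age_group <- function(cohort, age_group) {
  if (is.null(age_group)) return(cohort)
  lo <- c("70s" = 70, "80s" = 80, "90s" = 90)[[age_group]]
  hi <- if (age_group == "90s") Inf else lo + 10
  keep <- cohort$subjects$age >= lo & cohort$subjects$age < hi
  if (sum(keep) < 10L) stop("age-group filter leaves too few subjects")
  cohort$subjects <- cohort$subjects[keep, , drop = FALSE]
  rownames(cohort$subjects) <- NULL
  if (!is.null(cohort$visits)) {
    cohort$visits <- cohort$visits[
      cohort$visits$subject_id %in% cohort$subjects$subject_id, ,
      drop = FALSE]
  }
  cohort
}

#' Run the full TCP analysis pipeline
#'
#' Executes the complete analysis sequence on a cohort: listwise
#' exclusions, TCP labeling, demographic comparisons, the a priori
#' six-ROI cingulate logistic model, whole-brain forward selection over
#' all 62 ROIs, apparent ROC/AUC for both models, the DeLong contrast
#' between them, permutation-derived alphas (rebuilding each model per
#' label shuffle — the forward selection is re-run inside the whole-brain
#' null), covariate-augmented AUCs for the selected ROI set, and the
#' stratified-bootstrap selection-frequency profile with its
#' shuffled-label chance baseline and shape classification.
#'
#' @param cohort a `tcp_cohort` (labeled or labelable).
#' @param config a [run_config()]; `n_permutations` / `n_bootstrap`
#'   control the resampling depth.
#' @param criteria [tcp_criteria()] used if the cohort is unlabeled.
#' @param run_bootstrap set `FALSE` to skip the bootstrap stage.
#' @param run_permutation set `FALSE` to skip the permutation stage.
#' @return list of class `tcp_pipeline_result` with elements
#'   `cohort`, `demographics`, `cingulate` (model, tests, roc),
#'   `whole_brain` (selection, roc), `contrast`, `permutation`
#'   (cingulate, whole_brain), `covariate_aucs`, `selection_profile`,
#'   `shape`, `config`.
#' @export
run_tcp_pipeline <- function(cohort, config = run_config(),
                             criteria = tcp_criteria(),
                             run_bootstrap = TRUE,
                             run_permutation = TRUE) {
  stopifnot(inherits(cohort, "tcp_cohort"), inherits(config, "run_config"))
  cohort <- apply_exclusions(cohort)
  cohort <- filter_age_group(cohort, config$age_group)
  if (is.null(cohort$subjects$is_tcp)) {
    cohort <- label_cohort(cohort, criteria)
  }
  y <- as.integer(cohort$subjects$is_tcp)
  X <- thickness_matrix(cohort)
  demog <- demographics_table(cohort)

  cing <- config$cingulate_rois
  if (!all(cing %in% colnames(X))) {
    stop("cingulate ROI set not present in the cohort: ",
         paste(setdiff(cing, colnames(X)), collapse = ", "))
  }
  cing_fit <- fit_logistic(X[, cing, drop = FALSE], y)
  cing_roc <- roc_curve(cing_fit$fitted, y)
  cing_tests <- if (cing_fit$converged) coefficient_tests(cing_fit) else NULL

  wb <- forward_select(X, y, entry_p = config$entry_p)
  wb_roc <- roc_curve(wb$model$fitted, y)

  contrast <- delong_contrast(wb$model$fitted, cing_fit$fitted, y)

  permutation <- NULL
  if (run_permutation) {
    build_cing <- function(Xm, yy) {
      fit_logistic(Xm[, cing, drop = FALSE], yy)$fitted
    }
    build_wb <- function(Xm, yy) {
      forward_select(Xm, yy, entry_p = config$entry_p)$model$fitted
    }
    permutation <- list(
      cingulate = permutation_alpha(X, y, build_cing,
                                    K = config$n_permutations,
                                    seed = config$seed),
      whole_brain = permutation_alpha(X, y, build_wb,
                                      K = config$n_permutations,
                                      seed = config$seed + 1L)
    )
  }

  covariate_aucs <- covariate_auc_table(cohort, wb$selected, y)

  selection_profile <- NULL
  shape <- NULL
  if (run_bootstrap) {
    selection_profile <- bootstrap_selection_frequency(
      X, y, B = config$n_bootstrap, entry_p = config$entry_p,
      seed = config$seed + 2L)
    chance <- chance_selection_baseline(
      X, y, B = config$n_bootstrap, entry_p = config$entry_p,
      seed = config$seed + 3L)
    selection_profile <- attach_chance_baseline(selection_profile, chance)
    shape <- classify_frequency_profile(selection_profile)
  }

  structure(list(
    cohort = cohort,
    demographics = demog,
    cingulate = list(model = cing_fit, tests = cing_tests, roc = cing_roc),
    whole_brain = list(selection = wb, roc = wb_roc),
    contrast = contrast,
    permutation = permutation,
    covariate_aucs = covariate_aucs,
    selection_profile = selection_profile,
    shape = shape,
    config = config
  ), class = "tcp_pipeline_result")
}

#' Apparent AUC of the selected-ROI model under covariate augmentation
#'
#' Refits the forward-selected ROI set with each covariate combination
#' (none; sex; education; sex + education; age + sex + education)
#' forced in, and reports the apparent AUC of each fit.
#'
#' @param cohort a labeled `tcp_cohort`.
#' @param selected character vector of selected ROI names.
#' @param y binary labels.
#' @return data.frame with `model` and `auc` columns.
#' @export
covariate_auc_table <- function(cohort, selected, y) {
  X <- thickness_matrix(cohort)
  sets <- list(
    "ROIs" = character(0),
    "ROIs + sex" = "sex",
    "ROIs + education" = "education",
    "ROIs + sex, education" = c("sex", "education"),
    "ROIs + age, sex, education" = c("age", "sex", "education")
  )
  out <- lapply(names(sets), function(nm) {
    cv <- covariate_matrix(cohort, sets[[nm]])
    design <- cbind(X[, selected, drop = FALSE], cv)
    if (ncol(design) == 0L) return(NULL)
    fit <- fit_logistic(design, y)
    data.frame(model = nm, auc = auc(fit$fitted, y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.tcp_pipeline_result <- function(x, ...) {
  cat("<tcp_pipeline_result>\n")
  cat("  subjects:", nrow(x$cohort$subjects),
      "| TCP:", sum(x$cohort$subjects$is_tcp), "\n")
  cat(sprintf("  cingulate AUC: %.3f | whole-brain AUC: %.3f (%d ROIs)\n",
              x$cingulate$roc$auc, x$whole_brain$roc$auc,
              length(x$whole_brain$selection$selected)))
  cat(sprintf("  DeLong contrast p = %.4g\n", x$contrast$p))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation alpha: cingulate %.4g, whole-brain %.4g\n",
                x$permutation$cingulate$alpha,
                x$permutation$whole_brain$alpha))
  }
  if (!is.null(x$shape)) cat("  selection profile shape:", x$shape$label, "\n")
  invisible(x)
}

#' Write pipeline outputs under a run directory
#'
#' Emits the paper-style output set as plain files: demographics CSV,
#' model coefficient CSVs with logit-equation text, selection trace, ROC
#' point CSVs, AUC/alpha summary JSON, sorted selection-frequency CSV and
#' a manifest of everything written.
#'
#' @param result a `tcp_pipeline_result`.
#' @param dir output directory.
#' @return invisibly, the manifest (named vector of paths).
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[name] <<- p
  }
  wcsv(result$demographics, "demographics.csv")
  if (!is.null(result$cingulate$tests)) {
    wcsv(result$cingulate$tests, "cingulate_coefficients.csv")
  }
  writeLines(c(model_equation(result$cingulate$model),
               model_equation(result$whole_brain$selection$model)),
             file.path(dir, "model_equations.txt"))
  paths["model_equations.txt"] <- file.path(dir, "model_equations.txt")
  wcsv(result$whole_brain$selection$trace, "selection_trace.csv")
  wcsv(data.frame(fpr = result$cingulate$roc$fpr,
                  tpr = result$cingulate$roc$tpr), "roc_cingulate.csv")
  wcsv(data.frame(fpr = result$whole_brain$roc$fpr,
                  tpr = result$whole_brain$roc$tpr), "roc_whole_brain.csv")
  if (!is.null(result$covariate_aucs)) {
    wcsv(result$covariate_aucs, "covariate_aucs.csv")
  }
  if (!is.null(result$selection_profile)) {
    prof <- result$selection_profile$profile
    wcsv(prof[order(-prof$frequency), ], "selection_frequencies.csv")
  }
  summary <- list(
    n_subjects = nrow(result$cohort$subjects),
    n_tcp = sum(result$cohort$subjects$is_tcp),
    cingulate_auc = result$cingulate$roc$auc,
    whole_brain_auc = result$whole_brain$roc$auc,
    n_selected = length(result$whole_brain$selection$selected),
    delong_p = result$contrast$p
  )
  if (!is.null(result$permutation)) {
    summary$alpha_cingulate <- result$permutation$cingulate$alpha
    summary$alpha_whole_brain <- result$permutation$whole_brain$alpha
    nulls <- data.frame(
      cingulate = result$permutation$cingulate$null_aucs,
      whole_brain = result$permutation$whole_brain$null_aucs)
    wcsv(nulls, "null_aucs.csv")
  }
  if (!is.null(result$shape)) summary$profile_shape <- result$shape$label
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["summary.json"] <- file.path(dir, "summary.json")
  jsonlite::write_json(as.list(paths), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
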