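# Shared fixtures: all built in code at test time.

# Small labeled cohort with an optional planted single-ROI effect.
small_cohort <- function(n = 200, seed = 1, signal = character(0),
                         effect = 0) {
  cfg <- synthetic_config(n_subjects = n, signal_rois = signal,
                          signal_effect = effect, seed = seed)
  label_cohort(generate_cohort(cfg))
}

# Hand-built minimal cohort from explicit scores; thickness/volumes are
# filled with neutral values so the object passes structural checks.
score_cohort <- function(memory, trails, age = NULL) {
  n <- length(memory)
  rois <- dkt_roi_names()
  th <- matrix(2.5, n, 62, dimnames = list(NULL, rois))
  vol <- matrix(3000, n, 62, dimnames = list(NULL, paste0("vol_", rois)))
  subjects <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    age = if (is.null(age)) rep(75, n) else age,
    sex = rep(c("F", "M"), length.out = n),
    education = rep(15, n),
    memory_score = memory,
    trails_b_time = trails,
    scan_date = as.Date("2015-01-01"),
    stringsAsFactors = FALSE
  )
  structure(list(subjects = cbind(subjects, as.data.frame(th),
                                  as.data.frame(vol)),
                 visits = NULL, roi_names = rois, config = NULL),
            class = "tcp_cohort")
}

# Independent brute-force AUC: explicit pairwise counting with 1/2 ties.
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
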