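#' Configuration for the synthetic cohort generator
#'
#' Describes a full generative recipe for a cohort with the statistical
#' structure the TCP analysis assumes: 62 correlated DKT ROI thicknesses,
#' a latent cognition variable shifted by a planted subset of signal ROIs,
#' two cognitive scores (a delayed-recall memory score, higher better, and
#' a Trails-B completion time, lower better) driven by that latent, and
#' demographics. Defaults emulate the NACC 70-89 analysis sample:
#' n = 347 subjects, a TCP base rate near 30%, regional thickness means of
#' roughly 2-3 mm with 0.2 mm SD, and exchangeable inter-ROI correlation.
#'
#' @param n_subjects number of subjects.
#' @param age_group one of `"70s"`, `"80s"`, `"90s"`, `"mixed"`. `"mixed"`
#'   draws decades 70s/80s in the 244:103 proportion of the reference
#'   cohort.
#' @param roi_names 62 unique `L_`/`R_`-prefixed ROI labels.
#' @param mean_thickness per-ROI mean thickness in mm (length 62 or scalar);
#'   must lie in \[1.5, 4.5\].
#' @param roi_sd per-ROI thickness SD in mm (> 0).
#' @param roi_correlation exchangeable inter-ROI correlation in \[0, 1).
#' @param roi_correlation_bilateral correlation between left/right homologous
#'   ROIs; must be >= `roi_correlation`. Default equal to it.
#' @param signal_rois subset of `roi_names` whose thickness shifts latent
#'   cognition.
#' @param signal_effect standardized effect size: latent cognition shift
#'   (in SD units) per SD of mean signal-ROI thickness.
#' @param tcp_base_rate_target target TCP proportion in \[0.25, 0.49\];
#'   achieved by calibrating the correlation between the two cognitive
#'   scores (see Details).
#' @param sex_split proportion female.
#' @param education_mean,education_sd years-of-education model (NACC style).
#' @param education_levels optional length-3 probability vector for a
#'   3-level education category (90+ style); overrides the years model.
#' @param education_confound years-of-education shift per SD of latent
#'   cognition (0 = independent; > 0 emulates the education difference
#'   between TCP groups seen in real cohorts).
#' @param n_visits_range integer range `c(lo, hi)` of neuropsychological
#'   visits per subject.
#' @param seed integer RNG seed.
#'
#' @details TCP labeling thresholds both scores at their within-sample
#' medians, so on the latent-normal scale the TCP rate is the bivariate
#' normal quadrant probability `1/4 + asin(r)/(2*pi)` where `r` is the
#' correlation between the two score latents. The generator inverts this:
#' `r = sin(2*pi*(target - 1/4))`, making the realized base rate match the
#' target up to sampling error regardless of the planted signal (the latent
#' is standardized before scores are formed).
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_subjects = 347,
                             age_group = c("mixed", "70s", "80s", "90s"),
                             roi_names = dkt_roi_names(),
                             mean_thickness = dkt_default_mean_thickness(),
                             roi_sd = 0.2,
                             roi_correlation = 0.3,
                             roi_correlation_bilateral = NULL,
                             signal_rois = character(0),
                             signal_effect = 0,
                             tcp_base_rate_target = 0.303,
                             sex_split = 0.61,
                             education_mean = 15,
                             education_sd = 3.4,
                             education_levels = NULL,
                             education_confound = 0,
                             n_visits_range = c(1L, 1L),
                             seed = 1L) {
  age_group <- match.arg(age_group)
  if (length(mean_thickness) == 1L) {
    mean_thickness <- stats::setNames(rep(mean_thickness, length(roi_names)),
                                      roi_names)
  }
  if (is.null(roi_correlation_bilateral)) {
    roi_correlation_bilateral <- roi_correlation
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), age_group = age_group,
    roi_names = roi_names, mean_thickness = mean_thickness, roi_sd = roi_sd,
    roi_correlation = roi_correlation,
    roi_correlation_bilateral = roi_correlation_bilateral,
    signal_rois = signal_rois, signal_effect = signal_effect,
    tcp_base_rate_target = tcp_base_rate_target, sex_split = sex_split,
    education_mean = education_mean, education_sd = education_sd,
    education_levels = education_levels,
    education_confound = education_confound,
    n_visits_range = as.integer(n_visits_range), seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_subjects < 4L) stop("n_subjects must be at least 4")
  rn <- cfg$roi_names
  if (length(rn) != 62L || anyDuplicated(rn)) {
    stop("roi_names must be 62 unique labels")
  }
  if (!all(grepl("^[LR]_", rn))) {
    stop("every ROI label must be hemisphere-tagged with an L_ or R_ prefix")
  }
  if (sum(startsWith(rn, "L_")) != 31L) {
    stop("roi_names must contain 31 ROIs per hemisphere")
  }
  mt <- cfg$mean_thickness
  if (length(mt) != 62L || any(mt < 1.5) || any(mt > 4.5)) {
    stop("mean_thickness must give 62 values in [1.5, 4.5] mm")
  }
  if (!is.null(names(mt)) && !identical(names(mt), rn)) {
    stop("mean_thickness names must match roi_names")
  }
  if (cfg$roi_sd <= 0) stop("roi_sd must be positive")
  rho <- cfg$roi_correlation
  if (rho < 0 || rho >= 1) stop("roi_correlation must lie in [0, 1)")
  rhob <- cfg$roi_correlation_bilateral
  if (rhob < rho || rhob >= 1) {
    stop("roi_correlation_bilateral must lie in [roi_correlation, 1)")
  }
  if (!all(cfg$signal_rois %in% rn)) {
    stop("signal_rois must be a subset of roi_names")
  }
  tgt <- cfg$tcp_base_rate_target
  if (tgt < 0.25 || tgt > 0.49) {
    stop("tcp_base_rate_target must lie in [0.25, 0.49] ",
         "(quadrant probability of a positively correlated bivariate normal)")
  }
  if (cfg$sex_split < 0 || cfg$sex_split > 1) stop("sex_split must be in [0, 1]")
  if (!is.null(cfg$education_levels)) {
    pl <- cfg$education_levels
    if (length(pl) != 3L || any(pl < 0) || abs(sum(pl) - 1) > 1e-8) {
      stop("education_levels must be 3 probabilities summing to 1")
    }
  }
  nv <- cfg$n_visits_range
  if (length(nv) != 2L || nv[1] < 1L || nv[2] < nv[1]) {
    stop("n_visits_range must be an increasing integer range with lo >= 1")
  }
  invisible(cfg)
}

# Index of the bilateral partner of each ROI column (L_x <-> R_x).
bilateral_pair_index <- function(roi_names) {
  base <- sub("^[LR]_", "", roi_names)
  match(base, unique(base))
}

# Analytic variance of the mean of k standardized ROI deviates under the
# exchangeable + bilateral covariance (1 on the diagonal, rho_b within a
# homologous pair, rho otherwise).
signal_mean_variance <- function(cfg) {
  idx <- match(cfg$signal_rois, cfg$roi_names)
  k <- length(idx)
  if (k == 0L) return(NA_real_)
  pair <- bilateral_pair_index(cfg$roi_names)[idx]
  n_pair_offdiag <- 2 * sum(table(pair) == 2L)
  total <- k + n_pair_offdiag * cfg$roi_correlation_bilateral +
    (k * (k - 1) - n_pair_offdiag) * cfg$roi_correlation
  total / k^2
}

draw_age <- function(n, age_group) {
  draw_decade <- function(n, lo) lo + stats::runif(n) * 9.9
  switch(age_group,
    "70s" = draw_decade(n, 70),
    "80s" = draw_decade(n, 80),
    "90s" = pmin(90 + stats::rgamma(n, shape = 2.3, scale = 1.7), 105),
    "mixed" = {
      in70s <- stats::runif(n) < 244 / 347
      ifelse(in70s, draw_decade(n, 70), draw_decade(n, 80))
    }
  )
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [synthetic_config()] recipe: ROI thicknesses
#' from a multivariate normal with exchangeable correlation (plus an
#' optional stronger left/right homologous correlation), a standardized
#' latent cognition equal to the scaled mean of the signal ROIs' deviates
#' plus noise, a memory score increasing in the latent, a lognormal
#' Trails-B completion time decreasing in it, demographics, per-ROI
#' volumes, and a visit table. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `tcp_cohort`: a list with elements
#'   `subjects` (one row per subject: id, demographics, basis cognitive
#'   scores, scan date, 62 thickness columns named by ROI, 62 volume
#'   columns prefixed `vol_`), `visits` (subject_id, visit_date,
#'   memory_score, trails_b_time), `roi_names`, and `config`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  p <- length(cfg$roi_names)

  rho <- cfg$roi_correlation
  rhob <- cfg$roi_correlation_bilateral
  g <- stats::rnorm(n)
  pair <- bilateral_pair_index(cfg$roi_names)
  h <- matrix(stats::rnorm(n * max(pair)), n, max(pair))
  eps <- matrix(stats::rnorm(n * p), n, p)
  z <- sqrt(rho) * g + sqrt(rhob - rho) * h[, pair, drop = FALSE] +
    sqrt(1 - rhob) * eps
  thickness <- sweep(z * cfg$roi_sd, 2, cfg$mean_thickness, "+")
  thickness[thickness <= 0.1] <- 0.1  # guard: thickness strictly positive
  colnames(thickness) <- cfg$roi_names

  # latent cognition: standardized so the score model below stays calibrated
  if (length(cfg$signal_rois) > 0L && cfg$signal_effect != 0) {
    idx <- match(cfg$signal_rois, cfg$roi_names)
    s <- rowMeans(z[, idx, drop = FALSE]) / sqrt(signal_mean_variance(cfg))
    latent <- (cfg$signal_effect * s + stats::rnorm(n)) /
      sqrt(cfg$signal_effect^2 + 1)
  } else {
    latent <- stats::rnorm(n)
  }

  # score correlation calibrated to the TCP base-rate target (quadrant rule)
  r <- sin(2 * pi * (cfg$tcp_base_rate_target - 0.25))
  mem_lat <- sqrt(r) * latent + sqrt(1 - r) * stats::rnorm(n)
  exe_lat <- sqrt(r) * latent + sqrt(1 - r) * stats::rnorm(n)
  memory_score <- 12 + 4 * mem_lat
  trails_b_time <- exp(log(120) + 0.35 * (-exe_lat))

  sex <- ifelse(stats::runif(n) < cfg$sex_split, "F", "M")
  if (is.null(cfg$education_levels)) {
    education <- stats::rnorm(n, cfg$education_mean, cfg$education_sd) +
      cfg$education_confound * latent
    education <- round(pmin(pmax(education, 6), 20))
  } else {
    lv <- c("HS-or-less", "some-college-to-grad", "graduate-plus")
    if (cfg$education_confound == 0) {
      education <- sample(lv, n, replace = TRUE, prob = cfg$education_levels)
    } else {
      # ordinal confounding: cut a latent at the target category quantiles
      e_lat <- cfg$education_confound * latent + stats::rnorm(n)
      qs <- stats::qnorm(cumsum(cfg$education_levels)[1:2],
                         sd = sqrt(1 + cfg$education_confound^2))
      education <- lv[1L + (e_lat > qs[1]) + (e_lat > qs[2])]
    }
  }
  age <- round(draw_age(n, cfg$age_group), 1)

  volumes <- sweep(exp(matrix(stats::rnorm(n * p, sd = 0.12), n, p)), 2,
                   dkt_default_volume()[seq_len(p)], "*")
  colnames(volumes) <- paste0("vol_", cfg$roi_names)

  scan_date <- as.Date("2015-06-15") + sample.int(365, n, replace = TRUE) - 1L

  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age,
    sex = sex,
    education = education,
    memory_score = memory_score,
    trails_b_time = trails_b_time,
    scan_date = scan_date,
    stringsAsFactors = FALSE
  )
  subjects <- cbind(subjects, as.data.frame(thickness),
                    as.data.frame(volumes))

  nv <- cfg$n_visits_range[1] +
    sample.int(cfg$n_visits_range[2] - cfg$n_visits_range[1] + 1L, n,
               replace = TRUE) - 1L
  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- nv[i]
    offs <- sort(sample(-720:720, k))
    # visit closest to the scan reproduces the basis scores exactly
    mem_noise <- stats::rnorm(k, sd = 0.8)
    tr_noise <- stats::rnorm(k, sd = 0.08)
    closest <- which.min(abs(offs))
    mem_noise[closest] <- 0
    tr_noise[closest] <- 0
    data.frame(
      subject_id = subjects$subject_id[i],
      visit_date = scan_date[i] + offs,
      memory_score = memory_score[i] + mem_noise,
      trails_b_time = trails_b_time[i] * exp(tr_noise),
      stringsAsFactors = FALSE
    )
  }))

  structure(list(subjects = subjects, visits = visits,
                 roi_names = cfg$roi_names, config = cfg),
            class = "tcp_cohort")
}

#' @export
print.tcp_cohort <- function(x, ...) {
  cat("<tcp_cohort> ", nrow(x$subjects), " subjects, ",
      length(x$roi_names), " ROIs", sep = "")
  if (!is.null(x$subjects$is_tcp)) {
    cat("; ", sum(x$subjects$is_tcp), " TCP (",
        round(100 * mean(x$subjects$is_tcp), 1), "%)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Thickness predictor matrix of a cohort
#' @param cohort a `tcp_cohort`.
#' @return numeric matrix, subjects x 62 ROIs in canonical order.
#' @export
thickness_matrix <- function(cohort) {
  as.matrix(cohort$subjects[, cohort$roi_names, drop = FALSE])
}

#' Generate a flat voxel thickness map for one ROI
#'
#' A test fixture for the 1 mm clipping rule: a vector of voxel thickness
#' values where "background" voxels (mask bleed outside the cortical
#' sheet) fall below 1 mm and foreground voxels scatter around the ROI
#' mean.
#'
#' @param roi_mean foreground mean thickness (mm).
#' @param n_voxels number of voxels (>= 1).
#' @param background_fraction proportion of sub-1 mm background voxels,
#'   in \[0, 1).
#' @param seed integer seed.
#' @param values optional explicit voxel values; stored verbatim,
#'   bypassing generation.
#' @return object of class `voxel_map` with element `values`.
#' @export
generate_voxel_map <- function(roi_mean, n_voxels, background_fraction = 0.2,
                               seed = 1L, values = NULL) {
  if (!is.null(values)) {
    return(structure(list(values = as.numeric(values)), class = "voxel_map"))
  }
  if (n_voxels < 1L) stop("n_voxels must be at least 1")
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("background_fraction must lie in [0, 1)")
  }
  set.seed(seed)
  n_bg <- floor(n_voxels * background_fraction)
  fg <- pmax(stats::rnorm(n_voxels - n_bg, roi_mean, 0.15), 1)
  bg <- stats::runif(n_bg, 0, 0.999)
  structure(list(values = sample(c(fg, bg))), class = "voxel_map")
}
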