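test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_subjects = 60, seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$visits, b$visits)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(roi_correlation = 1.0), "roi_correlation")
  expect_error(synthetic_config(roi_correlation = -0.1), "roi_correlation")
  expect_error(synthetic_config(roi_sd = 0), "roi_sd")
  expect_error(synthetic_config(signal_rois = "not_a_roi"), "signal_rois")
  expect_error(synthetic_config(mean_thickness = 5.0), "mean_thickness")
  expect_error(
    synthetic_config(roi_correlation = 0.5, roi_correlation_bilateral = 0.3),
    "bilateral")
  cfg <- synthetic_config()
  expect_length(unique(cfg$roi_names), 62)
  expect_equal(sum(dkt_hemisphere(cfg$roi_names) == "L"), 31)
})

test_that("zero signal effect leaves ROIs uncorrelated with cognition", {
  cors <- vapply(1:60, function(s) {
    coh <- generate_cohort(synthetic_config(n_subjects = 150, seed = s))
    cor(coh$subjects$L_entorhinal, coh$subjects$memory_score)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.04)
})

test_that("a planted effect thickens the signal ROI in top memory scorers", {
  cfg <- synthetic_config(n_subjects = 400, signal_rois = "L_entorhinal",
                          signal_effect = 1.0, seed = 3)
  coh <- generate_cohort(cfg)
  th <- coh$subjects$L_entorhinal
  top <- coh$subjects$memory_score >= median(coh$subjects$memory_score)
  expect_gt(mean(th[top]), mean(th[!top]))
})

test_that("TCP rate in thick-signal subjects rises with effect size", {
  rate_at <- function(effect) {
    rates <- vapply(1:25, function(s) {
      cfg <- synthetic_config(n_subjects = 250, signal_rois = "L_entorhinal",
                              signal_effect = effect, seed = 100 + s)
      coh <- label_cohort(generate_cohort(cfg))
      th <- coh$subjects$L_entorhinal
      top_q <- th >= quantile(th, 0.75)
      mean(coh$subjects$is_tcp[top_q])
    }, numeric(1))
    mean(rates)
  }
  rates <- vapply(c(0, 0.5, 1.0), rate_at, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("realized TCP base rate matches the target at n = 1000", {
  cfg <- synthetic_config(n_subjects = 1000, seed = 11)
  coh <- label_cohort(generate_cohort(cfg))
  expect_lt(abs(mean(coh$subjects$is_tcp) - cfg$tcp_base_rate_target), 0.05)
})

test_that("subject records satisfy structural invariants", {
  coh <- generate_cohort(synthetic_config(n_subjects = 50, seed = 2,
                                          n_visits_range = c(2L, 5L)))
  th <- thickness_matrix(coh)
  expect_true(all(th > 0))
  by_subj <- split(coh$visits$visit_date, coh$visits$subject_id)
  expect_true(all(vapply(by_subj, function(d) !is.unsorted(d), logical(1))))
  expect_true(all(coh$subjects$sex %in% c("F", "M")))
})

test_that("voxel maps respect background fraction and overrides", {
  m <- generate_voxel_map(2.5, 100, background_fraction = 0, seed = 1)
  expect_true(all(m$values >= 1))
  m2 <- generate_voxel_map(2.5, 4, values = c(0, 0.5, 2.0, 3.0))
  expect_identical(m2$values, c(0, 0.5, 2.0, 3.0))
  expect_identical(generate_voxel_map(2.5, 50, 0.3, seed = 9)$values,
                   generate_voxel_map(2.5, 50, 0.3, seed = 9)$values)
  expect_error(generate_voxel_map(2.5, 10, background_fraction = 1),
               "background_fraction")
})
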