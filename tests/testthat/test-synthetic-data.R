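# synthetic-data generators: pupil runs, twin cohorts, reliability tables

test_that("simulate_pupil_run is a pure function of (params, seed)", {
  p <- quick_params(seed = 7, closure_target_fraction = 0.1)
  a <- simulate_pupil_run(p)
  b <- simulate_pupil_run(p)
  expect_identical(a$trace$pupil, b$trace$pupil)
  expect_identical(a$blinks, b$blinks)
  expect_identical(a$closures, b$closures)
  # different seed changes the trace
  c_ <- simulate_pupil_run(quick_params(seed = 8, closure_target_fraction = 0.1))
  expect_false(identical(a$trace$pupil, c_$trace$pupil))
})

test_that("ground truth matches the trace: blinks are exact zero runs", {
  sim <- simulate_pupil_run(quick_params(seed = 3, closure_target_fraction = 0.05))
  tr <- sim$trace
  for (i in seq_len(nrow(sim$blinks))) {
    s <- round(sim$blinks$onset_ms[i] * tr$sampling_hz / 1000) + 1L
    e <- s + round(sim$blinks$duration_ms[i] * tr$sampling_hz / 1000) - 1L
    expect_true(all(tr$pupil[s:e] == 0))
    expect_true(all(tr$missing[s:e]))
  }
  # simulated blink durations always in [40, 400] ms, closures > 400 ms
  expect_true(all(sim$blinks$duration_ms >= 40 & sim$blinks$duration_ms <= 400))
  expect_true(all(sim$closures$duration_ms > 400))
})

test_that("realized blink count is calibrated to the requested rate", {
  # 12/min over 300 s -> 60 expected; mean over 25 seeds within 3 SE
  cnt <- vapply(1:25, function(s) {
    nrow(simulate_pupil_run(sim_run_params(duration_s = 300,
                                           blink_rate_per_min = 12,
                                           seed = s))$blinks)
  }, 0L)
  se <- stats::sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - 60), 3 * se + 1)
})

test_that("realized closure fraction hits the target within 0.05", {
  sim <- simulate_pupil_run(quick_params(seed = 5,
                                         closure_target_fraction = 0.25))
  closure_frac <- sum(sim$closures$duration_ms) / 1000 / QUICK_S
  expect_lt(abs(closure_frac - 0.25), 0.05)
  # and the trace mask agrees with the ground-truth lists
  total_loss <- (sum(sim$closures$duration_ms) + sum(sim$blinks$duration_ms)) / 1000
  expect_equal(mean(sim$trace$missing), total_loss / QUICK_S, tolerance = 1e-6)
})

test_that("infeasible event densities fail loudly", {
  expect_error(simulate_pupil_run(quick_params(seed = 1,
                                               blink_rate_per_min = 200)),
               "infeasible")
  expect_error(sim_run_params(blink_duration_range_ms = c(30, 200)), "40")
  expect_error(sim_run_params(closure_duration_range_s = c(0.2, 1)), "0.4")
  expect_error(sim_run_params(sampling_hz = 250), "500 or 1000")
})

test_that("twin cohort: perfect sharing and independence limits", {
  # a2 = 1, e2 = 0, MZ pairs: twins are identical
  coh <- simulate_twin_cohort(twin_cohort_spec(50, 0, model = "AE",
                                               a2 = 1, e2 = 0, seed = 2))
  expect_equal(attr(coh, "z1"), attr(coh, "z2"))
  # E only: both zygosities uncorrelated
  cohE <- simulate_twin_cohort(twin_cohort_spec(2000, 2000, model = "E",
                                                e2 = 1, seed = 3))
  for (z in c("MZ", "DZ")) {
    idx <- cohE$zygosity == z
    expect_lt(abs(cor(attr(cohE, "z1")[idx], attr(cohE, "z2")[idx])), 0.05)
  }
})

test_that("twin cohort: AE a2 = 0.6 yields the theoretical correlations", {
  coh <- simulate_twin_cohort(twin_cohort_spec(5000, 5000, model = "AE",
                                               a2 = 0.6, e2 = 0.4, seed = 4))
  z1 <- attr(coh, "z1"); z2 <- attr(coh, "z2")
  mz <- coh$zygosity == "MZ"
  expect_gt(cor(z1[mz], z2[mz]), 0.57)
  expect_lt(cor(z1[mz], z2[mz]), 0.63)
  expect_gt(cor(z1[!mz], z2[!mz]), 0.27)
  expect_lt(cor(z1[!mz], z2[!mz]), 0.33)
  # covariate-free phenotype has ~unit variance
  expect_equal(stats::var(c(z1, z2)), 1, tolerance = 0.05)
})

test_that("twin cohort covariates shift the mean as specified", {
  coh <- simulate_twin_cohort(twin_cohort_spec(4000, 0, model = "E", e2 = 1,
                                               beta_sex = 0.5, mean = 10,
                                               seed = 6))
  m2 <- mean(coh$y1[coh$sex1 == 2]); m1 <- mean(coh$y1[coh$sex1 == 1])
  expect_equal(m2 - m1, 0.5, tolerance = 0.1)
  expect_error(twin_cohort_spec(10, 10, model = "AE", a2 = 0.5, e2 = 0.4),
               "sum to 1")
  expect_error(twin_cohort_spec(10, 10, model = "E", a2 = 0.3, e2 = 0.7),
               "a2 must be 0")
})

test_that("reliability matrix: degenerate and deterministic cases", {
  sp <- reliability_spec(8, 4, var_subject = 2, var_run = 0, var_error = 0,
                         seed = 9)
  tab <- simulate_reliability_matrix(sp)
  per_subj_sd <- tapply(tab$value, tab$subject, stats::sd)
  expect_true(all(per_subj_sd < 1e-12))
  expect_identical(tab, simulate_reliability_matrix(sp))
  expect_error(reliability_spec(5, 1, 1, 1, 1), ">= 2")
  expect_error(reliability_spec(5, 3, -1, 1, 1), ">= 0")
})

test_that("implied population ICC(2,k) from a reliability spec", {
  # var_subject 2, var_run 0.1, var_error 1, k = 4 -> 2 / (2 + 1.1/4)
  icc_pop <- 2 / (2 + (0.1 + 1) / 4)
  expect_equal(round(icc_pop, 3), 0.879)
})

test_that("ASC writer round-trips through the parser", {
  sim <- simulate_pupil_run(quick_params(seed = 12,
                                         closure_target_fraction = 0.05))
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(sim$trace, path, ground_truth = sim[c("blinks", "closures")])
  back <- parse_asc_samples(path)
  expect_equal(length(back$pupil), length(sim$trace$pupil))
  expect_identical(back$missing, sim$trace$missing)
  expect_equal(back$pupil, round(sim$trace$pupil, 1), tolerance = 1e-9)
  gt <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(nrow(gt$blinks), nrow(sim$blinks))
})
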