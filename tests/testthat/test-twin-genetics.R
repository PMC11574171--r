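# twin correlations, ACE/ADE maximum likelihood, nested tests, CIs


test_that("intra-pair correlation matches the direct formula", {
  set.seed(3)
  pairs <- data.frame(y1 = rnorm(10), y2 = rnorm(10))
  res <- intrapair_correlation(pairs)
  x <- pairs$y1; y <- pairs$y2
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(res$df, 8)
  tv <- r_direct * sqrt(8 / (1 - r_direct^2))
  expect_equal(res$p_one_sided, pt(tv, 8, lower.tail = FALSE))

  expect_equal(intrapair_correlation(data.frame(y1 = 1:5, y2 = 1:5))$r, 1)
  expect_equal(intrapair_correlation(data.frame(y1 = 1:5, y2 = -(1:5)))$r, -1)
  expect_error(intrapair_correlation(data.frame(y1 = 1:2, y2 = 2:1)), ">= 3")
  expect_error(intrapair_correlation(data.frame(y1 = rep(1, 5), y2 = 1:5)),
               "zero variance")
})

test_that("model family choice follows the r_MZ vs 2 r_DZ rule", {
  expect_equal(choose_model_family(0.535, 0.221), "ADE")  # blink-rate pattern
  expect_equal(choose_model_family(0.625, 0.506), "ACE")  # pupil-size pattern
  expect_equal(choose_model_family(0.4, 0.2), "ACE")      # boundary -> ACE
  expect_equal(choose_model_family(0.59, -0.24), "ACE")   # negative r_DZ
})

test_that("E-model -2LL equals the independence closed form", {
  coh <- simulate_twin_cohort(twin_cohort_spec(100, 100, model = "E", e2 = 1,
                                               seed = 11))
  fit <- fit_twin_model(coh, "E", covariates = FALSE)
  z <- scale(c(coh$y1, coh$y2))
  closed <- sum(log(2 * pi) + z^2)  # at sigma = 1 after z-scoring
  expect_lt(abs(fit$minus2LL - closed), 2)
  expect_gt(fit$std["e2"], 0.999)
})

test_that("AE fit matches the grid-search oracle on 20-pair instances", {
  for (s in 1:3) {
    coh <- simulate_twin_cohort(twin_cohort_spec(10, 10, model = "AE",
                                                 a2 = 0.5, e2 = 0.5,
                                                 seed = 50 + s))
    fit <- fit_twin_model(coh, "AE", covariates = FALSE)
    oracle <- ae_grid_m2ll(coh, seq(0, 1.5, by = 0.005),
                           seq(0.05, 1.5, by = 0.005))
    expect_lt(fit$minus2LL, oracle + 1e-3)
    expect_gt(fit$minus2LL, oracle - 0.05)  # grid discretization slack
  }
})

test_that("AE parameter recovery at 2000+2000 pairs", {
  coh <- simulate_twin_cohort(twin_cohort_spec(2000, 2000, model = "AE",
                                               a2 = 0.6, e2 = 0.4, seed = 5))
  fit <- fit_twin_model(coh, "AE", covariates = FALSE)
  expect_gt(fit$std[["a2"]], 0.55)
  expect_lt(fit$std[["a2"]], 0.65)
  expect_equal(sum(fit$std), 1, tolerance = 1e-6)
})

test_that("covariate effects are estimated alongside the decomposition", {
  coh <- simulate_twin_cohort(twin_cohort_spec(800, 800, model = "AE",
                                               a2 = 0.5, e2 = 0.5,
                                               beta_age = 0.05,
                                               beta_sex = 0.4,
                                               beta_vig = -0.5, seed = 19))
  fit <- fit_twin_model(coh, "AE", covariates = TRUE)
  # slopes recovered on the standardized scale: beta / sd(y)
  sdy <- unname(fit$data$scale["sd"])
  expect_equal(unname(fit$betas["age"]), 0.05 / sdy, tolerance = 0.02)
  expect_equal(unname(fit$betas["sex"]), 0.4 / sdy, tolerance = 0.1)
  expect_equal(unname(fit$betas["vig"]), -0.5 / sdy, tolerance = 0.1)
  expect_gt(fit$std[["a2"]], 0.4)
  expect_lt(fit$std[["a2"]], 0.6)
})

test_that("nested comparisons: identity, null retention, power", {
  coh0 <- simulate_twin_cohort(twin_cohort_spec(300, 300, model = "AE",
                                                a2 = 0.5, e2 = 0.5, seed = 23))
  fit_ae <- fit_twin_model(coh0, "AE", covariates = FALSE)
  self <- nested_comparison(fit_ae, fit_ae)
  expect_equal(self$chi2_diff, 0)
  expect_equal(self$df_diff, 0)

  # data with c2 = 0: dropping C from ACE is mostly non-significant
  keepc <- vapply(1:20, function(s) {
    coh <- simulate_twin_cohort(twin_cohort_spec(150, 150, model = "AE",
                                                 a2 = 0.5, e2 = 0.5,
                                                 seed = 600 + s))
    full <- fit_twin_model(coh, "ACE", covariates = FALSE, seed = s)
    red <- fit_twin_model(coh, "AE", covariates = FALSE, seed = s)
    nested_comparison(full, red)$p > 0.05
  }, TRUE)
  expect_gte(sum(keepc), 15)

  # real additive signal: AE vs E strongly significant
  fit_e <- fit_twin_model(coh0, "E", covariates = FALSE)
  pw <- nested_comparison(fit_ae, fit_e)
  expect_lt(pw$p, 0.001)
  expect_equal(pw$df_diff, 1)

  # -2LL never increases from reduced to full
  expect_gte(fit_e$minus2LL, fit_ae$minus2LL - 1e-6)
})

test_that("implied MZ covariance is at least the DZ covariance", {
  for (s in 1:5) {
    coh <- simulate_twin_cohort(twin_cohort_spec(100, 100, model = "ACE",
                                                 a2 = 0.3, c2_or_d2 = 0.3,
                                                 e2 = 0.4, seed = 70 + s))
    fit <- fit_twin_model(coh, "ACE", covariates = FALSE, seed = s)
    cov_mz <- fit$a2 + fit$c2 + fit$d2
    cov_dz <- 0.5 * fit$a2 + fit$c2 + 0.25 * fit$d2
    expect_gte(cov_mz, cov_dz - 1e-12)
  }
})

test_that("model selection procedure walks the path-dropping tree", {
  coh_ae <- simulate_twin_cohort(twin_cohort_spec(500, 500, model = "AE",
                                                  a2 = 0.5, e2 = 0.5,
                                                  seed = 81))
  sel <- select_best_model(coh_ae, covariates = FALSE, seed = 1)
  expect_equal(sel$best_label, "AE")
  expect_true(all(c("AE", "E") %in% names(sel$fits)))
  # the chi-square AIC variant ranks models identically to -2LL + 2k
  ord1 <- order(sel$aic_table$aic)
  ord2 <- order(sel$aic_table$aic_chisq)
  expect_identical(ord1, ord2)

  coh_e <- simulate_twin_cohort(twin_cohort_spec(300, 300, model = "E",
                                                 e2 = 1, seed = 82))
  sel_e <- select_best_model(coh_e, covariates = FALSE, seed = 2)
  expect_equal(sel_e$best_label, "E")
})

test_that("profile CIs behave: coverage point check, width, boundaries", {
  coh <- simulate_twin_cohort(twin_cohort_spec(200, 200, model = "AE",
                                               a2 = 0.5, e2 = 0.5, seed = 91))
  fit <- fit_twin_model(coh, "AE", covariates = FALSE)
  ci <- profile_ci(fit, "a2")
  expect_lt(ci["lower"], fit$std["a2"])
  expect_gt(ci["upper"], fit$std["a2"])

  # width shrinks with pair count
  widths <- vapply(c(100, 400, 1600), function(n) {
    cohn <- simulate_twin_cohort(twin_cohort_spec(n, n, model = "AE",
                                                  a2 = 0.5, e2 = 0.5,
                                                  seed = 92))
    f <- fit_twin_model(cohn, "AE", covariates = FALSE)
    diff(unname(profile_ci(f, "a2")))
  }, 0)
  expect_true(all(diff(widths) < 0))

  # pure noise: e2 CI contains 1
  cohE <- simulate_twin_cohort(twin_cohort_spec(150, 150, model = "E",
                                                e2 = 1, seed = 93))
  fE <- fit_twin_model(cohE, "AE", covariates = FALSE)
  ciE <- profile_ci(fE, "e2")
  expect_gte(ciE[["upper"]], 1 - 1e-6)
  expect_lte(ciE[["lower"]], 1)
})

test_that("standardized fractions are invariant to affine phenotype scaling", {
  coh <- simulate_twin_cohort(twin_cohort_spec(200, 200, model = "AE",
                                               a2 = 0.6, e2 = 0.4, seed = 95))
  fit1 <- fit_twin_model(coh, "AE", covariates = FALSE)
  coh2 <- coh
  coh2$y1 <- 100 + 42 * coh$y1
  coh2$y2 <- 100 + 42 * coh$y2
  fit2 <- fit_twin_model(coh2, "AE", covariates = FALSE)
  expect_equal(fit1$std[["a2"]], fit2$std[["a2"]], tolerance = 1e-4)
  expect_equal(fit1$minus2LL, fit2$minus2LL, tolerance = 1e-4)
})
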