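#' Specification of a simulated twin cohort
#'
#' Describes a cohort of MZ and DZ twin pairs whose phenotype is generated
#' under a known variance decomposition: additive genetic (A, cross-twin
#' correlation 1 in MZ / 0.5 in DZ), shared environment (C, correlation 1
#' in both) or dominance (D, 1 in MZ / 0.25 in DZ), and unique environment
#' (E, uncorrelated). Covariate effects (age, sex coded 1/2, vigilance
#' state coded 1 = Vigilant / 2 = All Drowsy) are added to the mean.
#'
#' @param n_mz_pairs,n_dz_pairs pair counts.
#' @param model one of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param a2 additive-genetic variance fraction.
#' @param c2_or_d2 shared-environment (ACE-family) or dominance
#'   (ADE-family) fraction; must be 0 when the model has no such component.
#' @param e2 unique-environment fraction; fractions must be >= 0 and sum
#'   to 1.
#' @param beta_age,beta_sex,beta_vig covariate slopes in phenotype-SD
#'   units per covariate unit.
#' @param mean intercept.
#' @param age_range (min, max) age in years, shared within a pair.
#' @param seed integer RNG seed.
#' @return validated `twin_cohort_spec` list.
#' @export
twin_cohort_spec <- function(n_mz_pairs, n_dz_pairs,
                             model = c("ACE", "ADE", "AE", "CE", "E"),
                             a2 = 0, c2_or_d2 = 0, e2 = 1,
                             beta_age = 0, beta_sex = 0, beta_vig = 0,
                             mean = 0, age_range = c(22, 36), seed = 1L) {
  model <- match.arg(model)
  fr <- c(a2 = a2, mid = c2_or_d2, e2 = e2)
  if (any(fr < 0)) stop("variance fractions must be >= 0")
  if (abs(sum(fr) - 1) > 1e-8) stop("variance fractions must sum to 1")
  if (model %in% c("CE", "E") && a2 != 0) {
    stop("a2 must be 0 under model ", model)
  }
  if (model %in% c("AE", "E") && c2_or_d2 != 0) {
    stop("c2_or_d2 must be 0 under model ", model)
  }
  structure(list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                 model = model, a2 = a2, c2_or_d2 = c2_or_d2, e2 = e2,
                 beta_age = beta_age, beta_sex = beta_sex,
                 beta_vig = beta_vig, mean = mean, age_range = age_range,
                 seed = as.integer(seed)),
            class = "twin_cohort_spec")
}

#' Simulate a twin cohort with known variance components
#'
#' Latent components are built as common/unique mixtures so that the
#' cross-twin correlations are exact: for DZ twins
#' `A_i = sqrt(0.5) A_common + sqrt(0.5) A_unique_i` and
#' `D_i = sqrt(0.25) D_common + sqrt(0.75) D_unique_i`; MZ twins share A
#' (and D) fully; C is fully shared by both zygosities; E is independent.
#' The covariate-free phenotype has unit variance when the fractions sum
#' to 1.
#'
#' @param spec a [twin_cohort_spec()].
#' @return data.frame with one row per pair: `family_id`, `zygosity`
#'   (`"MZ"`/`"DZ"`), `y1`, `y2`, `age1`, `age2`, `sex1`, `sex2`, `vig1`,
#'   `vig2`. The covariate-free residuals are attached as attributes `z1`,
#'   `z2` for parameter-recovery tests.
#' @export
simulate_twin_cohort <- function(spec) {
  stopifnot(inherits(spec, "twin_cohort_spec"))
  old <- withr_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)

  n <- spec$n_mz_pairs + spec$n_dz_pairs
  zyg <- rep(c("MZ", "DZ"), c(spec$n_mz_pairs, spec$n_dz_pairs))
  a <- sqrt(spec$a2); e <- sqrt(spec$e2)
  mid <- sqrt(spec$c2_or_d2)
  is_d <- spec$model %in% c("ADE")

  r_shared <- function(r_dz) {
    common <- stats::rnorm(n)
    u1 <- stats::rnorm(n); u2 <- stats::rnorm(n)
    w <- ifelse(zyg == "MZ", 1, r_dz)
    list(x1 = sqrt(w) * common + sqrt(1 - w) * u1,
         x2 = sqrt(w) * common + sqrt(1 - w) * u2)
  }
  A <- r_shared(0.5)
  M <- if (is_d) r_shared(0.25) else {
    common <- stats::rnorm(n); list(x1 = common, x2 = common)
  }
  z1 <- a * A$x1 + mid * M$x1 + e * stats::rnorm(n)
  z2 <- a * A$x2 + mid * M$x2 + e * stats::rnorm(n)

  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex1 <- sample(c(1, 2), n, replace = TRUE)
  sex2 <- ifelse(zyg == "MZ", sex1, sample(c(1, 2), n, replace = TRUE))
  vig1 <- sample(c(1, 2), n, replace = TRUE)
  vig2 <- vig1  # a pair row represents one vigilance state

  mu1 <- spec$mean + spec$beta_age * age + spec$beta_sex * sex1 +
    spec$beta_vig * vig1
  mu2 <- spec$mean + spec$beta_age * age + spec$beta_sex * sex2 +
    spec$beta_vig * vig2

  out <- data.frame(family_id = seq_len(n), zygosity = zyg,
                    y1 = mu1 + z1, y2 = mu2 + z2,
                    age1 = age, age2 = age,
                    sex1 = sex1, sex2 = sex2,
                    vig1 = vig1, vig2 = vig2)
  attr(out, "z1") <- z1
  attr(out, "z2") <- z2
  out
}

#' Specification of a subjects-by-runs reliability design
#'
#' @param n_subjects number of subjects.
#' @param runs_per_subject scalar (balanced) or per-subject vector of run
#'   counts, all >= 2.
#' @param var_subject,var_run,var_error variance components of the two-way
#'   model `y_ij = s_i + r_j + e_ij`.
#' @param seed integer RNG seed.
#' @return validated `reliability_spec` list. The implied population
#'   ICC(2,k) for balanced k is
#'   `var_subject / (var_subject + (var_run + var_error)/k)`.
#' @export
reliability_spec <- function(n_subjects, runs_per_subject,
                             var_subject, var_run, var_error, seed = 1L) {
  if (any(c(var_subject, var_run, var_error) < 0)) {
    stop("variances must be >= 0")
  }
  k <- if (length(runs_per_subject) == 1) {
    rep(runs_per_subject, n_subjects)
  } else runs_per_subject
  if (length(k) != n_subjects) {
    stop("runs_per_subject must be a scalar or length n_subjects")
  }
  if (any(k < 2)) stop("runs_per_subject must be >= 2")
  structure(list(n_subjects = n_subjects, runs_per_subject = k,
                 var_subject = var_subject, var_run = var_run,
                 var_error = var_error, seed = as.integer(seed)),
            class = "reliability_spec")
}

#' Simulate a subjects-by-runs value table
#'
#' `y_ij = s_i + r_j + e_ij` with `s_i ~ N(0, var_subject)`, run effects
#' `r_j ~ N(0, var_run)` shared across subjects for run slot j, and
#' independent errors.
#'
#' @param spec a [reliability_spec()].
#' @return long data.frame `subject`, `run`, `value`.
#' @export
simulate_reliability_matrix <- function(spec) {
  stopifnot(inherits(spec, "reliability_spec"))
  old <- withr_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  kmax <- max(spec$runs_per_subject)
  s <- stats::rnorm(spec$n_subjects, 0, sqrt(spec$var_subject))
  r <- stats::rnorm(kmax, 0, sqrt(spec$var_run))
  rows <- do.call(rbind, lapply(seq_len(spec$n_subjects), function(i) {
    k <- spec$runs_per_subject[i]
    data.frame(subject = i, run = seq_len(k),
               value = s[i] + r[seq_len(k)] +
                 stats::rnorm(k, 0, sqrt(spec$var_error)))
  }))
  rownames(rows) <- NULL
  rows
}
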