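#' ICC(2,k): average-measure agreement under a two-way random-effects model
#'
#' Fits `value ~ 1 + (1 | subject) + (1 | run)` by REML (the run factor is
#' the within-subject chronological run slot) and reports
#' `icc = s2_subject / (s2_subject + (s2_run + s2_error) / k_bar)` with
#' `k_bar` the mean number of runs per retained subject. Subjects with a
#' single run are dropped. On balanced data the REML components coincide
#' with the classical ANOVA mean squares, so the estimate equals the
#' Shrout-Fleiss ICC(2,k) formula
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#'
#' @param data data.frame with columns `subject`, `run`, `value` (long
#'   format; possibly unbalanced).
#' @return list of class `icc_result`: `icc`, `k_effective`,
#'   `variance_components` (subject, run, residual), `n_subjects`.
#' @export
icc2k <- function(data) {
  stopifnot(all(c("subject", "run", "value") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  keep <- names(which(table(data$subject) >= 2))
  data <- data[data$subject %in% keep, , drop = FALSE]
  ns <- length(unique(data$subject))
  if (ns < 2) {
    stop("insufficient data: need >= 2 subjects with >= 2 runs each")
  }
  if (stats::var(data$value) < .Machine$double.eps) {
    stop("degenerate data: total variance is zero")
  }
  k_bar <- nrow(data) / ns
  # exact within-subject constancy: subject variance explains everything
  wss <- stats::ave(data$value, data$subject, FUN = stats::var)
  if (all(wss < 1e-24)) {
    vc <- c(subject = stats::var(tapply(data$value, data$subject, mean)),
            run = 0, residual = 0)
    return(structure(list(icc = 1, k_effective = k_bar,
                          variance_components = vc, n_subjects = ns),
                     class = "icc_result"))
  }
  d <- data.frame(value = data$value,
                  subject = factor(data$subject),
                  run = factor(data$run))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ 1 + (1 | subject) + (1 | run), data = d,
               REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 optimizer = "bobyqa",
                 optCtrl = list(rhoend = 1e-12)))))
  vc_df <- as.data.frame(lme4::VarCorr(fit))
  g <- function(nm) vc_df$vcov[match(nm, vc_df$grp)]
  vc <- c(subject = g("subject"), run = g("run"), residual = g("Residual"))
  icc <- vc["subject"] / (vc["subject"] + (vc["run"] + vc["residual"]) / k_bar)
  structure(list(icc = unname(icc), k_effective = k_bar,
                 variance_components = vc, n_subjects = ns),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,k) = %.4f  (n = %d subjects, k_bar = %.2f runs)\n",
              x$icc, x$n_subjects, x$k_effective))
  v <- x$variance_components
  cat(sprintf("  variance: subject %.4g, run %.4g, residual %.4g\n",
              v[1], v[2], v[3]))
  invisible(x)
}

#' Within-subject profile reliability across runs
#'
#' Each measure column is z-scored across all runs pooled over subjects
#' (within one vigilance state); for every subject with at least two runs,
#' the Pearson correlation between the z-scored nine-measure vectors of
#' each run pair is computed on the measures present in both runs (pairs
#' with fewer than 3 overlapping measures are skipped) and averaged over
#' pairs.
#'
#' @param measures data.frame with a `subject` column and the measure
#'   columns of [eye_measure_names()] (runs as rows).
#' @param measure_cols measure column names, default [eye_measure_names()].
#' @return list: `per_subject` (data.frame `subject`, `r`, `n_pairs`),
#'   `summary` (mean, median, sd over subjects).
#' @export
within_subject_reliability <- function(measures,
                                       measure_cols = eye_measure_names()) {
  stopifnot("subject" %in% names(measures))
  z <- measures
  for (mc in measure_cols) {
    v <- measures[[mc]]
    mu <- mean(v, na.rm = TRUE)
    sd_ <- stats::sd(v, na.rm = TRUE)
    z[[mc]] <- if (is.finite(sd_) && sd_ > 0) (v - mu) / sd_ else NA_real_
  }
  subjects <- unique(z$subject)
  res <- lapply(subjects, function(s) {
    rows <- which(z$subject == s)
    if (length(rows) < 2) return(NULL)
    prs <- utils::combn(rows, 2)
    rr <- apply(prs, 2, function(p) {
      v1 <- as.numeric(z[p[1], measure_cols])
      v2 <- as.numeric(z[p[2], measure_cols])
      ok <- is.finite(v1) & is.finite(v2)
      if (sum(ok) < 3) return(NA_real_)
      suppressWarnings(stats::cor(v1[ok], v2[ok]))
    })
    rr <- rr[is.finite(rr)]
    if (!length(rr)) return(NULL)
    data.frame(subject = s, r = mean(rr), n_pairs = length(rr))
  })
  per_subject <- do.call(rbind, res)
  if (is.null(per_subject)) {
    per_subject <- data.frame(subject = character(0), r = numeric(0),
                              n_pairs = integer(0))
  }
  list(per_subject = per_subject,
       summary = c(mean = mean(per_subject$r),
                   median = stats::median(per_subject$r),
                   sd = stats::sd(per_subject$r)))
}

#' Bonferroni-adjusted alpha for the measure family
#'
#' @param alpha family-wise error rate, default 0.05.
#' @param n_tests number of measures compared, default 9.
#' @return adjusted per-test alpha (0.05 / 9 = 0.0056 at the defaults).
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests = 9) alpha / n_tests

#' Paired vigilant-versus-drowsy one-way ANOVA
#'
#' Takes per-subject values of one measure in the Vigilant and All Drowsy
#' states (runs within a state already collapsed by averaging) and runs a
#' two-group one-way ANOVA on the subjects contributing both states.
#' Significance is flagged at the Bonferroni-adjusted alpha for the
#' nine-measure family (0.05 / 9).
#'
#' @param vigilant,drowsy numeric vectors aligned by subject (NA allowed;
#'   subjects missing either value are dropped).
#' @param alpha family-wise error rate, default 0.05.
#' @param n_tests family size for the Bonferroni correction, default 9.
#' @return list of class `anova_result`: `F`, `df` (between, within), `p`,
#'   `alpha_adjusted`, `significant_bonferroni`, `n_pairs`.
#' @export
paired_state_anova <- function(vigilant, drowsy, alpha = 0.05, n_tests = 9) {
  stopifnot(length(vigilant) == length(drowsy))
  ok <- is.finite(vigilant) & is.finite(drowsy)
  m <- sum(ok)
  if (m < 2) stop("need >= 2 subjects with both states available")
  y <- c(vigilant[ok], drowsy[ok])
  g <- rep(c(1, 2), each = m)
  gm <- tapply(y, g, mean)
  ssb <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df1 <- 1L
  df2 <- 2L * m - 2L
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  a_adj <- bonferroni_alpha(alpha, n_tests)
  structure(list(F = f, df = c(between = df1, within = df2), p = p,
                 alpha_adjusted = a_adj,
                 significant_bonferroni = p < a_adj, n_pairs = m),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g%s (alpha_adj = %.4f)\n",
              x$df[1], x$df[2], x$F, x$p,
              if (x$significant_bonferroni) " *" else "", x$alpha_adjusted))
  invisible(x)
}
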