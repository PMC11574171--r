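# Classical twin-study variance decomposition by maximum likelihood.
#
# Phenotypic variance is split into additive genetic (A), shared
# environment (C) or dominance (D), and unique environment (E). The
# expected cross-twin covariance is a2 + c2 + d2 for MZ pairs and
# 0.5*a2 + c2 + 0.25*d2 for DZ pairs; free parameters are path
# coefficients (a, c or d, e), so the implied components (squared paths)
# are nonnegative by construction. Covariate effects (age, sex 1/2,
# vigilance 1/2) enter the mean.

twin_model_paths <- function(model) {
  switch(model,
         ACE = c("a", "c", "e"),
         ADE = c("a", "d", "e"),
         AE = c("a", "e"),
         CE = c("c", "e"),
         E = "e",
         stop("unknown model: ", model))
}

# components (a2, c2, d2, e2) -> per-zygosity (V, cov)
twin_cov_structure <- function(a2, c2, d2, e2) {
  V <- a2 + c2 + d2 + e2
  list(V = V,
       cov_mz = a2 + c2 + d2,
       cov_dz = 0.5 * a2 + c2 + 0.25 * d2)
}

# minus twice the log likelihood of complete pairs under the bivariate
# normal model; dat holds y1, y2, X (pair-level covariate matrices X1, X2)
# and the zygosity indicator. Returns a large value when the implied
# covariance is not positive definite.
twin_m2ll <- function(a2, c2, d2, e2, beta, dat) {
  st <- twin_cov_structure(a2, c2, d2, e2)
  V <- st$V
  if (V <= 0) return(1e10)
  r1 <- dat$y1 - drop(dat$X1 %*% beta)
  r2 <- dat$y2 - drop(dat$X2 %*% beta)
  total <- 0
  for (z in c("MZ", "DZ")) {
    idx <- dat$zyg == z
    if (!any(idx)) next
    cv <- if (z == "MZ") st$cov_mz else st$cov_dz
    det <- V^2 - cv^2
    if (det <= 0) return(1e10)
    q <- (V * (r1[idx]^2 + r2[idx]^2) - 2 * cv * r1[idx] * r2[idx]) / det
    total <- total + sum(q) + sum(idx) * (2 * log(2 * pi) + log(det))
  }
  total
}

# assemble the pair-level data used by the likelihood
twin_fit_data <- function(pairs, covariates = TRUE, standardize = TRUE) {
  req <- c("zygosity", "y1", "y2")
  stopifnot(all(req %in% names(pairs)))
  cov_names <- c("age", "sex", "vig")
  have_cov <- covariates &&
    all(c("age1", "age2", "sex1", "sex2", "vig1", "vig2") %in% names(pairs))
  ok <- is.finite(pairs$y1) & is.finite(pairs$y2)
  if (have_cov) {
    ok <- ok & stats::complete.cases(
      pairs[, c("age1", "age2", "sex1", "sex2", "vig1", "vig2")])
  }
  d <- pairs[ok, , drop = FALSE]
  if (nrow(d) < 2) stop("insufficient complete twin pairs (", nrow(d), ")")
  y <- c(d$y1, d$y2)
  scale_mu <- 0; scale_sd <- 1
  if (standardize) {
    scale_mu <- mean(y); scale_sd <- stats::sd(y)
    if (!is.finite(scale_sd) || scale_sd == 0) {
      stop("phenotype has zero variance; cannot standardize")
    }
  }
  mk_X <- function(suffix) {
    X <- matrix(1, nrow(d), 1, dimnames = list(NULL, "intercept"))
    if (have_cov) {
      for (v in cov_names) {
        col <- d[[paste0(v, suffix)]]
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- v
      }
    }
    X
  }
  X1 <- mk_X("1"); X2 <- mk_X("2")
  # drop covariates constant across all individuals (unidentifiable)
  if (ncol(X1) > 1) {
    keep <- c(TRUE, vapply(2:ncol(X1), function(j) {
      length(unique(c(X1[, j], X2[, j]))) > 1
    }, TRUE))
    X1 <- X1[, keep, drop = FALSE]
    X2 <- X2[, keep, drop = FALSE]
  }
  list(y1 = (d$y1 - scale_mu) / scale_sd,
       y2 = (d$y2 - scale_mu) / scale_sd,
       X1 = X1, X2 = X2,
       zyg = as.character(d$zygosity),
       n_mz = sum(d$zygosity == "MZ"),
       n_dz = sum(d$zygosity == "DZ"),
       scale = c(mu = scale_mu, sd = scale_sd))
}

#' Fit an ACE/ADE-family twin model by maximum likelihood
#'
#' Maximizes the bivariate-normal likelihood of complete twin pairs under
#' the chosen variance decomposition, with optional age/sex/vigilance
#' covariates in the mean. Path coefficients are the free parameters
#' (components are their squares, hence nonnegative); the E path is
#' bounded away from zero so that the covariance matrix stays positive
#' definite. The optimizer is quasi-Newton (`L-BFGS-B`) with seeded random
#' multi-starts.
#'
#' @param pairs data.frame of twin pairs: `zygosity` (`"MZ"`/`"DZ"`),
#'   `y1`, `y2`, and optionally `age1/2`, `sex1/2`, `vig1/2`. A family may
#'   contribute one row per vigilance state (the vigilance covariate then
#'   absorbs the state shift, as in the duplicated-entry design).
#' @param model `"ACE"`, `"ADE"`, `"AE"`, `"CE"` or `"E"`.
#' @param covariates include age/sex/vigilance mean effects when the
#'   columns are present (constant columns are dropped automatically).
#' @param standardize z-score the phenotype over all individuals entering
#'   the fit (default TRUE; standardized components then sum to ~1).
#' @param n_starts number of optimizer starts, default 8.
#' @param seed seed for the random starts.
#' @return object of class `twin_fit`: raw components `a2`, `c2`, `d2`,
#'   `e2`, standardized fractions `std`, `betas`, `minus2LL`, `aic`
#'   (`-2LL + 2k`), `k` free parameters, pair counts, and the fitting data
#'   (for profiling and nested tests).
#' @export
fit_twin_model <- function(pairs, model = c("ACE", "ADE", "AE", "CE", "E"),
                           covariates = TRUE, standardize = TRUE,
                           n_starts = 8, seed = 1L) {
  model <- match.arg(model)
  dat <- twin_fit_data(pairs, covariates, standardize)
  if (nrow(dat$X1) < 5 && model %in% c("ACE", "ADE")) {
    stop("too few complete pairs (", nrow(dat$X1), ") for a 3-component model")
  }
  paths <- twin_model_paths(model)
  np <- length(paths)
  nb <- ncol(dat$X1)
  unpack <- function(par) {
    th <- par[seq_len(np)]
    comp <- c(a = 0, c = 0, d = 0, e = 0)
    comp[paths] <- th^2
    list(a2 = unname(comp["a"]), c2 = unname(comp["c"]),
         d2 = unname(comp["d"]), e2 = unname(comp["e"]),
         beta = par[np + seq_len(nb)])
  }
  obj <- function(par) {
    p <- unpack(par)
    twin_m2ll(p$a2, p$c2, p$d2, p$e2, p$beta, dat)
  }
  lower <- c(rep(0, np - 1), 1e-4, rep(-Inf, nb))
  upper <- rep(Inf, np + nb)

  beta0 <- rep(0, nb)
  beta0[1] <- mean(c(dat$y1, dat$y2))
  starts <- list(c(rep(sqrt(1 / np), np), beta0))
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (i in seq_len(max(0, n_starts - 1))) {
    starts[[i + 1]] <- c(stats::runif(np, 0.1, 1),
                         beta0 + stats::rnorm(nb, 0, 0.2))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e9) {
    stop("twin model fit failed to converge",
         if (!is.null(best)) paste0(" (best -2LL found: ", best$value, ")"))
  }
  p <- unpack(best$par)
  V <- p$a2 + p$c2 + p$d2 + p$e2
  k <- np + nb
  betas <- stats::setNames(p$beta, colnames(dat$X1))
  structure(list(model = model,
                 a2 = p$a2, c2 = p$c2, d2 = p$d2, e2 = p$e2,
                 V = V,
                 std = c(a2 = p$a2 / V, c2 = p$c2 / V,
                         d2 = p$d2 / V, e2 = p$e2 / V),
                 betas = betas,
                 minus2LL = best$value,
                 aic = best$value + 2 * k,
                 k = k,
                 n_pairs = c(MZ = dat$n_mz, DZ = dat$n_dz),
                 convergence = best$convergence,
                 data = dat),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  comp <- x$std[c("a2", "c2", "d2", "e2")]
  comp <- comp[comp > 0 | names(comp) == "e2"]
  cat(sprintf("%s twin model (%d MZ + %d DZ pairs)\n",
              x$model, x$n_pairs["MZ"], x$n_pairs["DZ"]))
  cat("  standardized: ",
      paste(sprintf("%s = %.3f", names(comp), comp), collapse = ", "), "\n")
  cat(sprintf("  -2LL = %.3f, AIC = %.3f (k = %d)\n",
              x$minus2LL, x$aic, x$k))
  invisible(x)
}

#' Intra-pair twin correlation
#'
#' Pearson correlation between the twins of each complete pair (in the
#' given y1, y2 order, no double entry), with a one-sided p-value from the
#' t transform (twin resemblance is a directed hypothesis).
#'
#' @param pairs data.frame with `y1`, `y2` (one zygosity).
#' @return list of class `twin_cor`: `r`, `df` (complete pairs - 2),
#'   `p_one_sided`, `n`.
#' @export
intrapair_correlation <- function(pairs) {
  ok <- is.finite(pairs$y1) & is.finite(pairs$y2)
  n <- sum(ok)
  if (n < 3) stop("need >= 3 complete pairs, got ", n)
  y1 <- pairs$y1[ok]; y2 <- pairs$y2[ok]
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0) {
    stop("undefined correlation: zero variance in a twin column")
  }
  r <- stats::cor(y1, y2)
  df <- n - 2L
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, df = df,
                 p_one_sided = stats::pt(tval, df, lower.tail = FALSE),
                 n = n),
            class = "twin_cor")
}

#' @export
print.twin_cor <- function(x, ...) {
  cat(sprintf("intra-pair r = %.3f (df = %d), one-sided p = %.4g\n",
              x$r, x$df, x$p_one_sided))
  invisible(x)
}

#' Choose between the ACE and ADE model families
#'
#' ADE is indicated when the MZ correlation exceeds twice the DZ
#' correlation (dominance inflates MZ resemblance specifically) and the DZ
#' correlation is nonnegative; otherwise ACE. Exact equality
#' `r_mz = 2 r_dz` points to AE, which is reachable from ACE by dropping
#' C, so ACE is returned there too.
#'
#' @param r_mz,r_dz intra-pair correlations (finite).
#' @return `"ACE"` or `"ADE"`.
#' @export
choose_model_family <- function(r_mz, r_dz) {
  stopifnot(is.finite(r_mz), is.finite(r_dz))
  if (r_mz > 2 * r_dz && r_dz >= 0) "ADE" else "ACE"
}

#' Likelihood-ratio test of a nested twin model
#'
#' @param full,reduced `twin_fit` objects fitted to identical data, the
#'   reduced model nested in the full one.
#' @return list: `chi2_diff`, `df_diff`, `p`.
#' @export
nested_comparison <- function(full, reduced) {
  stopifnot(inherits(full, "twin_fit"), inherits(reduced, "twin_fit"))
  chi2 <- reduced$minus2LL - full$minus2LL
  if (chi2 < -1e-4) {
    stop("reduced model fits better than the full model (chi2 = ",
         signif(chi2, 4), "); optimizer failure, refit with more starts")
  }
  chi2 <- max(0, chi2)
  df <- full$k - reduced$k
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else
    as.numeric(chi2 <= 0)
  list(chi2_diff = chi2, df_diff = df, p = p)
}

#' Path-dropping model selection within a twin-model family
#'
#' Fits the full family model (ACE or ADE, chosen from the twin
#' correlations unless forced), tests dropping the C (or D) path and - in
#' the ACE family - the A path by likelihood-ratio chi-square at
#' `alpha = 0.05`, prefers the most parsimonious non-rejected candidate
#' (AE-versus-CE resolved by lower AIC), and finally tests dropping down
#' to E. AIC is reported both as `-2LL + 2k` and as the chi-square-based
#' variant `chi2 - 2 df` relative to the full family model; the two
#' orderings are identical because they differ by a data constant.
#'
#' @param pairs twin-pair data.frame (see [fit_twin_model()]).
#' @param family `"auto"` (choose from correlations), `"ACE"` or `"ADE"`.
#' @param covariates,standardize,n_starts,seed passed to
#'   [fit_twin_model()].
#' @param alpha path-dropping test level, default 0.05.
#' @return list of class `twin_selection`: `best` (`twin_fit`), `family`,
#'   `fits` (all fitted models), `comparisons` (data.frame of nested tests
#'   and AICs), `r_mz`, `r_dz`.
#' @export
select_best_model <- function(pairs, family = "auto", covariates = TRUE,
                              standardize = TRUE, n_starts = 8, seed = 1L,
                              alpha = 0.05) {
  r_mz <- tryCatch(
    intrapair_correlation(pairs[pairs$zygosity == "MZ", ]), error = function(e) NULL)
  r_dz <- tryCatch(
    intrapair_correlation(pairs[pairs$zygosity == "DZ", ]), error = function(e) NULL)
  if (identical(family, "auto")) {
    if (is.null(r_mz) || is.null(r_dz)) {
      stop("cannot choose model family: too few complete pairs per zygosity")
    }
    family <- choose_model_family(r_mz$r, r_dz$r)
  }
  fit1 <- function(model) {
    fit_twin_model(pairs, model, covariates = covariates,
                   standardize = standardize, n_starts = n_starts,
                   seed = seed)
  }
  fits <- list()
  fits[[family]] <- fit1(family)
  fits$AE <- fit1("AE")
  fits$E <- fit1("E")
  mid_label <- if (family == "ACE") "C" else "D"
  drop_mid <- nested_comparison(fits[[family]], fits$AE)
  comparisons <- data.frame(test = paste0(family, " -> AE (drop ", mid_label, ")"),
                            chi2 = drop_mid$chi2_diff, df = drop_mid$df_diff,
                            p = drop_mid$p)
  candidates <- character(0)
  if (drop_mid$p > alpha) candidates <- c(candidates, "AE")
  if (family == "ACE") {
    fits$CE <- fit1("CE")
    drop_a <- nested_comparison(fits$ACE, fits$CE)
    comparisons <- rbind(comparisons,
                         data.frame(test = "ACE -> CE (drop A)",
                                    chi2 = drop_a$chi2_diff,
                                    df = drop_a$df_diff, p = drop_a$p))
    if (drop_a$p > alpha) candidates <- c(candidates, "CE")
  }
  best_label <- if (length(candidates) == 0) {
    family
  } else if (length(candidates) == 1) {
    candidates
  } else {
    # AE vs CE: non-nested, resolved by AIC
    candidates[which.min(vapply(fits[candidates], `[[`, 0, "aic"))]
  }
  # try collapsing further to E
  if (best_label %in% c("AE", "CE")) {
    drop_last <- nested_comparison(fits[[best_label]], fits$E)
    comparisons <- rbind(comparisons,
                         data.frame(test = paste0(best_label, " -> E"),
                                    chi2 = drop_last$chi2_diff,
                                    df = drop_last$df_diff, p = drop_last$p))
    if (drop_last$p > alpha) best_label <- "E"
  }
  full_m2 <- fits[[family]]$minus2LL
  full_k <- fits[[family]]$k
  aic_tab <- data.frame(
    model = names(fits),
    minus2LL = vapply(fits, `[[`, 0, "minus2LL"),
    k = vapply(fits, `[[`, 0L, "k"),
    aic = vapply(fits, `[[`, 0, "aic"))
  aic_tab$chi2_vs_full <- aic_tab$minus2LL - full_m2
  aic_tab$aic_chisq <- aic_tab$chi2_vs_full - 2 * (full_k - aic_tab$k)
  rownames(aic_tab) <- NULL
  structure(list(best = fits[[best_label]], family = family,
                 best_label = best_label, fits = fits,
                 comparisons = comparisons, aic_table = aic_tab,
                 r_mz = r_mz, r_dz = r_dz),
            class = "twin_selection")
}

#' @export
print.twin_selection <- function(x, ...) {
  cat(sprintf("family %s; best model: %s\n", x$family, x$best_label))
  if (!is.null(x$r_mz)) {
    cat(sprintf("  r_MZ = %.3f (df = %d), r_DZ = %.3f (df = %d)\n",
                x$r_mz$r, x$r_mz$df, x$r_dz$r, x$r_dz$df))
  }
  print(x$comparisons, row.names = FALSE)
  print(x$best)
  invisible(x)
}
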