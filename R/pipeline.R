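#' Study configuration
#'
#' Bundles every tunable of an end-to-end synthetic study: cohort size,
#' per-run generator template, the latent phenotype injected into the
#' blink-response kernel, and all analysis defaults (vigilance thresholds,
#' peak windows, minimum epochs, outlier rule, Bonferroni family size).
#' Defaults follow the analysis conventions documented in each stage.
#'
#' @param n_mz_pairs,n_dz_pairs twin-pair counts.
#' @param runs_per_subject runs recorded per subject; half are generated
#'   vigilant and half drowsy (odd counts favour vigilant).
#' @param run_params a [sim_run_params()] template; per-run seeds and
#'   closure targets are filled in by the pipeline.
#' @param vigilant_closure,drowsy_closure closure target fractions used
#'   for the vigilant-state and drowsy-state runs.
#' @param phenotype list describing the heritable latent trait injected
#'   into the generator: `model`, `a2`, `c2_or_d2`, `e2` (the twin
#'   decomposition of the latent z), `measure` (which eye measure carries
#'   it; only `"d_peak_amp"` is wired), `base` and `scale` mapping z to
#'   kernel dilation amplitude (au), and covariate slopes `beta_age`,
#'   `beta_sex`, `beta_vig` in latent-SD units.
#' @param heritability_measures measures to run the twin analysis on.
#' @param vigilance_thresholds,min_epochs,outlier_mult,alpha,n_tests
#'   analysis tunables (see the stage functions).
#' @param d_window_ms,c_window_ms peak search windows.
#' @param seed master seed; every stage seed derives from it.
#' @return validated `study_config` list.
#' @export
study_config <- function(n_mz_pairs = 44, n_dz_pairs = 36,
                         runs_per_subject = 4,
                         run_params = sim_run_params(duration_s = 160),
                         vigilant_closure = 0.03,
                         drowsy_closure = 0.25,
                         phenotype = list(model = "AE", a2 = 0.62,
                                          c2_or_d2 = 0, e2 = 0.38,
                                          measure = "d_peak_amp",
                                          base = 30, scale = 6,
                                          beta_age = 0, beta_sex = 0,
                                          beta_vig = 0),
                         heritability_measures = "d_peak_amp",
                         vigilance_thresholds = c(0.10, 0.40, 0.75),
                         min_epochs = 5,
                         outlier_mult = 2,
                         alpha = 0.05, n_tests = 9,
                         d_window_ms = c(50, 900),
                         c_window_ms = c(300, 2500),
                         seed = 1L) {
  stopifnot(inherits(run_params, "sim_run_params"))
  stopifnot(phenotype$measure %in% eye_measure_names())
  structure(as.list(environment()), class = "study_config")
}

# deterministic per-stage seed stream (kept below 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483399 + 1)
}

#' Collapse per-run measures to one value per subject and state
#'
#' Missing-aware mean over the available runs for every (subject, state,
#' measure) cell.
#'
#' @param measures data.frame with `subject`, `state` and measure columns.
#' @param measure_cols measure column names.
#' @return data.frame, one row per subject-state.
#' @export
collapse_runs_per_state <- function(measures,
                                    measure_cols = eye_measure_names()) {
  agg <- stats::aggregate(measures[measure_cols],
                          by = list(subject = measures$subject,
                                    state = measures$state),
                          FUN = function(v) {
                            v <- v[is.finite(v)]
                            if (length(v)) mean(v) else NA_real_
                          })
  agg
}

#' Run a full synthetic study end to end
#'
#' Generates a twin cohort whose latent trait modulates the blink-response
#' kernel, simulates and preprocesses every run, classifies vigilance
#' states and drops discarded runs, extracts the nine eye measures,
#' screens outliers, and produces the three report families: test-retest
#' reliability (ICC(2,k) per measure and state plus within-subject
#' profile reliability), the paired vigilant-versus-drowsy ANOVA, and the
#' twin heritability analysis with duplicated pair entries per vigilance
#' state and age/sex/vigilance covariates.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, TSV/JSON reports and a
#'   run manifest are written there.
#' @param verbose emit per-stage progress to stderr.
#' @return list of class `study_result`: `subjects`, `run_log`,
#'   `measures_run`, `measures_collapsed`, `reliability`, `anova`,
#'   `heritability`, `counts`.
#' @export
run_study <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message("[run_study] ", ...)
  ph <- config$phenotype

  # --- cohort with latent trait ---------------------------------------
  cohort <- simulate_twin_cohort(twin_cohort_spec(
    n_mz_pairs = config$n_mz_pairs, n_dz_pairs = config$n_dz_pairs,
    model = ph$model, a2 = ph$a2, c2_or_d2 = ph$c2_or_d2, e2 = ph$e2,
    beta_age = ph$beta_age, beta_sex = ph$beta_sex, beta_vig = ph$beta_vig,
    seed = derive_seed(config$seed, 1)))
  z1 <- attr(cohort, "z1"); z2 <- attr(cohort, "z2")
  subjects <- data.frame(
    subject = c(paste0("F", cohort$family_id, "T1"),
                paste0("F", cohort$family_id, "T2")),
    family_id = rep(cohort$family_id, 2),
    twin = rep(c(1L, 2L), each = nrow(cohort)),
    zygosity = rep(cohort$zygosity, 2),
    age = c(cohort$age1, cohort$age2),
    sex = c(cohort$sex1, cohort$sex2),
    latent = c(z1, z2))
  say(nrow(subjects), " subjects (", config$n_mz_pairs, " MZ + ",
      config$n_dz_pairs, " DZ pairs)")

  # --- simulate + preprocess + classify runs --------------------------
  n_vig <- ceiling(config$runs_per_subject / 2)
  run_rows <- list(); meas_rows <- list()
  counter <- 0L
  for (i in seq_len(nrow(subjects))) {
    kern <- config$run_params$kernel
    kern$d_amp <- max(1, ph$base + ph$scale * subjects$latent[i])
    for (r in seq_len(config$runs_per_subject)) {
      counter <- counter + 1L
      closure <- if (r <= n_vig) config$vigilant_closure else
        config$drowsy_closure
      rp <- config$run_params
      rp$kernel <- kern
      rp$closure_target_fraction <- closure
      rp$seed <- derive_seed(config$seed, 1000 + counter)
      sim <- simulate_pupil_run(rp)
      pp <- preprocess_run(sim$trace)
      state4 <- classify_run(pp$loss_fraction, config$vigilance_thresholds)
      state <- as.character(merge_drowsy(state4))
      run_rows[[counter]] <- data.frame(
        subject = subjects$subject[i], run = r,
        loss_fraction = pp$loss_fraction,
        state4 = as.character(state4), state = state)
      if (state != "Discarded") {
        m <- compute_eye_measures(pp, min_epochs = config$min_epochs,
                                  d_window_ms = config$d_window_ms,
                                  c_window_ms = config$c_window_ms)
        meas_rows[[length(meas_rows) + 1L]] <-
          cbind(data.frame(subject = subjects$subject[i], run = r,
                           state = state), m)
      }
    }
  }
  run_log <- do.call(rbind, run_rows)
  counts <- table(factor(run_log$state4,
                         c("Vigilant", "Drowsy", "VeryDrowsy", "Discarded")))
  say("runs: ", paste(names(counts), as.integer(counts), collapse = ", "))

  if (length(meas_rows) == 0) {
    say("no usable runs; downstream stages skipped")
    return(structure(list(subjects = subjects, run_log = run_log,
                          measures_run = NULL, measures_collapsed = NULL,
                          reliability = NULL, anova = NULL,
                          heritability = "no usable runs",
                          counts = counts),
                     class = "study_result"))
  }
  measures_run <- do.call(rbind, meas_rows)

  # --- collapse + outlier screen (per measure within state) -----------
  collapsed <- collapse_runs_per_state(measures_run)
  for (mc in eye_measure_names()) {
    for (st in unique(collapsed$state)) {
      idx <- collapsed$state == st
      collapsed[idx, mc] <- remove_outliers(collapsed[idx, mc],
                                            config$outlier_mult)
    }
  }

  # --- reliability -----------------------------------------------------
  reliability <- list()
  for (st in c("Vigilant", "AllDrowsy")) {
    sub <- measures_run[measures_run$state == st, , drop = FALSE]
    if (nrow(sub) == 0) next
    icc_tab <- lapply(eye_measure_names(), function(mc) {
      d <- data.frame(subject = sub$subject, run = sub$run,
                      value = sub[[mc]])
      res <- tryCatch(icc2k(d), error = function(e) NULL)
      data.frame(measure = mc, state = st,
                 icc = if (is.null(res)) NA_real_ else res$icc,
                 n_subjects = if (is.null(res)) NA_integer_ else res$n_subjects)
    })
    reliability[[st]] <- list(
      icc = do.call(rbind, icc_tab),
      within_subject = within_subject_reliability(sub))
  }

  # --- paired state ANOVA ----------------------------------------------
  wide <- function(mc, st) {
    v <- collapsed[collapsed$state == st, c("subject", mc)]
    stats::setNames(v[[mc]], v$subject)
  }
  anova_tab <- do.call(rbind, lapply(eye_measure_names(), function(mc) {
    vg <- wide(mc, "Vigilant"); dr <- wide(mc, "AllDrowsy")
    common <- intersect(names(vg), names(dr))
    res <- tryCatch(
      paired_state_anova(vg[common], dr[common],
                         alpha = config$alpha, n_tests = config$n_tests),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(measure = mc, F = NA, df1 = NA, df2 = NA, p = NA,
                        significant = NA))
    }
    data.frame(measure = mc, F = res$F, df1 = res$df[1], df2 = res$df[2],
               p = res$p, significant = res$significant_bonferroni)
  }))

  # --- heritability: duplicated pair entry per state -------------------
  heritability <- list()
  for (mc in config$heritability_measures) {
    pair_rows <- list()
    for (st in c("Vigilant", "AllDrowsy")) {
      vals <- wide(mc, st)
      vig_code <- if (st == "Vigilant") 1 else 2
      for (fi in cohort$family_id) {
        s1 <- paste0("F", fi, "T1"); s2 <- paste0("F", fi, "T2")
        y1 <- vals[s1]; y2 <- vals[s2]
        if (is.na(y1) || is.na(y2)) next
        j <- match(fi, cohort$family_id)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          family_id = fi, zygosity = cohort$zygosity[j],
          y1 = unname(y1), y2 = unname(y2),
          age1 = cohort$age1[j], age2 = cohort$age2[j],
          sex1 = cohort$sex1[j], sex2 = cohort$sex2[j],
          vig1 = vig_code, vig2 = vig_code)
      }
    }
    pairs <- do.call(rbind, pair_rows)
    if (is.null(pairs) || nrow(pairs) < 10) {
      heritability[[mc]] <- "no usable runs"
      next
    }
    sel <- select_best_model(pairs, covariates = TRUE,
                             seed = derive_seed(config$seed, 7),
                             alpha = config$alpha)
    cis <- list()
    for (comp in c("a2", "c2", "d2", "e2")) {
      if (comp %in% c(paste0(tolower(strsplit(sel$best_label, "")[[1]]), "2"))) {
        cis[[comp]] <- tryCatch(profile_ci(sel$best, comp),
                                error = function(e) c(lower = NA, upper = NA))
      }
    }
    heritability[[mc]] <- list(selection = sel, ci = cis,
                               n_pair_rows = nrow(pairs))
    say("heritability[", mc, "]: best ", sel$best_label,
        ", a2 = ", round(sel$best$std["a2"], 3))
  }

  result <- structure(list(subjects = subjects, run_log = run_log,
                           measures_run = measures_run,
                           measures_collapsed = collapsed,
                           reliability = reliability,
                           anova = anova_tab,
                           heritability = heritability,
                           counts = counts,
                           seed = config$seed),
                      class = "study_result")
  if (!is.null(out_dir)) write_study_reports(result, out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n  runs: ",
      paste(names(x$counts), as.integer(x$counts), collapse = ", "), "\n")
  if (!is.null(x$anova)) {
    cat("  ANOVA (paired vigilant vs all-drowsy):\n")
    print(x$anova, row.names = FALSE)
  }
  for (mc in names(x$heritability)) {
    h <- x$heritability[[mc]]
    if (is.character(h)) { cat("  heritability[", mc, "]: ", h, "\n"); next }
    cat("  heritability[", mc, "]: best ", h$selection$best_label,
        ", a2 = ", round(h$selection$best$std["a2"], 3), "\n", sep = "")
  }
  invisible(x)
}

#' Write study reports to disk
#'
#' Emits TSV tables (run log, per-run measures, collapsed measures, ICC
#' table, ANOVA table, heritability summary) and a JSON manifest (seed,
#' stage counts) under `out_dir`.
#'
#' @param result a `study_result` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$run_log, "run_log.tsv")
  if (!is.null(result$measures_run)) {
    wt(result$measures_run, "measures_per_run.tsv")
    wt(result$measures_collapsed, "measures_collapsed.tsv")
    icc_all <- do.call(rbind, lapply(result$reliability, `[[`, "icc"))
    if (!is.null(icc_all)) wt(icc_all, "reliability_icc.tsv")
    wt(result$anova, "anova_state.tsv")
  }
  herit <- lapply(result$heritability, function(h) {
    if (is.character(h)) return(list(status = h))
    list(best_model = h$selection$best_label,
         family = h$selection$family,
         r_mz = h$selection$r_mz$r, r_dz = h$selection$r_dz$r,
         std = as.list(h$selection$best$std),
         minus2LL = h$selection$best$minus2LL,
         aic_table = h$selection$aic_table,
         ci = lapply(h$ci, as.list),
         n_pair_rows = h$n_pair_rows)
  })
  jsonlite::write_json(
    list(seed = result$seed,
         counts = as.list(as.integer(result$counts)),
         heritability = herit),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}
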