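# bipr: blink-induced pupillary response analysis and twin heritability

`bipr` is an R package for researchers who study arousal and oculomotor
traits with resting-state eye tracking. Every eye blink is followed by a
stereotyped pupil-size waveform — a dilation peak (**D**) around 500 ms
after blink onset and a constriction trough (**C**) around 1 s — called
the blink-induced pupillary response (BIPR). The package implements the
full analysis chain needed to treat blink and BIPR parameters as
individual-difference phenotypes:

1. **Preprocessing** of EyeLink-ASC-style pupil recordings: blink
   detection by the 40–400 ms pupil-loss rule, least-squares cubic
   interpolation of blink gaps, zero-phase FIR band-pass filtering
   (0.02–4 Hz), and downsampling to 100 Hz.
2. **Vigilance classification** of each run from its pupil-loss
   fraction: vigilant (< 10%), drowsy (10–40%), very drowsy (40–75%),
   discarded (> 75%); drowsy and very drowsy merge to "All Drowsy".
3. **BIPR feature extraction**: blink-locked epochs (−2 s … +3 s,
   baselined to −200…0 ms), per-run average profiles, and nine measures —
   blink rate, blink duration, pupil size, D/C peak times and
   amplitudes, D–C time difference, and D–C peak-drop magnitude — with a
   2×IQR outlier screen.
4. **Measurement statistics**: test–retest reliability via ICC(2,k)
   under a two-way random-effects model, within-subject profile
   reliability, and a paired vigilant-vs-drowsy one-way ANOVA with
   Bonferroni correction (α = 0.05/9 = 0.0056).
5. **Twin heritability**: intra-pair correlations, maximum-likelihood
   ACE/ADE structural-equation models with MZ/DZ cross-twin correlations
   1/0.5 (A), 1/1 (C), 1/0.25 (D), age/sex/vigilance covariates, nested
   χ² path-dropping, AIC model selection, and profile-likelihood 95%
   confidence intervals. Heritability a² is the standardized additive
   genetic variance fraction of the best-fitting model.
6. **Synthetic data**: generators for pupil runs (blinks, eye closures,
   injected D/C kernel), reliability designs, and twin cohorts with
   known variance components, so that every stage has a
   parameter-recovery test surface. Real HCP recordings are
   access-restricted and are not required anywhere.

## Worked example

Simulate one drowsy 160 s recording, preprocess it, and extract the nine
eye measures:

```r
library(bipr)
sim <- simulate_pupil_run(sim_run_params(duration_s = 160,
                                         closure_target_fraction = 0.15,
                                         seed = 7))
pp <- preprocess_run(sim$trace)
as.character(merge_drowsy(classify_run(pp$loss_fraction)))
#> [1] "AllDrowsy"
round(compute_eye_measures(pp), 2)
#>   blink_rate blink_duration pupil_size d_peak_time d_peak_amp c_peak_time
#> 1      19.85         202.53    1503.31         500      24.06         980
#>   c_peak_amp dc_time_diff dc_magnitude_drop n_epochs
#> 1     -20.39          480             44.45       38
```

The injected response kernel had its dilation peak at 500 ms and its
constriction trough at 1 s; the pipeline recovers D at 500 ms and C at
980 ms (the 100 Hz grid and the band-pass account for the small shift),
with 38 valid blink epochs averaged. Blink rate is per minute of
eyes-open time, pupil size is the mean of the interpolated, unfiltered
trace in tracker units.

Fit twin models to a simulated cohort generated under an AE model with
heritability a² = 0.6:

```r
coh <- simulate_twin_cohort(twin_cohort_spec(300, 300, model = "AE",
                                             a2 = 0.6, e2 = 0.4, seed = 2))
sel <- select_best_model(coh, covariates = FALSE, seed = 1)
sel
#> family ADE; best model: AE
#>   r_MZ = 0.630 (df = 298), r_DZ = 0.246 (df = 298)
#>                test        chi2 df            p
#>  ADE -> AE (drop D)   0.6989345  1 4.031419e-01
#>             AE -> E 169.5135537  1 9.449571e-39
#> AE twin model (300 MZ + 300 DZ pairs)
#>   standardized:  a2 = 0.605, e2 = 0.395
#>   -2LL = 3234.939, AIC = 3240.939 (k = 3)
ci <- profile_ci(sel$best, "a2")
sprintf("a2 = %.2f, 95%% CI [%.2f, %.2f]", sel$best$std[["a2"]], ci[1], ci[2])
#> [1] "a2 = 0.60, 95% CI [0.54, 0.66]"
```

Here r_MZ exceeds twice r_DZ, so the ADE family is fitted first; the D
path drops without loss of fit (χ²(1) = 0.70, p = 0.40), the A path does
not (p ≈ 1e-39), and AE is selected with â² = 0.60 covering the
generating value.

An end-to-end synthetic study (cohort → recordings → preprocessing →
states → measures → reliability, ANOVA, heritability reports) runs with
`run_study(study_config(...))`; a command-line driver with `simulate`,
`preprocess`, `measures`, `reliability`, `heritability` and `run-all`
subcommands is in `inst/scripts/bipr-cli.R`.

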