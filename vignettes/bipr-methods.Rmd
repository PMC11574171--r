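---
title: "Methods: pupillometry preprocessing, BIPR extraction and twin heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupillometry preprocessing, BIPR extraction and twin heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in `bipr`,
the tunable parameters and their defaults, the numerical choices made
where the method leaves room, and what the synthetic-data generator does
and does not establish. It states no empirical result that the test
suite does not itself compute.

## 1. The measurement model

A resting-state pupil recording is a time series of pupil size in
arbitrary tracker units (au), sampled at 500 Hz or 1 kHz, with the value
`0.0` wherever the pupil is not detected. Loss intervals of 40–400 ms
are blinks; anything else (brief flickers, long eye closures) is a
closure. Blinks are recoverable measurement gaps; closures are genuine
eyes-closed time and index drowsiness.

The preprocessing chain is fixed: parse → up-sample to 1 kHz → detect
blinks → interpolate blink gaps → band-pass 0.02–4 Hz (zero-phase) →
decimate to 100 Hz. Each stage tags its output, and every stage rejects
input with the wrong tag, so the order cannot be violated silently.
Vendor blink labels in the input (e.g. `EBLINK` event lines) are
deliberately ignored: blinks are re-derived from the pupil signal so
that the same rule is applied to real and synthetic data.

Per run, nine measures are computed:

* **blink rate** — blinks per minute of eyes-open time (run duration
  minus total closure time; blinks count as open);
* **blink duration** — mean loss duration of blinks (ms);
* **pupil size** — mean of the interpolated, *unfiltered* trace over
  non-missing samples. The 0.02 Hz high-pass removes the mean, so the
  mean must be taken before filtering; this is the only self-consistent
  reading and is applied uniformly;
* **six BIPR parameters** — from the per-run average of blink-locked
  epochs (−2 s … +3 s at 100 Hz, 500 samples, baselined to the mean of
  the −200…0 ms window): D-peak time and amplitude (maximum in
  [50, 900] ms, must be positive), C-peak time and amplitude (minimum in
  [300, 2500] ms constrained after D, must be negative), their time
  difference, and the peak-drop magnitude `d_amp − c_amp`. The peak-drop
  definition is a package decision — the name alone does not pin down a
  formula — and is therefore configurable in one place.

Epochs whose full window leaves the run are dropped, not padded. An
epoch is invalid when more than 40% of its 0–3 s window is missing
(closures after the blink); a run needs at least `min_epochs = 5` valid
epochs for a usable profile, since single-epoch profiles make the peak
features noise-dominated. Outliers beyond 2×IQR from the quartiles
(type-7 quantiles, the common linear-interpolation convention) are
removed per measure within each vigilance state.

## 2. Filtering: realization of the 0.02–4 Hz zero-phase band-pass

A literal 0.02 Hz FIR high-pass at 1 kHz needs on the order of 10⁵ taps.
`bandpass_filter()` therefore realizes the band-pass as:

1. a 751-tap Hamming-windowed sinc low-pass at 4 Hz, applied
   forward–backward (odd-reflection padding of one filter order per
   side, both passes fused into a single FFT product);
2. a high-pass obtained by subtracting a slow trend: the signal is
   decimated 10:1, low-passed at 0.02 Hz with a 15001-tap FIR
   (forward–backward), and linearly re-expanded. The trend is computed
   in both time directions and averaged, which makes the whole operation
   commute with time reversal to numerical precision — the property the
   test suite checks at 1e-8.

This keeps the filtering entirely at 1 kHz (band-pass before
downsampling, matching the stated order of operations) at roughly the
cost of the decimated design. DC is removed *exactly*: the low-pass taps
are normalized to unit sum, so a constant input yields a constant trend
and a zero output. The decimation to 100 Hz afterwards keeps every 10th
sample — the 4 Hz low-pass is the anti-alias filter — and ORs the
missingness mask over each 10-sample block.

Two consequences worth knowing: the 15001-tap trend filter requires at
least ~150 s of signal (shorter runs raise an explicit error naming the
minimum), and signal components near the 0.02 Hz edge (periods of about
a minute) are only partially passed.

Closure gaps are bridged linearly *for the duration of filtering only*
and re-masked afterwards: closures are never interpolated as data; the
bridge merely prevents edge transients from leaking into valid samples.

Blink gaps, by contrast, are filled before filtering, by a least-squares
cubic fitted to 100 ms anchor windows of valid samples on each side of
the gap. An *interpolating* spline through every (noisy) anchor sample
oscillates badly inside the gap; the LS cubic reproduces polynomial
signals up to degree 3 exactly — which is what the recovery tests
require — while averaging the noise. A blink at a trace edge falls back
to linear extrapolation from the available side, with a warning.

## 3. Vigilance states

Each run is classified from the fraction of samples with no detected
pupil, computed at 1 kHz *before* interpolation (blink gaps count):
vigilant < 0.10 ≤ drowsy < 0.40 ≤ very drowsy ≤ 0.75 < discarded. The
interval endpoints overlap in their verbal definition; the package fixes
them left-closed at 0.10 and 0.40 and right-closed at 0.75 (so 0.10 →
Drowsy, 0.40 → VeryDrowsy, 0.75 → VeryDrowsy) and exposes the cut points
as configuration. Drowsy and very drowsy merge to "All Drowsy" for all
state-contrast analyses; discarded runs leave the pipeline entirely.

## 4. Reliability and state statistics

**ICC(2,k)** treats subjects and run slots as crossed random effects:
`value ~ (1|subject) + (1|run)`, fitted by REML (`lme4`), with
`ICC = σ²_subject / (σ²_subject + (σ²_run + σ²_error)/k̄)` and `k̄` the
mean number of runs per retained subject (subjects with a single run are
dropped). On balanced data the REML components coincide with the
classical ANOVA mean squares, so the estimate equals the Shrout–Fleiss
average-measure formula `(MSR − MSE)/(MSR + (MSC − MSE)/n)`; the test
suite asserts this to 1e-6. Two caveats are documented rather than
hidden: REML truncates negative variance components at zero, so the
equivalence holds when the ANOVA estimates are interior; and for
unbalanced designs the `k̄` aggregation is a package choice (a harmonic
mean would be defensible too) — recovery is therefore validated by
simulation against the generator's known components rather than against
any published table.

**Within-subject reliability** z-scores each measure across all runs of
a state pooled over subjects, then correlates the nine-measure vectors
of every run pair within a subject (pairwise-complete, at least 3
overlapping measures) and averages over pairs.

**State contrast**: subjects contributing both a vigilant and an
all-drowsy value (runs within a state collapsed by averaging) enter a
two-group one-way ANOVA per measure — deliberately the plain two-group
form, not repeated measures, giving df = (1, 2m−2) — with significance
flagged at the Bonferroni-adjusted α = 0.05/9 ≈ 0.0056 for the
nine-measure family.

## 5. Twin variance decomposition

For one measure in one state, each twin pair contributes a bivariate
observation. A family appears once per vigilance state (the
duplicated-entry design, with vigilance as a mean covariate); the
resulting non-independence between a family's rows is inherited from the
design and documented, not corrected.

The phenotype is z-scored over all individuals entering a fit. The mean
model is `β0 + β_age·age + β_sex·sex + β_vig·vig` (sex 1/2, vigilance
1/2; covariates constant in the data are dropped as unidentifiable). The
covariance model per zygosity is

|        | total variance | MZ covariance | DZ covariance |
|--------|----------------|---------------|---------------|
| ACE    | a²+c²+e²       | a²+c²         | ½a²+c²        |
| ADE    | a²+d²+e²       | a²+d²         | ½a²+¼d²       |

with free parameters the *path coefficients* (a, c or d, e), so the
components are nonnegative by construction and the E path is bounded
away from zero (positive-definite covariance). The likelihood is the
product of bivariate normal densities over complete pairs (listwise
deletion when a twin's phenotype is missing). Optimization is
quasi-Newton (L-BFGS-B) with 8 seeded multi-starts — the likelihood is
multimodal in the sign of each path, and bounding paths at zero plus
multi-start makes that harmless. An exact sufficient-statistics grid
search serves as the independent oracle in the tests.

**Family choice**: ADE is considered when r_MZ > 2·r_DZ *and* r_DZ ≥ 0;
otherwise ACE. Exact equality points to AE, reachable from ACE by
dropping C, so the boundary maps to ACE. The r_DZ ≥ 0 guard matches how
negative DZ correlations are handled in practice (a DE model being
biologically implausible, and ADE adding no explanatory power for
anti-correlated DZ twins).

**Selection**: fit the family model; test dropping C (or D), and in the
ACE family dropping A, by the χ² difference of −2LL at α = 0.05; keep
the most parsimonious non-rejected candidate, breaking the non-nested
AE-vs-CE tie by AIC; finally test collapsing to E. AIC is reported both
as −2LL + 2k and as the χ²-versus-full variant (χ² − 2Δdf); the two
differ by a data constant and rank models identically (asserted in the
tests).

**Profile CIs**: the standardized fraction of interest (e.g. a²/V) is
held fixed while total variance, the remaining fraction and the mean
parameters are re-optimized; the 95% bound is where −2LL rises 3.841
above its minimum. Bounds are reported on the standardized scale and the
lower bound may be searched below zero — the likelihood stays defined
while the implied covariance matrices remain positive definite — which
reproduces the convention of printing slightly negative lower bounds
instead of clamping at zero. A bound that cannot be bracketed is
reported at the search boundary and flagged.

## 6. The synthetic world

The generator is a pure function of its specification and seed.

A simulated run is baseline + slow sinusoidal drift + white noise, with
three event processes: blinks (renewal process with refractory dead
time; the exponential rate is corrected so the expected count equals the
requested rate × duration), a blink-locked response kernel added after
every blink, and closures accumulated to a target loss fraction by
free-segment splitting. Defaults: 1500 au baseline, 50 au drift with a
60 s period (chosen to straddle the 0.02 Hz edge so the high-pass is
exercised meaningfully), 10 au noise, 15 blinks/min, blink durations
60–350 ms, closures 0.6–4 s. Half of the blinks keep a closure-free 3 s
tail so valid epochs exist by construction. The blink range default
avoids the 40/400 ms rule boundaries because upsampling a 500 Hz
recording widens each loss interval by one 1 ms sample, which would
otherwise flip boundary-length events across the classification edge.

The response kernel is the sum of a positive and a negative Gaussian
(defaults: +30 au at 500 ms, sd 100 ms; −20 au at 1000 ms, sd 180 ms).
Gaussians make the true peak locations analytically known; the default
widths keep the bumps nearly disjoint so the argmax of their sum stays
within ~2 ms of the nominal latencies. The amplitude scale in au is a
free choice — no claim is made that it matches any particular tracker's
magnitudes.

Twin cohorts draw latent components as common/unique mixtures with the
exact theoretical cross-twin correlations (A: 1 MZ / 0.5 DZ; C: 1/1;
D: 1/0.25; E: independent), so the covariate-free phenotype has unit
variance when the fractions sum to one. The end-to-end study maps each
subject's latent trait onto the kernel's dilation amplitude, simulates
and preprocesses every run, and hands the measured `d_peak_amp` to the
twin analysis — so the heritability recovered at the end has passed
through blink detection, interpolation, filtering, epoching and peak
finding, not just through the fitting code.

What the generator does *not* emulate: gaze and saccade dynamics,
luminance responses, pupil oscillation spectra of real drowsiness,
asymmetric or reopening-artifact blink profiles, and any realistic
distribution of measurement artifacts. A green end-to-end test
establishes that the pipeline recovers what it was told the world
contains — it does not establish that real recordings satisfy those
assumptions.

## 7. Scale choices and limitations

* Synthetic runs default to 160 s — just above the ~150 s minimum the
  0.02 Hz high-pass imposes — so that full studies (160 subjects × 4
  runs) fit in minutes; real resting-state runs are several times
  longer, which only helps the filter and the epoch counts.
* The ICC's unbalanced-design aggregation and the REML boundary
  truncation are the two places where a different software stack could
  produce slightly different reliability numbers; both are documented
  above.
* Peak times inherit the 10 ms resolution of the 100 Hz epoch grid.
* The duplicated pair entry across vigilance states understates
  standard errors in the twin fits (rows from one family are not
  independent); this mirrors the design being reproduced.
* Model selection at small cohort sizes (tens of pairs) is noisy by
  nature; the selection-consistency guarantees in the tests are stated
  at 500+500 pairs.
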