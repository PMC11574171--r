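# Blink-locked epoching and BIPR feature extraction at 100 Hz.
# The epoch timebase is fixed: 500 samples covering -2.0 s ... +2.99 s
# around blink onset (sample k has time (k - 201) * 10 ms), baselined to
# the mean of the 20 samples in the -200..0 ms window.

EPOCH_PRE <- 200L    # samples before onset
EPOCH_POST <- 300L   # samples from onset on
EPOCH_LEN <- EPOCH_PRE + EPOCH_POST
BASELINE_N <- 20L    # -200..0 ms at 100 Hz

#' Epoch timebase
#'
#' @return the 500 per-sample times (ms relative to blink onset) of a BIPR
#'   epoch or profile.
#' @export
epoch_times_ms <- function() (seq_len(EPOCH_LEN) - EPOCH_PRE - 1L) * 10

#' Extract baselined blink-locked epochs
#'
#' For every blink whose full -2 s ... +3 s window lies inside the run, the
#' 100 Hz pupil signal is cut out and baselined to the mean of the
#' non-missing samples in the -200..0 ms pre-onset window. Epochs whose
#' window crosses the run boundary are dropped, not padded. An epoch is
#' `valid` when at most 40% of the samples in the 0-3 s post-onset window
#' are missing (longer eye closures following the blink invalidate it) and
#' the baseline window contains at least one usable sample.
#'
#' @param trace a [pupil_trace()] at stage `"downsampled"` (100 Hz).
#' @param blinks data.frame with `onset_ms` (from [detect_blinks()]).
#' @param max_missing_post maximal tolerated missing fraction in the 0-3 s
#'   window, default 0.40.
#' @return list of epochs, each a list with `values` (500 samples, NA where
#'   missing), `valid`, `missing_fraction_post`, `onset_ms`. The number of
#'   boundary-dropped blinks is attached as attribute `n_dropped`.
#' @export
extract_epochs <- function(trace, blinks, max_missing_post = 0.40) {
  assert_stage(trace, "downsampled", "extract_epochs")
  n <- length(trace$pupil)
  fs <- trace$sampling_hz
  stopifnot(fs == 100)
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(blinks))) {
    c0 <- round((blinks$onset_ms[i] - trace$start_time_ms) * fs / 1000) + 1L
    lo <- c0 - EPOCH_PRE
    hi <- c0 + EPOCH_POST - 1L
    if (lo < 1L || hi > n) {
      dropped <- dropped + 1L
      next
    }
    v <- trace$pupil[lo:hi]
    v[trace$missing[lo:hi]] <- NA_real_
    base_idx <- (EPOCH_PRE - BASELINE_N + 1L):EPOCH_PRE
    base <- mean(v[base_idx], na.rm = TRUE)
    post_idx <- (EPOCH_PRE + 1L):EPOCH_LEN
    mf <- mean(is.na(v[post_idx]))
    valid <- is.finite(base) && mf <= max_missing_post
    out[[length(out) + 1L]] <- list(values = v - base,
                                    valid = valid,
                                    missing_fraction_post = mf,
                                    onset_ms = blinks$onset_ms[i])
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Average valid epochs into a per-run BIPR profile
#'
#' Pointwise mean over valid epochs, ignoring missing samples per
#' timepoint. Runs with fewer than `min_epochs` valid epochs yield no
#' profile (`NULL`): single-epoch profiles make peak features
#' noise-dominated.
#'
#' @param epochs list from [extract_epochs()].
#' @param min_epochs minimum number of valid epochs, default 5.
#' @return list with `values` (500-sample mean waveform) and `n_epochs`,
#'   or `NULL` if too few valid epochs.
#' @export
average_bipr <- function(epochs, min_epochs = 5) {
  valid <- Filter(function(e) isTRUE(e$valid), epochs)
  if (length(valid) < min_epochs) return(NULL)
  mat <- vapply(valid, `[[`, numeric(EPOCH_LEN), "values")
  list(values = rowMeans(mat, na.rm = TRUE), n_epochs = length(valid))
}

#' Locate the dilation (D) and constriction (C) peaks of a BIPR profile
#'
#' D is the maximum of the profile within the D search window and must be
#' positive; C is the minimum within the C window, constrained to occur
#' after D, and must be negative. A peak that fails its sign constraint is
#' reported as missing (NA). Times are in ms after blink onset.
#'
#' @param profile list from [average_bipr()] (or any list with a 500-sample
#'   `values` element on the standard epoch timebase).
#' @param d_window_ms D search window, default `c(50, 900)`.
#' @param c_window_ms C search window, default `c(300, 2500)`.
#' @return named numeric vector `d_peak_time`, `d_peak_amp`, `c_peak_time`,
#'   `c_peak_amp` (NA where undetermined).
#' @export
find_bipr_peaks <- function(profile, d_window_ms = c(50, 900),
                            c_window_ms = c(300, 2500)) {
  out <- c(d_peak_time = NA_real_, d_peak_amp = NA_real_,
           c_peak_time = NA_real_, c_peak_amp = NA_real_)
  if (is.null(profile)) return(out)
  v <- profile$values
  tt <- epoch_times_ms()
  d_idx <- which(tt >= d_window_ms[1] & tt <= d_window_ms[2] & !is.na(v))
  if (length(d_idx)) {
    di <- d_idx[which.max(v[d_idx])]
    if (v[di] > 0) {
      out["d_peak_time"] <- tt[di]
      out["d_peak_amp"] <- v[di]
    }
  }
  if (is.finite(out["d_peak_time"])) {
    c_idx <- which(tt >= max(c_window_ms[1], out["d_peak_time"] + 10) &
                     tt <= c_window_ms[2] & !is.na(v))
    if (length(c_idx)) {
      ci <- c_idx[which.min(v[c_idx])]
      if (v[ci] < 0) {
        out["c_peak_time"] <- tt[ci]
        out["c_peak_amp"] <- v[ci]
      }
    }
  }
  out
}

#' Per-run eye measures
#'
#' Computes the nine per-run scalars: blink rate (blinks per minute of
#' eyes-open time, i.e. run duration minus total closure time), mean blink
#' duration (ms), mean pupil size (au, on the interpolated unfiltered
#' trace), and the six BIPR parameters (D/C peak time and amplitude, D-C
#' time difference, D-C peak-drop magnitude, defined as
#' `d_peak_amp - c_peak_amp`).
#'
#' @param run output of [preprocess_run()].
#' @param min_epochs minimum valid epochs for a usable BIPR profile.
#' @param d_window_ms,c_window_ms peak search windows, see
#'   [find_bipr_peaks()].
#' @return one-row data.frame with the nine measures plus `n_epochs`;
#'   missing fields are NA.
#' @export
compute_eye_measures <- function(run, min_epochs = 5,
                                 d_window_ms = c(50, 900),
                                 c_window_ms = c(300, 2500)) {
  dur_min <- length(run$trace100$pupil) / run$trace100$sampling_hz / 60
  closed_min <- sum(run$closures$duration_ms) / 1000 / 60
  open_min <- dur_min - closed_min
  out <- data.frame(blink_rate = NA_real_, blink_duration = NA_real_,
                    pupil_size = NA_real_,
                    d_peak_time = NA_real_, d_peak_amp = NA_real_,
                    c_peak_time = NA_real_, c_peak_amp = NA_real_,
                    dc_time_diff = NA_real_, dc_magnitude_drop = NA_real_,
                    n_epochs = 0L)
  if (open_min <= 0) return(out)
  nb <- nrow(run$blinks)
  out$blink_rate <- nb / open_min
  if (nb > 0) out$blink_duration <- mean(run$blinks$duration_ms)
  out$pupil_size <- run$pupil_size
  epochs <- extract_epochs(run$trace100, run$blinks)
  profile <- average_bipr(epochs, min_epochs = min_epochs)
  if (!is.null(profile)) {
    pk <- find_bipr_peaks(profile, d_window_ms, c_window_ms)
    out$d_peak_time <- pk["d_peak_time"]
    out$d_peak_amp <- pk["d_peak_amp"]
    out$c_peak_time <- pk["c_peak_time"]
    out$c_peak_amp <- pk["c_peak_amp"]
    if (is.finite(pk["d_peak_time"]) && is.finite(pk["c_peak_time"])) {
      out$dc_time_diff <- pk["c_peak_time"] - pk["d_peak_time"]
      out$dc_magnitude_drop <- pk["d_peak_amp"] - pk["c_peak_amp"]
    }
    out$n_epochs <- profile$n_epochs
  }
  out
}

#' Names of the nine per-run eye measures
#' @return character vector of measure column names.
#' @export
eye_measure_names <- function() {
  c("blink_rate", "blink_duration", "pupil_size",
    "d_peak_time", "d_peak_amp", "c_peak_time", "c_peak_amp",
    "dc_time_diff", "dc_magnitude_drop")
}

#' Interquartile-range outlier screen
#'
#' Keeps values `v` with `Q1 - mult*IQR <= v <= Q3 + mult*IQR`, where Q1/Q3
#' are the 25%/75% quantiles (type-7 linear interpolation) of the finite
#' values and `mult` defaults to 2. Missing values pass through untouched;
#' with fewer than 4 finite values nothing is excluded.
#'
#' @param values numeric vector (may contain NA).
#' @param mult IQR multiplier, default 2.
#' @return `values` with outliers replaced by NA.
#' @export
remove_outliers <- function(values, mult = 2) {
  fin <- is.finite(values)
  if (sum(fin) < 4) return(values)
  q <- stats::quantile(values[fin], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values
  bad <- fin & (values < q[1] - mult * iqr | values > q[2] + mult * iqr)
  out[bad] <- NA_real_
  out
}
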