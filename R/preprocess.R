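#' Parse EyeLink-ASC-style sample lines
#'
#' Reads the plain-sample dialect of EyeLink ASC exports: tab- or
#' whitespace-separated lines `time_ms gaze_x gaze_y pupil`, where a lost
#' pupil is printed as `0.0`. Lines whose first token is not numeric
#' (`MSG`, `EBLINK`, `SSACC`, ... event lines) are skipped: vendor blink
#' labels are deliberately discarded and blinks are re-derived from the
#' pupil signal itself by [detect_blinks()].
#'
#' @param con a file path, connection, or character vector of lines.
#' @return A [pupil_trace()] at stage `"raw"`. The sampling rate is
#'   inferred from the median timestamp step (1 ms -> 1000 Hz, 2 ms -> 500
#'   Hz).
#' @export
parse_asc_samples <- function(con) {
  lines <- if (is.character(con) && length(con) == 1 && file.exists(con)) {
    readLines(con)
  } else if (is.character(con)) {
    con
  } else {
    readLines(con)
  }
  first_tok <- sub("^\\s*(\\S+).*$", "\\1", lines)
  is_sample <- grepl("^[0-9]+(\\.[0-9]+)?$", first_tok)
  lines <- lines[is_sample]
  if (length(lines) == 0) {
    stop("empty input: no sample lines (numeric first field) found")
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4)) {
    fields[nf < 4] <- lapply(fields[nf < 4], function(f) c(f, rep(NA, 4 - length(f))))
  }
  tm <- as.numeric(vapply(fields, `[`, "", 1))
  pupil <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
  bad <- which(diff(tm) <= 0)
  if (length(bad)) {
    stop("non-monotonic timestamps: sample line ", bad[1] + 1,
         " (t = ", tm[bad[1] + 1], ") does not advance past t = ", tm[bad[1]])
  }
  step <- stats::median(diff(tm))
  fs <- if (isTRUE(all.equal(step, 1))) 1000 else if (isTRUE(all.equal(step, 2))) 500 else {
    stop("unsupported sampling rate: median timestamp step ", step,
         " ms (expected 1 or 2 ms)")
  }
  missing <- !is.finite(pupil) | pupil == 0
  pupil[missing] <- 0
  pupil_trace(pupil, fs, missing = missing, start_time_ms = tm[1],
              stage = "raw")
}

#' Up-sample a raw trace to 1 kHz
#'
#' 500 Hz recordings are up-sampled to 1 kHz by linear interpolation at the
#' midpoints (output length 2n-1, end timestamps preserved); 1 kHz
#' recordings pass through unchanged apart from the stage tag. The
#' missingness mask is up-sampled conservatively: an inserted sample is
#' missing if either flanking source sample is missing.
#'
#' @param trace a raw [pupil_trace()] at 500 or 1000 Hz.
#' @return A [pupil_trace()] at 1000 Hz, stage `"upsampled"`.
#' @export
resample_to_1khz <- function(trace) {
  assert_stage(trace, "raw", "resample_to_1khz")
  if (trace$sampling_hz == 1000) {
    out <- trace
    out$stage <- "upsampled"
    return(out)
  }
  if (trace$sampling_hz != 500) {
    stop("unsupported sampling rate: ", trace$sampling_hz, " Hz")
  }
  n <- length(trace$pupil)
  x <- trace$pupil
  m <- trace$missing
  out_n <- 2L * n - 1L
  px <- numeric(out_n)
  pm <- logical(out_n)
  px[seq(1, out_n, by = 2)] <- x
  pm[seq(1, out_n, by = 2)] <- m
  px[seq(2, out_n, by = 2)] <- (x[-n] + x[-1]) / 2
  pm[seq(2, out_n, by = 2)] <- m[-n] | m[-1]
  px[pm] <- 0
  pupil_trace(px, 1000, missing = pm, start_time_ms = trace$start_time_ms,
              stage = "upsampled")
}

# maximal contiguous TRUE runs of a logical vector -> matrix [start, end]
missing_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect blinks and eye closures from pupil loss
#'
#' Every maximal contiguous interval of undetected pupil is classified by
#' its duration: 40-400 ms is a blink, anything else (shorter flickers or
#' longer eye closures) is a closure. The onset is the time of the first
#' lost sample. Classification is exhaustive and exclusive: every lost
#' interval becomes exactly one event.
#'
#' @param trace a [pupil_trace()] at stage `"upsampled"` (1 kHz).
#' @param blink_range_ms inclusive (min, max) blink duration rule,
#'   default `c(40, 400)`.
#' @return list with data.frames `blinks` and `closures`, each with columns
#'   `onset_ms`, `duration_ms`, time-ordered.
#' @export
detect_blinks <- function(trace, blink_range_ms = c(40, 400)) {
  assert_stage(trace, "upsampled", "detect_blinks")
  runs <- missing_runs(trace$missing)
  ms <- 1000 / trace$sampling_hz
  tm <- trace$start_time_ms
  if (nrow(runs) == 0) {
    empty <- data.frame(onset_ms = numeric(0), duration_ms = numeric(0))
    return(list(blinks = empty, closures = empty))
  }
  onset <- tm + (runs[, "start"] - 1) * ms
  dur <- (runs[, "end"] - runs[, "start"] + 1) * ms
  is_blink <- dur >= blink_range_ms[1] & dur <= blink_range_ms[2]
  list(blinks = data.frame(onset_ms = onset[is_blink],
                           duration_ms = dur[is_blink]),
       closures = data.frame(onset_ms = onset[!is_blink],
                             duration_ms = dur[!is_blink]))
}

#' Cubic interpolation of blink gaps
#'
#' Samples inside blink intervals are replaced by a cubic fitted by least
#' squares to anchor windows of valid samples flanking the gap (100 ms per
#' side by default). The least-squares cubic reproduces polynomial signals
#' up to degree 3 exactly (like an interpolating cubic spline through
#' clean anchors) while averaging out sample noise instead of threading
#' through it, which keeps the fill from oscillating inside the gap.
#' Closure intervals are left missing: only loss caused by blinks is
#' treated as recoverable data. If one flank has no valid samples (blink
#' at a trace edge), the gap is filled by linear extrapolation from the
#' other side and a warning is issued.
#'
#' @param trace a [pupil_trace()] at stage `"upsampled"`.
#' @param blinks data.frame from [detect_blinks()] (`$blinks`).
#' @param anchor_ms width of the valid-sample anchor window on each side.
#' @return A [pupil_trace()] at stage `"interpolated"` with blink gaps
#'   filled and their mask cleared.
#' @export
interpolate_blinks <- function(trace, blinks, anchor_ms = 100) {
  assert_stage(trace, "upsampled", "interpolate_blinks")
  x <- trace$pupil
  m <- trace$missing
  n <- length(x)
  fs <- trace$sampling_hz
  anchor_n <- round(anchor_ms * fs / 1000)
  for (i in seq_len(nrow(blinks))) {
    s <- round((blinks$onset_ms[i] - trace$start_time_ms) * fs / 1000) + 1L
    e <- s + round(blinks$duration_ms[i] * fs / 1000) - 1L
    if (s < 1L || e > n) next
    left <- seq(max(1L, s - anchor_n), s - 1L)
    right <- seq(e + 1L, min(n, e + anchor_n))
    left <- left[left >= 1 & !m[pmax(left, 1)]]
    right <- right[right <= n & !m[pmin(right, n)]]
    gap <- s:e
    if (length(left) >= 2 && length(right) >= 2) {
      anchors <- c(left, right)
      # centered/scaled abscissa keeps the cubic basis well conditioned
      mid <- (s + e) / 2
      span <- max(anchors) - min(anchors)
      u <- (anchors - mid) / span
      B <- cbind(1, u, u^2, u^3)
      fit <- stats::lm.fit(B, x[anchors])
      ug <- (gap - mid) / span
      x[gap] <- drop(cbind(1, ug, ug^2, ug^3) %*% fit$coefficients)
    } else if (length(left) + length(right) >= 2) {
      anchors <- c(left, right)
      fit <- stats::lm.fit(cbind(1, anchors), x[anchors])
      x[gap] <- fit$coefficients[1] + fit$coefficients[2] * gap
      warning("blink at trace edge (", blinks$onset_ms[i],
              " ms): linear extrapolation used")
    } else if (length(left) + length(right) == 1) {
      x[gap] <- x[c(left, right)]
      warning("blink at trace edge (", blinks$onset_ms[i],
              " ms): constant fill used")
    } else {
      warning("blink at ", blinks$onset_ms[i],
              " ms has no valid neighbours; left missing")
      next
    }
    m[gap] <- FALSE
  }
  pupil_trace(x, fs, missing = m, start_time_ms = trace$start_time_ms,
              stage = "interpolated")
}

#' Zero-phase FIR band-pass filter (0.02-4 Hz)
#'
#' Applies the preprocessing band-pass as a cascade of two zero-phase
#' (forward-backward) Hamming-windowed FIR stages at 1 kHz:
#' a 4 Hz low-pass (order `3 * fs / 4`, i.e. 751 taps), then a 0.02 Hz
#' high-pass realized by subtracting a slow trend. The trend is the 0.02 Hz
#' low-pass of the signal, computed economically on a 10:1 decimated copy
#' (15001 taps at 100 Hz) and linearly re-expanded; it is evaluated
#' symmetrically in both time directions so that the whole operation
#' commutes exactly with time reversal. Closure gaps are bridged linearly
#' for the duration of filtering and re-masked afterwards; their samples
#' never re-enter the data. The output has (near-)zero mean by
#' construction: DC is removed exactly.
#'
#' @param trace a [pupil_trace()] at stage `"interpolated"` (1 kHz).
#' @param low_hz high-pass cutoff (default 0.02 Hz).
#' @param high_hz low-pass cutoff (default 4 Hz).
#' @return A [pupil_trace()] at stage `"filtered"`.
#' @export
bandpass_filter <- function(trace, low_hz = 0.02, high_hz = 4) {
  assert_stage(trace, "interpolated", "bandpass_filter")
  if (trace$sampling_hz != 1000) {
    stop("bandpass_filter requires a 1 kHz trace")
  }
  fs <- trace$sampling_hz
  n <- length(trace$pupil)
  dec <- 10L
  fs_lo <- fs / dec
  hp_order <- 2L * ceiling(3 * fs_lo / low_hz / 2)    # 15000 at 100 Hz
  lp_order <- 2L * ceiling(3 * fs / high_hz / 2)      # 750 at 1 kHz
  min_n <- (hp_order + 1L) * dec
  if (n < min_n) {
    stop("trace too short to band-pass at ", low_hz, " Hz: need at least ",
         min_n, " samples (", min_n / fs, " s), got ", n)
  }

  x <- trace$pupil
  m <- trace$missing
  # bridge remaining missing spans (closures) linearly for filtering only
  if (any(m)) {
    idx <- which(!m)
    if (length(idx) < 2) stop("trace has fewer than 2 valid samples")
    gap <- which(m)
    x[gap] <- stats::approx(idx, x[idx], xout = gap, rule = 2)$y
  }

  h_lp <- fir_lowpass(high_hz, fs, lp_order)
  y <- filtfilt_fir(x, h_lp)

  h_trend <- fir_lowpass(low_hz, fs_lo, hp_order)
  trend_once <- function(sig) {
    d <- sig[seq(1L, length(sig), by = dec)]
    td <- filtfilt_fir(d, h_trend)
    stats::approx(seq(1L, length(sig), by = dec), td,
                  xout = seq_along(sig), rule = 2)$y
  }
  trend <- (trend_once(y) + rev(trend_once(rev(y)))) / 2
  z <- y - trend
  z[m] <- 0
  pupil_trace(z, fs, missing = m, start_time_ms = trace$start_time_ms,
              stage = "filtered")
}

#' Decimate a filtered 1 kHz trace to 100 Hz
#'
#' Retains every 10th sample (the preceding 4 Hz low-pass acts as the
#' anti-alias filter). The missingness mask is decimated with a logical OR
#' over each 10-sample block: if any source sample in a block was missing,
#' the decimated sample is missing.
#'
#' @param trace a [pupil_trace()] at stage `"filtered"` (1 kHz).
#' @return A [pupil_trace()] at 100 Hz, stage `"downsampled"`.
#' @export
downsample_100hz <- function(trace) {
  assert_stage(trace, "filtered", "downsample_100hz")
  if (trace$sampling_hz != 1000) {
    stop("downsample_100hz requires a 1 kHz input")
  }
  n <- length(trace$pupil)
  keep <- seq(1L, n, by = 10L)
  block <- (seq_len(n) - 1L) %/% 10L
  pm <- as.logical(tapply(trace$missing, block, any))
  pupil_trace(trace$pupil[keep], 100, missing = pm,
              start_time_ms = trace$start_time_ms, stage = "downsampled")
}

#' Run the full preprocessing chain on a raw trace
#'
#' parse -> resample to 1 kHz -> detect blinks -> spline-interpolate blink
#' gaps -> zero-phase 0.02-4 Hz band-pass -> decimate to 100 Hz. Also
#' computes the pre-interpolation pupil-loss fraction (the vigilance
#' criterion) and the mean pupil size on the interpolated, unfiltered
#' trace (the high-pass removes the mean, so pupil size must be taken
#' before filtering).
#'
#' @param raw a [pupil_trace()] at stage `"raw"`.
#' @param blink_range_ms blink duration rule passed to [detect_blinks()].
#' @return list: `trace100` (downsampled filtered trace), `blinks`,
#'   `closures`, `loss_fraction`, `pupil_size` (mean au),
#'   `trace_interp` (1 kHz interpolated trace).
#' @export
preprocess_run <- function(raw, blink_range_ms = c(40, 400)) {
  up <- resample_to_1khz(raw)
  ev <- detect_blinks(up, blink_range_ms)
  loss <- pupil_loss_fraction(up)
  interp <- interpolate_blinks(up, ev$blinks)
  pupil_size <- mean(interp$pupil[!interp$missing])
  filt <- bandpass_filter(interp)
  ds <- downsample_100hz(filt)
  list(trace100 = ds, blinks = ev$blinks, closures = ev$closures,
       loss_fraction = loss, pupil_size = pupil_size,
       trace_interp = interp)
}
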