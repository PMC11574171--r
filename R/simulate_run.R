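#' Parameters for a simulated pupil recording
#'
#' Bundles and validates every tunable of the single-run generator. The
#' generator emulates resting-state pupil recordings: a slow sinusoidal
#' drift around a baseline with additive white noise, blinks (40-400 ms of
#' total pupil loss, each followed by the blink-locked dilation/constriction
#' kernel), and long eye closures (> 400 ms pupil loss) whose cumulative
#' duration is steered to a target fraction of the run, as in drowsy
#' recordings.
#'
#' @param duration_s run duration in seconds. Runs shorter than ~151 s
#'   cannot be band-pass filtered (the 0.02 Hz high-pass needs that much
#'   signal); the default emulates a typical resting-state run at desk
#'   scale.
#' @param sampling_hz 500 or 1000 Hz.
#' @param baseline_pupil mean pupil size (au).
#' @param drift_amplitude amplitude of the slow sinusoidal drift (au).
#' @param drift_period_s period of the drift (s).
#' @param blink_rate_per_min expected blink rate (events/min of run time).
#' @param blink_duration_range_ms (min, max) blink duration, within
#'   \[40, 400\] ms. The default avoids the rule boundaries so that
#'   upsampling a 500 Hz recording cannot push a blink across the 40/400 ms
#'   classification edge.
#' @param closure_target_fraction fraction of samples in \[0, 1) to be lost
#'   to long closures.
#' @param closure_duration_range_s (min, max) closure duration in seconds,
#'   both > 0.4 s.
#' @param kernel a [bipr_kernel()] added after every blink.
#' @param noise_sd white-noise standard deviation (au).
#' @param clean_tail_fraction fraction of blinks whose following 3 s are
#'   protected from closures, guaranteeing some valid blink epochs by
#'   construction.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (params, seed).
#' @return A validated `sim_run_params` list.
#' @export
sim_run_params <- function(duration_s = 300,
                           sampling_hz = 1000,
                           baseline_pupil = 1500,
                           drift_amplitude = 50,
                           drift_period_s = 60,
                           blink_rate_per_min = 15,
                           blink_duration_range_ms = c(60, 350),
                           closure_target_fraction = 0,
                           closure_duration_range_s = c(0.6, 4),
                           kernel = bipr_kernel(),
                           noise_sd = 10,
                           clean_tail_fraction = 0.5,
                           seed = 1L) {
  if (!sampling_hz %in% c(500, 1000)) {
    stop("sampling_hz must be 500 or 1000")
  }
  if (duration_s <= 0) stop("duration_s must be positive")
  bd <- blink_duration_range_ms
  if (length(bd) != 2 || bd[1] > bd[2] || bd[1] < 40 || bd[2] > 400) {
    stop("blink_duration_range_ms must lie within [40, 400] ms")
  }
  cd <- closure_duration_range_s
  if (length(cd) != 2 || cd[1] > cd[2] || cd[1] <= 0.4) {
    stop("closure durations must be strictly > 0.4 s")
  }
  if (closure_target_fraction < 0 || closure_target_fraction >= 1) {
    stop("closure_target_fraction must be in [0, 1)")
  }
  if (blink_rate_per_min < 0) stop("blink_rate_per_min must be >= 0")
  if (clean_tail_fraction < 0 || clean_tail_fraction > 1) {
    stop("clean_tail_fraction must be in [0, 1]")
  }
  stopifnot(inherits(kernel, "bipr_kernel"))
  structure(list(duration_s = duration_s, sampling_hz = sampling_hz,
                 baseline_pupil = baseline_pupil,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_duration_range_ms = bd,
                 closure_target_fraction = closure_target_fraction,
                 closure_duration_range_s = cd,
                 kernel = kernel,
                 noise_sd = noise_sd,
                 clean_tail_fraction = clean_tail_fraction,
                 seed = as.integer(seed)),
            class = "sim_run_params")
}

# Complement of occupied intervals (two-column [start, end] matrix of
# sample indices) within 1..n, as a two-column matrix of free segments.
free_segments <- function(occupied, n) {
  if (nrow(occupied) == 0) return(cbind(1L, n))
  occ <- occupied[order(occupied[, 1]), , drop = FALSE]
  segs <- NULL
  cur <- 1L
  for (i in seq_len(nrow(occ))) {
    s <- max(1L, occ[i, 1]); e <- min(n, occ[i, 2])
    if (s > cur) segs <- rbind(segs, c(cur, s - 1L))
    cur <- max(cur, e + 1L)
  }
  if (cur <= n) segs <- rbind(segs, c(cur, n))
  if (is.null(segs)) cbind(integer(0), integer(0)) else segs
}

#' Simulate one pupil recording with ground truth
#'
#' Generates a raw pupil trace (lost samples encoded as 0.0) together with
#' the exact list of simulated blinks, closures and the injected response
#' kernel. Blinks are placed by a Poisson process thinned to forbid overlap;
#' a configurable fraction of blinks keeps a closure-free 3 s tail so that
#' valid blink epochs exist by construction. Closure durations are drawn
#' from the configured range and accumulated until the target loss fraction
#' is met (the last closure is trimmed, never below the 0.4 s rule
#' boundary).
#'
#' @param params a [sim_run_params()].
#' @return list with elements
#'   \describe{
#'     \item{trace}{[pupil_trace()] at stage `"raw"`.}
#'     \item{blinks}{data.frame `onset_ms`, `duration_ms` (ground truth).}
#'     \item{closures}{data.frame `onset_ms`, `duration_ms`.}
#'     \item{kernel}{the injected [bipr_kernel()].}
#'   }
#' @export
simulate_pupil_run <- function(params) {
  stopifnot(inherits(params, "sim_run_params"))
  p <- params
  fs <- p$sampling_hz
  n <- round(p$duration_s * fs)
  ms_per_sample <- 1000 / fs

  # feasibility: expected event time must leave room
  exp_blink_frac <- p$blink_rate_per_min / 60 * mean(p$blink_duration_range_ms) / 1000
  if (exp_blink_frac + p$closure_target_fraction > 0.9) {
    stop("requested event density infeasible: expected blink loss (",
         round(exp_blink_frac, 2), ") + closure target (",
         p$closure_target_fraction, ") exceeds 0.9 of the run")
  }

  old <- withr_seed(p$seed)
  on.exit(restore_seed(old), add = TRUE)

  # --- blinks: renewal process with dead time ---------------------------
  # Exponential gaps with a refractory period (blink duration + margin)
  # forbid overlap; the exponential rate is corrected so the expected
  # count still equals blink_rate_per_min * duration.
  margin <- round(0.15 * fs)  # >= 150 ms between events
  bl <- list(onset = integer(0), len = integer(0))
  if (p$blink_rate_per_min > 0) {
    mean_interval_s <- 60 / p$blink_rate_per_min
    dead_s <- mean(p$blink_duration_range_ms) / 1000 + margin / fs
    if (mean_interval_s <= dead_s) {
      stop("requested event density infeasible: mean blink interval (",
           round(mean_interval_s, 2), " s) does not exceed the blink ",
           "refractory period (", round(dead_s, 2), " s)")
    }
    lambda_adj <- 1 / (mean_interval_s - dead_s)
    t_cur <- 0
    repeat {
      gap <- stats::rexp(1, lambda_adj)
      len <- round(stats::runif(1, p$blink_duration_range_ms[1],
                                p$blink_duration_range_ms[2]) / ms_per_sample)
      on <- round((t_cur + gap) * fs) + 1L
      if (on + len - 1L > n) break
      bl$onset <- c(bl$onset, on)
      bl$len <- c(bl$len, len)
      t_cur <- (on + len - 1L + margin) / fs
    }
  }

  # protected 3 s tails after a fraction of blinks (closures keep out)
  n_bl <- length(bl$onset)
  protected <- matrix(numeric(0), 0, 2)
  if (n_bl > 0 && p$clean_tail_fraction > 0) {
    n_prot <- ceiling(p$clean_tail_fraction * n_bl)
    prot_idx <- seq_len(n_bl) %in%
      sample.int(n_bl, n_prot)
    ends <- bl$onset[prot_idx] + bl$len[prot_idx] - 1
    protected <- cbind(ends + 1, pmin(ends + 3 * fs, n))
  }

  occupied <- rbind(cbind(bl$onset, bl$onset + bl$len - 1), protected)

  # --- closures: free-segment splitting up to the target fraction ------
  # The complement of blinks/protected tails is kept as a list of free
  # segments; each closure is dropped uniformly into a segment with
  # enough capacity, which then splits. This packs reliably even at high
  # target fractions (very drowsy runs).
  cl_on <- integer(0); cl_len <- integer(0)
  target_samples <- round(p$closure_target_fraction * n)
  if (target_samples > 0) {
    segs <- free_segments(occupied, n)
    got <- 0L
    min_len <- round(p$closure_duration_range_s[1] * fs)
    while (got < target_samples) {
      len <- round(stats::runif(1, p$closure_duration_range_s[1],
                                p$closure_duration_range_s[2]) * fs)
      # trim the final closure toward the target, never below the range min
      if (got + len > target_samples) len <- max(min_len, target_samples - got)
      cap <- segs[, 2] - segs[, 1] + 1L - len - 2L * margin
      ok <- which(cap > 0)
      if (length(ok) == 0) {
        # no segment fits this length; try the smallest allowed
        len <- min_len
        cap <- segs[, 2] - segs[, 1] + 1L - len - 2L * margin
        ok <- which(cap > 0)
        if (length(ok) == 0) break
      }
      pick <- if (length(ok) == 1) ok else
        sample(ok, 1, prob = cap[ok])
      # dense targets would jam under fully random ("parking") placement
      # (~75% packing limit), so closures then sit near segment starts
      # with a small jitter; sparse targets keep uniform placement
      jitter_max <- if (p$closure_target_fraction > 0.5) {
        min(cap[pick], max(1L, round(0.25 * fs)))
      } else cap[pick]
      on <- segs[pick, 1] + margin + sample.int(jitter_max, 1L) - 1L
      cl_on <- c(cl_on, on); cl_len <- c(cl_len, len)
      got <- got + len
      old_seg <- segs[pick, ]
      segs <- segs[-pick, , drop = FALSE]
      left <- c(old_seg[1], on - 1L)
      right <- c(on + len, old_seg[2])
      if (left[2] - left[1] >= 0) segs <- rbind(segs, left)
      if (right[2] - right[1] >= 0) segs <- rbind(segs, right)
    }
    if (got < (p$closure_target_fraction - 0.05) * n) {
      stop("requested event density infeasible: could not reach the ",
           "closure target fraction (placed ", round(got / n, 3),
           " of target ", p$closure_target_fraction, ")")
    }
    ord <- order(cl_on); cl_on <- cl_on[ord]; cl_len <- cl_len[ord]
  }

  # --- signal -----------------------------------------------------------
  t_s <- (seq_len(n) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  x <- p$baseline_pupil +
    p$drift_amplitude * sin(2 * pi * t_s / p$drift_period_s + phase) +
    stats::rnorm(n, 0, p$noise_sd)

  # blink-locked kernel added after each blink, relative to blink onset
  horizon <- round(3.5 * fs)
  for (i in seq_along(bl$onset)) {
    on <- bl$onset[i]
    idx <- on:min(n, on + horizon)
    x[idx] <- x[idx] + eval_kernel(p$kernel, (idx - on) * ms_per_sample)
  }

  miss <- rep(FALSE, n)
  for (i in seq_along(bl$onset)) {
    miss[bl$onset[i]:(bl$onset[i] + bl$len[i] - 1)] <- TRUE
  }
  for (i in seq_along(cl_on)) {
    miss[cl_on[i]:(cl_on[i] + cl_len[i] - 1)] <- TRUE
  }
  x[miss] <- 0

  to_ms <- function(idx) (idx - 1) * ms_per_sample
  list(trace = pupil_trace(x, fs, missing = miss, start_time_ms = 0,
                           stage = "raw"),
       blinks = data.frame(onset_ms = to_ms(bl$onset),
                           duration_ms = bl$len * ms_per_sample),
       closures = data.frame(onset_ms = to_ms(cl_on),
                             duration_ms = cl_len * ms_per_sample),
       kernel = p$kernel)
}

#' Write a trace in the EyeLink-ASC sample dialect
#'
#' Emits one tab-separated sample line per sample: `time_ms  gaze_x  gaze_y
#' pupil`, with pupil printed as `0.0` where the pupil was not detected.
#' A JSON ground-truth sidecar can be written alongside.
#'
#' @param trace a raw [pupil_trace()].
#' @param path output file path.
#' @param ground_truth optional list (e.g. the `blinks`/`closures` element
#'   of [simulate_pupil_run()]) written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_asc <- function(trace, path, ground_truth = NULL) {
  stopifnot(inherits(trace, "pupil_trace"))
  tm <- trace_times(trace)
  pupil <- ifelse(trace$missing, "0.0", formatC(trace$pupil, format = "f",
                                                digits = 1))
  lines <- sprintf("%d\t640.0\t512.0\t%s", as.integer(round(tm)), pupil)
  writeLines(c("MSG\t0 RECORD_START", lines, "MSG\t0 RECORD_STOP"), path)
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# seed handling: save/restore the global RNG state so generators are pure
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
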