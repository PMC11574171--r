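#' Pupil time-series container
#'
#' A `pupil_trace` holds a uniformly sampled pupil-size signal together with
#' a missingness mask and a processing-stage tag. The preprocessing pipeline
#' (`resample_to_1khz()`, `detect_blinks()`, `interpolate_blinks()`,
#' `bandpass_filter()`, `downsample_100hz()`) consumes and produces traces,
#' and each stage refuses input carrying the wrong stage tag so that the
#' fixed pipeline order cannot be violated silently.
#'
#' @param pupil numeric vector of pupil sizes in arbitrary tracker units
#'   (au). In the `"raw"` stage lost samples are encoded as `0.0`.
#' @param sampling_hz sampling rate; one of 500, 1000 (raw/processed at full
#'   rate) or 100 (after decimation).
#' @param missing logical vector, `TRUE` where the pupil was not detected.
#'   Defaults to `pupil == 0` for raw traces.
#' @param start_time_ms timestamp of the first sample (ms).
#' @param stage processing stage tag, one of `"raw"`, `"upsampled"`,
#'   `"interpolated"`, `"filtered"`, `"downsampled"`.
#' @return An object of class `pupil_trace`: a list with elements `pupil`,
#'   `missing`, `sampling_hz`, `start_time_ms`, `stage`.
#' @export
pupil_trace <- function(pupil, sampling_hz,
                        missing = NULL,
                        start_time_ms = 0,
                        stage = "raw") {
  stage <- match.arg(stage,
                     c("raw", "upsampled", "interpolated", "filtered",
                       "downsampled"))
  if (!is.numeric(pupil)) stop("`pupil` must be numeric")
  if (!sampling_hz %in% c(500, 1000, 100)) {
    stop("unsupported sampling rate: ", sampling_hz,
         " (must be 500, 1000 or 100 Hz)")
  }
  if (is.null(missing)) missing <- !is.finite(pupil) | pupil == 0
  if (length(missing) != length(pupil)) {
    stop("`pupil` and `missing` must have equal length")
  }
  pupil[missing & stage == "raw"] <- 0
  structure(
    list(pupil = as.numeric(pupil),
         missing = as.logical(missing),
         sampling_hz = sampling_hz,
         start_time_ms = start_time_ms,
         stage = stage),
    class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  n <- length(x$pupil)
  cat(sprintf("<pupil_trace> %d samples @ %g Hz (%.1f s), stage '%s'\n",
              n, x$sampling_hz, n / x$sampling_hz, x$stage))
  cat(sprintf("  missing: %d samples (%.1f%%)\n",
              sum(x$missing), 100 * mean(x$missing)))
  invisible(x)
}

#' @export
length.pupil_trace <- function(x) length(x$pupil)

#' Sample times of a trace
#'
#' @param trace a [pupil_trace()].
#' @return numeric vector of per-sample timestamps in ms.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "pupil_trace"))
  trace$start_time_ms + (seq_along(trace$pupil) - 1) * 1000 / trace$sampling_hz
}

#' Export a trace as a columnar table
#'
#' @param trace a [pupil_trace()].
#' @return `data.frame` with columns `time_ms`, `pupil`, `missing`.
#' @export
trace_table <- function(trace) {
  data.frame(time_ms = trace_times(trace),
             pupil = trace$pupil,
             missing = trace$missing)
}

assert_stage <- function(trace, expected, fn) {
  if (!inherits(trace, "pupil_trace")) {
    stop(fn, "() expects a pupil_trace, got ", class(trace)[1])
  }
  if (!trace$stage %in% expected) {
    stop(fn, "() requires a trace at stage ",
         paste(sQuote(expected), collapse = " or "),
         ", got ", sQuote(trace$stage),
         " (pipeline order is parse -> resample -> detect -> interpolate ",
         "-> filter -> downsample)")
  }
  invisible(TRUE)
}
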