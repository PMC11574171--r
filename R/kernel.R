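#' Blink-locked pupil response kernel
#'
#' Parameterizes the stereotyped pupil waveform that follows a blink: a
#' positive dilation bump (the D peak, typically near 500 ms after blink
#' onset) followed by a negative constriction bump (the C peak, near 1 s).
#' The waveform is modelled as the sum of two Gaussian bumps so that the
#' true peak times and amplitudes are analytically known, which makes
#' parameter-recovery tests exact.
#'
#' @param d_time_ms latency of the dilation peak (ms after blink onset).
#' @param d_amp amplitude of the dilation peak (au, > 0).
#' @param d_width_ms Gaussian scale (sd) of the dilation bump (ms).
#' @param c_time_ms latency of the constriction trough (ms); must exceed
#'   `d_time_ms`.
#' @param c_amp magnitude of the constriction trough (au, > 0; applied with
#'   a negative sign).
#' @param c_width_ms Gaussian scale of the constriction bump (ms).
#' @return An object of class `bipr_kernel`.
#' @examples
#' k <- bipr_kernel()
#' plot((-500:2000), eval_kernel(k, -500:2000), type = "l")
#' @export
bipr_kernel <- function(d_time_ms = 500, d_amp = 30, d_width_ms = 100,
                        c_time_ms = 1000, c_amp = 20, c_width_ms = 180) {
  if (!(c_time_ms > d_time_ms)) stop("c_time_ms must exceed d_time_ms")
  if (d_amp <= 0 || c_amp <= 0) stop("kernel amplitudes must be positive")
  if (d_width_ms <= 0 || c_width_ms <= 0) stop("kernel widths must be positive")
  structure(list(d_time_ms = d_time_ms, d_amp = d_amp, d_width_ms = d_width_ms,
                 c_time_ms = c_time_ms, c_amp = c_amp, c_width_ms = c_width_ms),
            class = "bipr_kernel")
}

#' Evaluate a blink-response kernel
#'
#' @param kernel a [bipr_kernel()].
#' @param t_ms numeric vector of times relative to blink onset (ms).
#' @return numeric vector of kernel values (au).
#' @export
eval_kernel <- function(kernel, t_ms) {
  stopifnot(inherits(kernel, "bipr_kernel"))
  kernel$d_amp * exp(-0.5 * ((t_ms - kernel$d_time_ms) / kernel$d_width_ms)^2) -
    kernel$c_amp * exp(-0.5 * ((t_ms - kernel$c_time_ms) / kernel$c_width_ms)^2)
}
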