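#' Fraction of the run with no detected pupil
#'
#' Computed on the pre-interpolation trace (raw or upsampled): blink gaps
#' count as loss, because the criterion is time with "pupil not detected",
#' not time with unusable data.
#'
#' @param trace a [pupil_trace()] at stage `"raw"` or `"upsampled"`.
#' @return fraction in \[0, 1\].
#' @export
pupil_loss_fraction <- function(trace) {
  assert_stage(trace, c("raw", "upsampled"), "pupil_loss_fraction")
  if (length(trace$pupil) == 0) stop("empty trace")
  mean(trace$missing)
}

#' Classify a run's vigilance state from its pupil-loss fraction
#'
#' Four states partition \[0, 1\]: less than 10% loss is Vigilant, 10-40%
#' is Drowsy, 40-75% is VeryDrowsy, and more than 75% is Discarded. The
#' interval endpoints are assigned left-closed at 0.10 and 0.40 and
#' right-closed at 0.75 (so 0.10 -> Drowsy, 0.40 -> VeryDrowsy, 0.75 ->
#' VeryDrowsy); the cut points are configurable.
#'
#' @param loss_fraction numeric vector in \[0, 1\].
#' @param thresholds the three cut points, default `c(0.10, 0.40, 0.75)`.
#' @return factor with levels `Vigilant`, `Drowsy`, `VeryDrowsy`,
#'   `Discarded`.
#' @export
classify_run <- function(loss_fraction, thresholds = c(0.10, 0.40, 0.75)) {
  if (any(!is.finite(loss_fraction)) ||
      any(loss_fraction < 0 | loss_fraction > 1)) {
    stop("loss_fraction must lie in [0, 1]")
  }
  labels <- c("Vigilant", "Drowsy", "VeryDrowsy", "Discarded")
  idx <- 1L + (loss_fraction >= thresholds[1]) +
    (loss_fraction >= thresholds[2]) +
    (loss_fraction > thresholds[3])
  factor(labels[idx], levels = labels)
}

#' Merge the two drowsy states into "All Drowsy"
#'
#' Drowsy and VeryDrowsy collapse to `AllDrowsy`; Vigilant and Discarded
#' are unchanged.
#'
#' @param states factor or character vector of vigilance labels.
#' @return factor with levels `Vigilant`, `AllDrowsy`, `Discarded`.
#' @export
merge_drowsy <- function(states) {
  s <- as.character(states)
  s[s %in% c("Drowsy", "VeryDrowsy")] <- "AllDrowsy"
  if (!all(s %in% c("Vigilant", "AllDrowsy", "Discarded"))) {
    stop("unknown vigilance label: ",
         paste(setdiff(s, c("Vigilant", "AllDrowsy", "Discarded")),
               collapse = ", "))
  }
  factor(s, levels = c("Vigilant", "AllDrowsy", "Discarded"))
}
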