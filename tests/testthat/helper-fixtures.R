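# Shared fixture builders. All data are generated in code; a "quick" run
# uses the shortest duration the 0.02 Hz high-pass admits (~151 s).

QUICK_S <- 160

quick_params <- function(seed, ...) {
  sim_run_params(duration_s = QUICK_S, seed = seed, ...)
}

# a clean 1 kHz trace at a given stage, no missing samples
flat_trace <- function(x, stage = "interpolated", fs = 1000) {
  pupil_trace(x, fs, missing = rep(FALSE, length(x)), stage = stage)
}

# raw trace from a pupil vector where zeros mark loss
raw_trace <- function(x, fs = 1000) pupil_trace(x, fs, stage = "raw")

# independent type-7 quantile (linear interpolation between order stats)
quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# analytic peak locations of a two-Gaussian kernel, by fine grid search
kernel_true_peaks <- function(kernel) {
  tt <- seq(0, 2500, by = 0.5)
  v <- eval_kernel(kernel, tt)
  c(d_time = tt[which.max(v)], d_amp = max(v),
    c_time = tt[which.min(v)], c_amp = min(v))
}
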