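# Windowed-sinc FIR design and zero-phase filtering.
#
# The `signal` package is not a dependency: the filters here are the core
# of the preprocessing contract (documented tap counts, exact DC null,
# exact time-reversal symmetry), so they are built from first principles
# with FFT-based convolution.

# Hamming-windowed sinc low-pass; `order` is forced even so the filter has
# odd length and an integer group delay. Coefficients are normalized to
# unit DC gain (sum == 1 exactly).
fir_lowpass <- function(cutoff_hz, fs, order) {
  order <- 2L * ceiling(order / 2)
  m <- order / 2
  k <- seq(-m, m)
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Linear convolution via FFT, returning the "same"-length centered result
# for an odd-length symmetric kernel.
conv_same <- function(x, h) {
  n <- length(x); l <- length(h)
  m <- (l - 1L) / 2L
  nfft <- stats::nextn(n + l - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  H <- stats::fft(c(h, rep(0, nfft - l)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[(m + 1L):(m + n)]
}

# cache of kernel FFTs keyed by kernel hash and FFT length
.fir_cache <- new.env(parent = emptyenv())

kernel_fft <- function(h, nfft) {
  key <- paste0("h", length(h), "_", format(sum(h * seq_along(h)), digits = 17),
                "_", nfft)
  got <- .fir_cache[[key]]
  if (!is.null(got)) return(got)
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  .fir_cache[[key]] <- H
  H
}

# Zero-phase filtering: odd-reflection padding of length = filter order on
# each side, then two passes of the symmetric kernel (the forward and
# backward passes of a linear-phase FIR are identical centered
# convolutions). Both passes are fused into one FFT round (multiply by
# H^2); the kernel FFT is cached across calls. Exactly symmetric under
# time reversal.
filtfilt_fir <- function(x, h) {
  n <- length(x)
  l <- length(h)
  pad <- l - 1L
  if (n < pad + 1L) {
    stop("signal too short for zero-phase filtering: need at least ",
         pad + 1L, " samples, got ", n)
  }
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  np <- length(xp)
  nfft <- stats::nextn(np + 2L * pad, c(2, 3, 5))
  H <- kernel_fft(h, nfft)
  X <- stats::fft(c(xp, rep(0, nfft - np)))
  y <- Re(stats::fft(X * H * H, inverse = TRUE)) / nfft
  # total delay of two causal passes is 2 * (l-1)/2 = pad samples
  y[(2L * pad + 1L):(2L * pad + n)]
}
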