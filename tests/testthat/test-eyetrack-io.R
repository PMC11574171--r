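# preprocessing chain: parsing, resampling, blink detection,
# interpolation, band-pass filtering, decimation

test_that("parser keeps sample lines and ignores event lines", {
  lines <- c("MSG\t100 RECORD",
             "1000\t640.0\t512.0\t1500.0",
             "1001\t640.0\t512.0\t0.0",
             "EBLINK R 1001 1003",
             "1002\t640.0\t512.0\t0.0",
             "1003\t640.0\t512.0\t0.0",
             "1004\t640.0\t512.0\t1498.0",
             "1005\t640.0\t512.0\t1497.0",
             "SSACC R 1005",
             "1006\t640.0\t512.0\t1501.0",
             "1007\t640.0\t512.0\t1502.0",
             "1008\t640.0\t512.0\t1500.5",
             "1009\t640.0\t512.0\t1499.5")
  tr <- parse_asc_samples(lines)
  expect_equal(length(tr$pupil), 10)
  expect_equal(sum(tr$missing), 3)
  expect_equal(tr$sampling_hz, 1000)
  expect_equal(tr$start_time_ms, 1000)
})

test_that("parser errors: empty input and non-monotonic timestamps", {
  expect_error(parse_asc_samples(c("MSG only", "EBLINK R 1 2")), "empty input")
  expect_error(parse_asc_samples(character(0)), "empty input")
  bad <- c("1000\t0\t0\t10.0", "1001\t0\t0\t10.0", "1001\t0\t0\t10.0")
  expect_error(parse_asc_samples(bad), "non-monotonic.*line 3")
})

test_that("unparseable pupil fields become missing", {
  lines <- c("1000\t0\t0\t10.0", "1001\t0\t0\t.", "1002\t0\t0\t12.0")
  tr <- parse_asc_samples(lines)
  expect_identical(tr$missing, c(FALSE, TRUE, FALSE))
})

test_that("resampling: identity at 1 kHz, midpoints at 500 Hz", {
  tr1k <- raw_trace(c(1, 2, 3, 4))
  up <- resample_to_1khz(tr1k)
  expect_identical(up$pupil, tr1k$pupil)
  expect_equal(up$stage, "upsampled")

  ramp <- pupil_trace(c(10, 20, 30, 40), 500,
                      missing = rep(FALSE, 4), stage = "raw")
  up2 <- resample_to_1khz(ramp)
  expect_equal(length(up2$pupil), 2 * 4 - 1)
  expect_equal(up2$pupil, c(10, 15, 20, 25, 30, 35, 40))
  expect_equal(up2$sampling_hz, 1000)

  # conservative mask: inserted sample missing if either flank is
  holes <- pupil_trace(c(10, 0, 30, 40), 500,
                       missing = c(FALSE, TRUE, FALSE, FALSE), stage = "raw")
  up3 <- resample_to_1khz(holes)
  expect_identical(up3$missing, c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("blink/closure classification is exhaustive and exclusive", {
  x <- rep(100, 3000)
  x[1001:1100] <- 0                     # 100 ms -> blink
  x[1501:1530] <- 0                     # 30 ms -> closure (too short)
  x[2001:2800] <- 0                     # 800 ms -> closure (too long)
  ev <- detect_blinks(resample_to_1khz(raw_trace(x)))
  expect_equal(nrow(ev$blinks), 1)
  expect_equal(nrow(ev$closures), 2)
  expect_equal(ev$blinks$onset_ms, 1000)
  expect_equal(ev$blinks$duration_ms, 100)
  expect_equal(ev$closures$duration_ms, c(30, 800))
  # the rule boundaries are inclusive for blinks
  y <- rep(100, 2000); y[101:140] <- 0; y[1001:1400] <- 0
  ev2 <- detect_blinks(resample_to_1khz(raw_trace(y)))
  expect_equal(ev2$blinks$duration_ms, c(40, 400))
  # clean trace -> empty lists
  ev3 <- detect_blinks(resample_to_1khz(raw_trace(rep(100, 500))))
  expect_equal(nrow(ev3$blinks) + nrow(ev3$closures), 0)
})

test_that("every maximal lost interval becomes exactly one event", {
  set.seed(41)
  for (rep_i in 1:5) {
    sim <- simulate_pupil_run(quick_params(seed = 100 + rep_i,
                                           closure_target_fraction = 0.15))
    up <- resample_to_1khz(sim$trace)
    ev <- detect_blinks(up)
    runs <- rle(up$missing)
    n_lost <- sum(runs$values)
    expect_equal(nrow(ev$blinks) + nrow(ev$closures), n_lost)
    # detected blink onsets match ground truth exactly at 1 kHz
    expect_equal(ev$blinks$onset_ms, sim$blinks$onset_ms)
    expect_equal(ev$blinks$duration_ms, sim$blinks$duration_ms)
  }
})

test_that("blink interpolation: constants and cubics are reproduced", {
  # constant signal: gap filled with the constant
  x <- rep(500, 2000); x[901:1100] <- 0
  up <- resample_to_1khz(raw_trace(x))
  ev <- detect_blinks(up)
  out <- interpolate_blinks(up, ev$blinks)
  expect_true(all(abs(out$pupil[901:1100] - 500) < 1e-9))
  expect_false(any(out$missing[901:1100]))

  # cubic polynomial: reconstruction error < 1e-6 au
  tt <- seq_len(2000)
  cub <- 2 + 0.01 * tt - 3e-6 * tt^2 + 1e-9 * tt^3 + 10
  xc <- cub; xc[901:1100] <- 0
  upc <- pupil_trace(xc, 1000, missing = seq_len(2000) %in% 901:1100,
                     stage = "upsampled")
  evc <- detect_blinks(upc)
  outc <- interpolate_blinks(upc, evc$blinks)
  expect_lt(max(abs(outc$pupil[901:1100] - cub[901:1100])), 1e-6)

  # closures stay missing
  xl <- rep(500, 3000); xl[1001:1900] <- 0
  upl <- resample_to_1khz(raw_trace(xl))
  evl <- detect_blinks(upl)
  outl <- interpolate_blinks(upl, evl$blinks)
  expect_true(all(outl$missing[1001:1900]))
})

test_that("blink at a trace edge falls back with a warning", {
  x <- rep(500, 1500); x[1:100] <- 0
  up <- resample_to_1khz(raw_trace(x))
  ev <- detect_blinks(up)
  expect_warning(out <- interpolate_blinks(up, ev$blinks), "edge")
  expect_false(any(out$missing[1:100]))
})

test_that("band-pass: DC null, stopband, passband, reversal symmetry", {
  n <- QUICK_S * 1000
  tt <- seq_len(n) / 1000

  dc <- bandpass_filter(flat_trace(rep(1234, n)))
  expect_lt(max(abs(dc$pupil)), 1e-3 * 1234)

  s10 <- bandpass_filter(flat_trace(sin(2 * pi * 10 * tt)))
  mid <- 20000:(n - 20000)
  atten_db <- 20 * log10(max(abs(s10$pupil[mid])))
  expect_lt(atten_db, -20)

  s1 <- bandpass_filter(flat_trace(sin(2 * pi * 1 * tt)))
  expect_lt(abs(max(abs(s1$pupil[mid])) - 1), 0.05)

  # zero-phase: filtering the reversed signal reverses the filtered one
  set.seed(5)
  x <- cumsum(rnorm(n)) / 50 + sin(2 * pi * 0.5 * tt)
  f1 <- bandpass_filter(flat_trace(x))$pupil
  f2 <- rev(bandpass_filter(flat_trace(rev(x)))$pupil)
  expect_lt(max(abs(f1 - f2)), 1e-8)
})

test_that("band-pass rejects too-short input with the minimum length", {
  expect_error(bandpass_filter(flat_trace(rep(1, 1000))),
               "at least 150010 samples")
})

test_that("decimation to 100 Hz: lengths, mask OR, tone preservation", {
  n <- QUICK_S * 1000
  tt <- seq_len(n) / 1000
  filt <- bandpass_filter(flat_trace(sin(2 * pi * 1 * tt)))
  ds <- downsample_100hz(filt)
  expect_equal(length(ds$pupil), n / 10)
  expect_equal(ds$sampling_hz, 100)
  mid <- 2000:(length(ds$pupil) - 2000)
  expect_lt(abs(max(abs(ds$pupil[mid])) - max(abs(filt$pupil[10 * mid]))), 0.01)

  # any missing sample in a 10-block poisons the decimated sample
  m <- rep(FALSE, n); m[25] <- TRUE
  tr <- pupil_trace(filt$pupil, 1000, missing = m, stage = "filtered")
  ds2 <- downsample_100hz(tr)
  expect_true(ds2$missing[3])
  expect_equal(sum(ds2$missing), 1)
})

test_that("pipeline stages reject out-of-order input", {
  raw <- raw_trace(rep(1, 100))
  expect_error(detect_blinks(raw), "requires a trace at stage")
  expect_error(bandpass_filter(raw), "requires a trace at stage")
  expect_error(downsample_100hz(raw), "requires a trace at stage")
  expect_error(extract_epochs(raw, data.frame(onset_ms = 1)),
               "requires a trace at stage")
  up <- resample_to_1khz(raw)
  expect_error(resample_to_1khz(up), "requires a trace at stage")
})
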