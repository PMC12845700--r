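test_that("low-pass filter has unit DC gain, preserves zero, matches the designed response", {
  expect_equal(lowpass_filter(rep(3.7, 400)), rep(3.7, 400), tolerance = 1e-8)
  expect_equal(lowpass_filter(rep(0, 200)), rep(0, 200))
  expect_error(lowpass_filter(rnorm(100), cutoff = 60, fs = 100), "cutoff")

  # transfer-function oracle: steady-state amplitude of a 10 Hz tone after
  # forward-backward first-order 1 Hz filtering is |H(e^{j w})|^2
  fs <- 100; f0 <- 10
  bf <- signal::butter(1, 1 / (fs / 2), "low")
  z <- exp(-1i * 2 * pi * f0 / fs)
  H <- sum(bf$b * z^(0:(length(bf$b) - 1))) /
       sum(bf$a * z^(0:(length(bf$a) - 1)))
  expected_amp <- Mod(H)^2
  t <- 0:3999
  y <- lowpass_filter(sin(2 * pi * f0 * t / fs), cutoff = 1, order = 1, fs = fs)
  mid <- y[1000:3000]
  measured_amp <- sqrt(2 * mean(mid^2))
  expect_equal(measured_amp, expected_amp, tolerance = 0.02)
})

test_that("segments are cut per maximal nonzero label run", {
  rec <- structure(list(emg = matrix(1:12, nrow = 2, byrow = TRUE),
                        fs = 100, labels = c(0, 0, 3, 3, 3, 0),
                        repetitions = c(0, 0, 1, 1, 1, 0)),
                   class = "recording")
  segs <- extract_segments(rec)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$gesture, 3)
  expect_equal(segs[[1]]$raw_bounds, c(3, 5))
  expect_equal(segs[[1]]$repetition, 1)

  rec$labels <- rep(0L, 6)
  expect_length(extract_segments(rec), 0)

  rec$labels <- c(2, 2, 0, 2, 2, 0); rec$repetitions <- c(1, 1, 0, 2, 2, 0)
  segs <- extract_segments(rec)
  expect_length(segs, 2)
  expect_equal(sapply(segs, `[[`, "repetition"), c(1, 2))
})

test_that("GLR locates a known variance step and fuses by earliest/latest vote", {
  set.seed(42)
  # three channels with true onsets/offsets at different positions;
  # fused bounds must be the earliest onset and the latest offset
  T_len <- 1000
  ons <- c(300, 290, 295); offs <- c(700, 710, 705)
  emg <- matrix(rnorm(3 * T_len, 0, 0.05), nrow = 3)
  for (ch in 1:3) emg[ch, ons[ch]:offs[ch]] <-
    emg[ch, ons[ch]:offs[ch]] + rnorm(offs[ch] - ons[ch] + 1, 0, 1)
  labels <- integer(T_len); labels[305:695] <- 1L
  rec <- structure(list(emg = emg, fs = 100, labels = labels,
                        repetitions = as.integer(labels)),
                   class = "recording")
  seg <- extract_segments(rec)[[1]]
  ref <- refine_boundaries_glr(rec, seg, glr_config())
  expect_lte(abs(ref$refined_bounds[1] - min(ons)), 5)
  expect_lte(abs(ref$refined_bounds[2] - max(offs)), 5)
  # fusion monotonicity: fused bounds contain every per-channel truth
  expect_lte(ref$refined_bounds[1], min(ons) + 5)
  expect_gte(ref$refined_bounds[2], max(offs) - 5)
  # refinement containment inside the expanded window
  e <- round(0.25 * (seg$raw_bounds[2] - seg$raw_bounds[1] + 1))
  expect_gte(ref$refined_bounds[1], seg$raw_bounds[1] - e)
  expect_lte(ref$refined_bounds[2], seg$raw_bounds[2] + e)

  # exhaustive scan oracle on one channel's onset window
  mid <- floor(mean(seg$raw_bounds))
  lo <- seg$raw_bounds[1] - e
  x <- abs(emg[1, lo:mid]); n <- length(x)
  lls <- sapply(11:(n - 9), function(c) {
    v1 <- mean(x[1:(c - 1)]^2); v2 <- mean(x[c:n]^2)
    -(c - 1) / 2 * log(v1 + 1e-12) - (n - c + 1) / 2 * log(v2 + 1e-12)
  })
  oracle_onset <- lo + (11:(n - 9))[which.max(lls)] - 1
  res <- frozemg:::glr_scan(x, 10, 1e-12)
  expect_equal(lo + res$change - 1, oracle_onset)
})

test_that("GLR falls back to raw bounds on a pure-noise window", {
  set.seed(1)
  emg <- matrix(rnorm(2 * 600, 0, 0.3), nrow = 2)
  labels <- integer(600); labels[200:400] <- 1L
  rec <- structure(list(emg = emg, fs = 100, labels = labels,
                        repetitions = as.integer(labels)),
                   class = "recording")
  seg <- extract_segments(rec)[[1]]
  ref <- refine_boundaries_glr(rec, seg, glr_config())
  expect_equal(ref$refined_bounds, seg$raw_bounds)
})

test_that("length standardization pads, truncates, and is idempotent", {
  m <- matrix(rnorm(3 * 900), nrow = 3)
  out <- standardize_length(m, 1100)
  expect_equal(dim(out), c(3, 1100))
  expect_true(all(out[, 901:1100] == 0))
  expect_equal(out[, 1:900], m)

  long <- matrix(rnorm(3 * 1300), nrow = 3)
  expect_equal(standardize_length(long, 1100), long[, 1:1100])

  exact <- matrix(rnorm(3 * 1100), nrow = 3)
  expect_identical(standardize_length(exact, 1100), exact)
  expect_identical(standardize_length(standardize_length(m, 1100), 1100),
                   standardize_length(m, 1100))
})

test_that("Welch PSD matches FFT peak and variance oracles", {
  expect_equal(welch_psd(rep(0, 1024))$psd, rep(0, 257))
  expect_error(welch_psd(rnorm(100)), "shorter")

  # 0.5 Hz tone at fs = 100: peak at the grid frequency nearest 0.5 Hz
  t <- 0:2047
  w <- welch_psd(sin(2 * pi * 0.5 * t / 100), fs = 100)
  expect_equal(w$freq[which.max(w$psd)], w$freq[which.min(abs(w$freq - 0.5))])
  expect_true(all(w$psd >= 0))
  expect_equal(range(w$freq), c(0, 50))

  # white noise: band-integrated power within 3x of the variance
  set.seed(8)
  x <- rnorm(4096, 0, 1.3)
  w <- welch_psd(x, fs = 100)
  total <- sum(w$psd) * (w$freq[2] - w$freq[1])
  expect_gt(total, var(x) / 3)
  expect_lt(total, var(x) * 3)
})
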