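test_that("front-end is causal, linear, and kills DC and mains", {
  cfg <- eog_config()
  fs <- 256

  # all-zero block stays zero
  bank <- filter_bank(fs, cfg)
  zero <- tibble::tibble(block_index = 0L, t0 = 0,
                         left = list(rep(0, fs)), right = list(rep(0, fs)))
  out <- apply_frontend(zero, bank)
  expect_equal(out$left[[1]], rep(0, fs))

  # steady 50 Hz is attenuated by far more than 20 dB at steady state
  t <- (0:(20 * fs - 1)) / fs
  s50 <- sin(2 * pi * 50 * t)
  bank <- filter_bank(fs, cfg)
  y <- numeric(0)
  for (i in 1:20) {
    blk <- tibble::tibble(block_index = i - 1L, t0 = i - 1,
                          left = list(s50[((i - 1) * fs + 1):(i * fs)]),
                          right = list(rep(0, fs)))
    y <- c(y, apply_frontend(blk, bank)$left[[1]])
  }
  rms_in <- sqrt(mean(s50^2))
  rms_out <- sqrt(mean(tail(y, 5 * fs)^2))
  expect_lt(20 * log10(rms_out / rms_in), -20)

  # constant offset decays towards zero (0.5 Hz high-pass edge)
  bank <- filter_bank(fs, cfg)
  y <- numeric(0)
  for (i in 1:10) {
    blk <- tibble::tibble(block_index = i - 1L, t0 = i - 1,
                          left = list(rep(100, fs)), right = list(rep(0, fs)))
    y <- c(y, apply_frontend(blk, bank)$left[[1]])
  }
  expect_lt(abs(mean(tail(y, fs))), 5)
})

test_that("block-streamed filtering equals whole-record filtering", {
  cfg <- eog_config()
  fs <- 256
  set.seed(3)
  x <- rnorm(10 * fs, sd = 20)

  bp <- signal::butter(cfg$bandpass$order / 2,
                       c(cfg$bandpass$lo, cfg$bandpass$hi) / (fs / 2), "pass")
  nt <- signal::butter(cfg$notch$order / 2, cfg$notch$band / (fs / 2), "stop")
  ref <- filter_whole(nt, filter_whole(bp, x))

  bank <- filter_bank(fs, cfg)
  y <- numeric(0)
  for (i in 1:10) {
    blk <- tibble::tibble(block_index = i - 1L, t0 = i - 1,
                          left = list(x[((i - 1) * fs + 1):(i * fs)]),
                          right = list(rep(0, fs)))
    y <- c(y, apply_frontend(blk, bank)$left[[1]])
  }
  expect_lt(max(abs(y - ref)), 1e-6)
})

test_that("band split separates slow and fast content and conserves energy", {
  cfg <- eog_config()
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs

  rms <- function(v) sqrt(mean(v^2))
  steady <- function(v) tail(v, 5 * fs)

  bank <- filter_bank(fs, cfg)
  s2 <- sin(2 * pi * 2 * t)
  sp <- split_bands(s2, bank, "left")
  expect_gt(rms(steady(sp$low)), 0.9 * rms(s2))
  expect_lt(rms(steady(sp$high)), 0.1 * rms(s2))

  bank <- filter_bank(fs, cfg)
  s40 <- sin(2 * pi * 40 * t)
  sp <- split_bands(s40, bank, "left")
  expect_gt(rms(steady(sp$high)), 0.9 * rms(s40))
  expect_lt(rms(steady(sp$low)), 0.1 * rms(s40))

  # broadband noise: energy approximately partitions across the two bands
  set.seed(4)
  bank <- filter_bank(fs, cfg)
  w <- rnorm(20 * fs)
  sp <- split_bands(w, bank, "left")
  lhs <- rms(steady(sp$low))^2 + rms(steady(sp$high))^2
  expect_lt(abs(lhs - rms(steady(w))^2) / rms(steady(w))^2, 0.15)

  # zero in, zero out; empty in, empty out
  bank <- filter_bank(fs, cfg)
  expect_equal(split_bands(rep(0, fs), bank, "left")$low, rep(0, fs))
  expect_equal(split_bands(numeric(0), bank, "left")$low, numeric(0))
})

test_that("filter stages are linear operators", {
  cfg <- eog_config()
  fs <- 256
  set.seed(5)
  x <- rnorm(2 * fs); y <- rnorm(2 * fs)
  run <- function(v) {
    bank <- filter_bank(fs, cfg)
    eogbci:::run_stage(bank, "bandpass", "left", v)
  }
  expect_equal(run(2 * x + 3 * y), 2 * run(x) + 3 * run(y), tolerance = 1e-9)
})

test_that("baseline correction removes drift and the mean, preserving transients", {
  fs <- 256
  # constant signal -> all zero
  expect_equal(correct_baseline(rep(7, fs), 1.0, fs), rep(0, fs))

  # any input -> zero mean
  set.seed(6)
  x <- rnorm(fs) + 30
  expect_lt(abs(mean(correct_baseline(x, 0.25, fs))), 1e-9)

  # equals the brute-force residual oracle (ramp, 100-ms window)
  ramp <- seq(0, 1, length.out = fs)
  got <- correct_baseline(ramp, 0.1, fs)
  resid <- ramp - ma_brute(ramp, round(0.1 * fs))
  expect_equal(got, resid - mean(resid), tolerance = 1e-12)

  # window longer than the signal is clamped with a warning
  expect_warning(correct_baseline(rnorm(100), 1.0, fs), "clamped")

  # a fast biphasic transient survives; slow drift does not
  t <- (0:(3 * fs - 1)) / fs
  drift <- 20 * sin(2 * pi * 0.2 * t)
  lobe <- sin(pi * seq(0, 1, length.out = 21))
  pulse <- rep(0, length(t))
  pulse[380:400] <- 60 * lobe; pulse[401:421] <- -60 * lobe
  y <- correct_baseline(drift + pulse, 1.0, fs)
  expect_gt(max(y), 40)                         # transient retained
  y_far <- y[t > 2.2]                           # away from the transient
  expect_lt(max(abs(y_far)), 6)                 # drift suppressed
})

test_that("derived pair implements difference and smoothed sum", {
  fs <- 256
  set.seed(8)
  x <- rnorm(fs)

  # identical channels cancel in Y1
  p <- derive_pair(x, x, 0.1, fs)
  expect_equal(p$y1[[1]], rep(0, fs))

  # antisymmetric channels cancel in Y2 exactly (linear smoothing of zero)
  p <- derive_pair(x, -x, 0.1, fs)
  expect_equal(p$y2[[1]], rep(0, fs), tolerance = 1e-12)

  # unit pulse smears but conserves area on interior support
  pulse <- rep(0, fs); pulse[128] <- 1
  p <- derive_pair(pulse, rep(0, fs), 0.1, fs)
  expect_equal(p$y1[[1]], pulse)
  expect_equal(sum(p$y2[[1]]), 1, tolerance = 1e-6)

  expect_error(derive_pair(rnorm(10), rnorm(9)), "equal length")
})
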