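cfg <- eog_config()

test_that("a zero or noise-only block classifies as center", {
  fs <- 256
  th <- default_thresholds()
  p0 <- derive_pair(rep(0, fs), rep(0, fs), 0.1, fs)
  expect_equal(classify_block(p0, th, cfg), "center")

  rec <- noise_recording(n_s = 10, seed = 50, sd = 8)
  dec <- classify_stream(rec, th, cfg)
  expect_equal(nrow(dec), 10)
  expect_true(all(dec$decision == "center"))
})

test_that("synthetic event blocks classify as their generating class", {
  th <- default_thresholds()
  ds <- synth_dataset(2, synth_config(seed = 61))
  res <- classify_dataset(ds, th, cfg)
  for (cls in c("left", "right", "blink")) {
    expect_true(all(res$decision[res$class == cls] == cls),
                label = paste("class", cls))
  }
})

test_that("classification is deterministic given inputs and thresholds", {
  th <- default_thresholds()
  rec <- synth_trial("open_6class", synth_config(seed = 62))
  d1 <- classify_stream(rec, th, cfg)
  d2 <- classify_stream(rec, th, cfg)
  expect_identical(d1$decision, d2$decision)
})

test_that("calibration separates clean populations and reports statistics", {
  fe <- dataset_features(synth_dataset(5, synth_config(seed = 10)), cfg)
  th <- calibrate_thresholds(fe, cfg)
  expect_s3_class(th, "eog_thresholds")
  expect_true(all(unlist(th[c("e_y1", "e_y2", "cmax_min", "amp_min",
                              "vel_min", "blink_amp_min")]) > 0))
  rep <- attr(th, "report")
  expect_true(all(c("feature", "event_mean", "noise_mean", "threshold")
                  %in% names(rep)))
  # with well-separated populations every threshold lies between the means
  for (k in seq_len(nrow(rep))) {
    lo <- min(rep$event_mean[k], rep$noise_mean[k])
    hi <- max(rep$event_mean[k], rep$noise_mean[k])
    expect_gte(rep$threshold[k], lo)
    expect_lte(rep$threshold[k], hi)
  }
})

test_that("calibration fails loudly when a class is absent", {
  fe <- dataset_features(synth_dataset(5, synth_config(seed = 10)), cfg)
  expect_error(calibrate_thresholds(fe[fe$class != "blink", ], cfg), "blink")
  expect_error(calibrate_thresholds(fe[fe$class != "center", ], cfg), "center")
})

test_that("degenerate identical populations give midpoint-at-mean and center fallback", {
  # hand-built feature table: event and noise populations identical
  mk <- function(cls, sig) tibble::tibble(
    c_max = 10, auc_pos = 1, auc_neg = -1, amplitude = 20, velocity = 100,
    lead_sign = 1, mono_index = 0.5, signal = sig, energy = 1000,
    block_index = 0L, class = cls)
  fe <- dplyr::bind_rows(lapply(eye_classes(), function(cl)
    dplyr::bind_rows(replicate(6, dplyr::bind_rows(mk(cl, "y1"), mk(cl, "y2")),
                               simplify = FALSE))))
  th <- calibrate_thresholds(fe, cfg)
  expect_equal(th$amp_min, 20)      # midpoint of identical populations
  expect_equal(th$cmax_min, 10)
  # ambiguous blocks (energy below mean+4SD=1000... sd 0) -> gate blocks them
  fs <- 256
  p0 <- derive_pair(rnorm(fs, sd = 1e-3), rnorm(fs, sd = 1e-3), 0.1, fs)
  expect_equal(classify_block(p0, th, cfg), "center")
})

test_that("thresholds calibrated on one seed generalize to an independent seed", {
  th <- calibrate_thresholds(
    dataset_features(synth_dataset(5, synth_config(seed = 200)), cfg), cfg)
  res <- classify_dataset(synth_dataset(5, synth_config(seed = 201)), th, cfg)
  expect_gt(mean(res$class == res$decision) * 100, 100 / 6)  # above chance
})

test_that("polarity convention maps leading lobes to directions", {
  th <- default_thresholds()
  scfg <- synth_config(seed = 63, noise_sd = 0, line_amp = 0, drift_amp = 0)
  ds <- synth_dataset(1, scfg)
  res <- classify_dataset(ds, th, cfg)
  got <- stats::setNames(res$decision, res$class)
  expect_equal(got[["left"]], "left")
  expect_equal(got[["right"]], "right")
  expect_equal(got[["up"]], "up")
  expect_equal(got[["down"]], "down")
  expect_equal(got[["blink"]], "blink")

  # flipping the polarity constant flips horizontal and vertical directions
  cfg_flip <- eog_config(classify = list(polarity = -1))
  res_f <- classify_dataset(ds, th, cfg_flip)
  got_f <- stats::setNames(res_f$decision, res_f$class)
  expect_equal(got_f[["left"]], "right")
  expect_equal(got_f[["up"]], "down")
})

test_that("closed-eyes mode merges blink into up", {
  th <- default_thresholds()
  ds <- synth_dataset(2, synth_config(seed = 64))
  res <- classify_dataset(ds, th, cfg, mode = "closed_5class")
  expect_false("blink" %in% res$decision)
  expect_false("blink" %in% res$class)
  # blink-generated segments are decided as up in the merged mode
  expect_true(all(res$decision[ds$class == "blink"] == "up"))
})

test_that("streaming emits one decision per block and matches the protocol schedule", {
  th <- default_thresholds()
  rec <- synth_trial("open_6class", synth_config(seed = 65))
  dec <- classify_stream(rec, th, cfg)
  expect_equal(nrow(dec), 60)
  expect_equal(dec$block_index, 0:59)
  # each labeled event block matches within ±1 block
  ev <- dec[dec$label != "center", ]
  for (k in seq_len(nrow(ev))) {
    neigh <- dec$decision[abs(dec$block_index - ev$block_index[k]) <= 1]
    expect_true(ev$label[k] %in% neigh,
                label = sprintf("block %d (%s)", ev$block_index[k], ev$label[k]))
  }
})

test_that("triple blinks within five seconds register a toggle", {
  d <- tibble::tibble(block_index = c(2, 10, 12, 14, 30),
                      decision = c("blink", "blink", "blink", "blink", "blink"))
  expect_equal(blink_toggles(d), 14)
  d2 <- tibble::tibble(block_index = c(1, 10, 20),
                       decision = rep("blink", 3))
  expect_equal(blink_toggles(d2), integer(0))
})

test_that("six-class accuracy degrades monotonically with noise", {
  th <- calibrate_thresholds(
    dataset_features(synth_dataset(10, synth_config(seed = 10)), cfg), cfg)
  acc <- vapply(c(0.5, 1, 2, 4), function(mult) {
    scfg <- synth_config(seed = 300 + round(mult * 10), noise_sd = 8 * mult)
    res <- classify_dataset(synth_dataset(5, scfg), th, cfg)
    mean(res$class == res$decision) * 100
  }, numeric(1))
  # non-increasing, allowing one inversion of <= 2 points for sampling error
  expect_true(all(diff(acc) <= 2))
  expect_lt(acc[4], acc[1])
})

test_that("threshold YAML round-trip is exact", {
  th <- default_thresholds()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds(th, f)
  back <- read_thresholds(f)
  expect_equal(unclass(back)[names(th)], unclass(th)[names(th)],
               tolerance = 1e-9)
  expect_equal(tidy(th)$parameter, names(th))
})
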