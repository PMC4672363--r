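#' Synthetic EOG/EEG generator configuration
#'
#' Parameters of the two-channel synthetic signal model that stands in for
#' recorded data. Events are deterministic class templates added onto a
#' stochastic background:
#' \itemize{
#'   \item left/right saccades: antisymmetric biphasic transients (one
#'     raised-cosine lobe per phase, opposite polarity on the two channels),
#'     so the channel difference Y1 carries the signature;
#'   \item up/down movements: common-mode biphasic transients with unequal
#'     channel gains (`vertical_asymmetry` : 1) --- the eyes do not move at
#'     mirrored angles across the midline, so the two temporal electrodes see
#'     slightly different vertical EOG, which the smoothed sum Y2 amplifies
#'     while leaving a small residue on Y1;
#'   \item blink: a same-polarity Gaussian pulse (SD = `blink_dur`/4) on both
#'     channels.
#' }
#' Background = band-limited pink (1/f) noise, 10 Hz alpha bursts at ~20%
#' duty cycle, common-mode 50 Hz mains, and slow (< 0.3 Hz) drift.
#'
#' @param sample_rate Hz (default 256).
#' @param saccade_amp Saccade lobe amplitude, microvolts (default 60).
#' @param saccade_dur Duration of one saccade lobe, seconds (default 0.08).
#' @param blink_amp Blink pulse amplitude, microvolts (default 120).
#' @param blink_dur Blink pulse nominal duration, seconds (default 0.25).
#' @param vertical_asymmetry Left/right channel gain ratio for vertical
#'   events; must be strictly > 1 or up/down become invisible on Y2's
#'   companion Y1 margin (default 1.3).
#' @param noise_sd Pink-noise standard deviation, microvolts (default 8).
#' @param alpha_amp Amplitude of 10 Hz alpha bursts, microvolts; default
#'   0.6 * `noise_sd` so a noiseless configuration is fully silent.
#' @param line_amp 50 Hz mains amplitude, microvolts (default 5).
#' @param drift_amp Slow drift amplitude, microvolts (default 20).
#' @param seed Integer master seed.
#' @return A list of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$saccade_amp
#' @export
synth_config <- function(sample_rate = 256, saccade_amp = 60,
                         saccade_dur = 0.08, blink_amp = 120, blink_dur = 0.25,
                         vertical_asymmetry = 1.3, noise_sd = 8,
                         alpha_amp = NULL, line_amp = 5, drift_amp = 20,
                         seed = 1) {
  if (vertical_asymmetry <= 1)
    abort("vertical_asymmetry must be strictly greater than 1")
  stopifnot(saccade_amp >= 0, blink_amp >= 0, noise_sd >= 0, line_amp >= 0,
            drift_amp >= 0, saccade_dur > 0, blink_dur > 0)
  structure(list(
    sample_rate = sample_rate, saccade_amp = saccade_amp,
    saccade_dur = saccade_dur, blink_amp = blink_amp, blink_dur = blink_dur,
    vertical_asymmetry = vertical_asymmetry, noise_sd = noise_sd,
    alpha_amp = alpha_amp %||% (0.6 * noise_sd), line_amp = line_amp,
    drift_amp = drift_amp, seed = as.integer(seed)
  ), class = c("synth_config", "list"))
}

#' The six decision classes
#' @return Character vector: up, down, left, right, center, blink.
#' @export
eye_classes <- function() c("up", "down", "left", "right", "center", "blink")

# one raised-cosine (Hann) lobe of duration d seconds, peak 1
hann_lobe <- function(d, fs) {
  n <- max(2L, round(d * fs))
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

# class templates, deterministic; returns list(left, right)
event_template <- function(cls, cfg) {
  fs <- cfg$sample_rate
  if (cls %in% c("left", "right", "up", "down")) {
    lobe <- hann_lobe(cfg$saccade_dur, fs) * cfg$saccade_amp
    bi <- c(lobe, -lobe)                      # positive lobe leading
    switch(cls,
      left  = list(left =  bi, right = -bi),
      right = list(left = -bi, right =  bi),
      up    = list(left = cfg$vertical_asymmetry * bi, right = bi),
      down  = list(left = -cfg$vertical_asymmetry * bi, right = -bi))
  } else if (cls == "blink") {
    sdv <- cfg$blink_dur / 4
    tt <- seq(-2 * cfg$blink_dur, 2 * cfg$blink_dur, by = 1 / fs)
    g <- cfg$blink_amp * exp(-tt^2 / (2 * sdv^2))
    list(left = g, right = g)
  } else {
    abort(paste0("unsupported event class: ", cls))
  }
}

#' Generate one event as a two-channel segment
#'
#' @param cls One of `"up"`, `"down"`, `"left"`, `"right"`, `"blink"`
#'   (`"center"` has no template --- it is the absence of an event).
#' @param cfg A [synth_config()].
#' @param t0 Start time of the segment in seconds (stamps the `time_s` axis).
#' @return A tibble `time_s`, `left_uV`, `right_uV` covering the event
#'   support only.
#' @examples
#' ev <- synth_event("blink", synth_config())
#' max(abs(ev$left_uV + ev$right_uV)) >= 1.5 * max(abs(ev$left_uV - ev$right_uV))
#' @export
synth_event <- function(cls, cfg = synth_config(), t0 = 0) {
  tpl <- event_template(cls, cfg)
  tibble(time_s = t0 + (seq_along(tpl$left) - 1) / cfg$sample_rate,
         left_uV = tpl$left, right_uV = tpl$right)
}

# band-limited pink (1/f) noise, sd scaled to `sd_target`
pink_noise <- function(n, fs, sd_target, lo = 0.5, hi = 100) {
  if (sd_target <= 0 || n < 4) return(rep(0, n))
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- ifelse(f >= lo & f <= hi, 1 / sqrt(f), 0)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, Conj(rev(spec[1:(n - nf - 1)])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s * sd_target
}

# 10 Hz alpha bursts, ~duty fraction of the time, Hann-windowed 1-s bursts
alpha_bursts <- function(n, fs, amp, duty = 0.2) {
  if (amp <= 0) return(rep(0, n))
  x <- rep(0, n)
  blen <- round(fs * 1.0)
  n_bursts <- max(0L, round(duty * n / blen))
  if (n_bursts == 0) return(x)
  starts <- sort(sample.int(max(1L, n - blen), n_bursts))
  for (s in starts) {
    idx <- s:min(n, s + blen - 1)
    tt <- (idx - s) / fs
    x[idx] <- x[idx] + amp * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) *
      0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
  }
  x
}

# stochastic background; line noise is common-mode across channels
synth_background <- function(n, cfg) {
  fs <- cfg$sample_rate
  t <- (seq_len(n) - 1) / fs
  line <- cfg$line_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
  one_channel <- function() {
    drift <- 0
    if (cfg$drift_amp > 0) {
      for (k in 1:2) {
        f <- runif(1, 0.05, 0.3)
        drift <- drift + (cfg$drift_amp / 2) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
      }
    }
    pink_noise(n, fs, cfg$noise_sd) + alpha_bursts(n, fs, cfg$alpha_amp) + drift
  }
  list(left = one_channel() + line, right = one_channel() + line)
}

# add a template into a channel canvas, centered at sample `center` (1-based)
add_centered <- function(canvas, tpl, center) {
  m <- length(tpl)
  start <- center - m %/% 2
  idx <- start:(start + m - 1)
  keep <- idx >= 1 & idx <= length(canvas)
  canvas[idx[keep]] <- canvas[idx[keep]] + tpl[keep]
  canvas
}

#' Generate one 60-s trial following the cued protocol
#'
#' The trial schedule mirrors the study protocol: 10 s of center fixation,
#' then four cued directional movements (one per cardinal direction, in
#' randomised order at nominal cue times 15/25/35/45 s with uniform +/- 1 s
#' jitter), and three blinks in the final 10 s (nominal 54/55.5/57 s,
#' +/- 0.5 s jitter: the three blinks form one deliberate toggle gesture, so
#' they fall within a 5-s span). Per-sample labels mark the whole 1-s block containing each event
#' center with the event class; all other samples are `"center"`.
#'
#' @param protocol `"open_6class"` or `"closed_5class"`. In the closed-eyes
#'   protocol the blink and up classes are merged: blink events are labeled
#'   `"up"`, yielding 5 label classes.
#' @param cfg A [synth_config()]; `cfg$seed` makes the trial reproducible
#'   bit-for-bit.
#' @param duration_s Trial length in seconds (default 60).
#' @return A labeled [eog_recording()] of `duration_s * sample_rate` samples.
#' @examples
#' rec <- synth_trial("open_6class", synth_config(seed = 3))
#' nrow(rec)  # 15360
#' @export
synth_trial <- function(protocol = c("open_6class", "closed_5class"),
                        cfg = synth_config(), duration_s = 60) {
  protocol <- match.arg(protocol)
  fs <- cfg$sample_rate
  set.seed(cfg$seed)
  n <- round(duration_s * fs)
  bg <- synth_background(n, cfg)
  labels <- rep("center", n)

  dirs <- sample(c("up", "down", "left", "right"))
  cues <- c(15, 25, 35, 45) + runif(4, -1, 1)
  blinks <- c(54, 55.5, 57) + runif(3, -0.5, 0.5)
  events <- tibble(class = c(dirs, rep("blink", 3)), t = c(cues, blinks))

  for (i in seq_len(nrow(events))) {
    tpl <- event_template(events$class[i], cfg)
    center <- round(events$t[i] * fs)
    bg$left <- add_centered(bg$left, tpl$left, center)
    bg$right <- add_centered(bg$right, tpl$right, center)
    blk <- (center - 1) %/% fs           # 0-based block containing the center
    span <- (blk * fs + 1):min(n, (blk + 1) * fs)
    lab <- events$class[i]
    if (protocol == "closed_5class" && lab == "blink") lab <- "up"
    labels[span] <- lab
  }
  eog_recording(bg$left, bg$right, sample_rate = fs, labels = labels,
                meta = list(protocol = protocol, seed = cfg$seed))
}

#' Generate a balanced dataset of event-centered segments
#'
#' For each of `n_trials_per_class` trials, one segment per event class (up,
#' down, left, right, blink) plus one noise-only `"center"` segment, i.e.
#' `6 * n` segments in total. Each segment is `segment_s` seconds (default 3)
#' of background with the event template centered in the middle 1-s block, so
#' that causal filters settle before the block of interest. Per-segment seeds
#' are derived deterministically from `cfg$seed`.
#'
#' @param n_trials_per_class Number of segments per class (>= 1).
#' @param cfg A [synth_config()].
#' @param segment_s Segment duration, seconds (integer, >= 3 recommended).
#' @return A tibble: `trial`, `class`, `seed`, list-columns `left`, `right`.
#' @examples
#' ds <- synth_dataset(2, synth_config(seed = 10))
#' nrow(ds)  # 12
#' @export
synth_dataset <- function(n_trials_per_class, cfg = synth_config(),
                          segment_s = 3) {
  stopifnot(n_trials_per_class >= 1)
  fs <- cfg$sample_rate
  n <- round(segment_s * fs)
  center_sample <- round((segment_s / 2) * fs)  # middle of the middle block
  classes <- c("up", "down", "left", "right", "blink", "center")
  grid <- tidyr::expand_grid(trial = seq_len(n_trials_per_class),
                             class = classes)
  grid$seed <- vapply(seq_len(nrow(grid)), function(i)
    derive_seed(cfg$seed, i), integer(1))
  segs <- purrr::map2(grid$class, grid$seed, function(cls, sd) {
    set.seed(sd)
    bg <- synth_background(n, cfg)
    if (cls != "center") {
      tpl <- event_template(cls, cfg)
      bg$left <- add_centered(bg$left, tpl$left, center_sample)
      bg$right <- add_centered(bg$right, tpl$right, center_sample)
    }
    bg
  })
  grid$left <- purrr::map(segs, "left")
  grid$right <- purrr::map(segs, "right")
  structure(grid, sample_rate = fs, segment_s = segment_s,
            class = c("eog_dataset", class(grid)))
}

derive_seed <- function(master, i) {
  as.integer((as.double(master) * 7919 + i * 104729) %% 2147483647)
}
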