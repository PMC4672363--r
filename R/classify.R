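#' Threshold set for hierarchical classification
#'
#' The classifier is a fixed decision tree; these are its knobs. Energy
#' thresholds `e_y1`/`e_y2` gate event detection per derived signal. The four
#' feature floors (`cmax_min`, `auc_min`, `amp_min`, `vel_min`) reject events
#' whose maximum wavelet coefficient, unsigned area, peak-to-peak amplitude or
#' peak velocity fall below plausible eye-movement scale. `blink_amp_min` and
#' `blink_sym_max` define the blink test on Y2: a blink is large, and after
#' the zero-DC causal front-end its positive hump and undershoot balance, so
#' its windowed net-to-total area ratio (`mono_index`) is close to zero ---
#' lower than the partially-windowed biphasic up/down transients;
#' `ratio_hv` is the scalogram-energy dominance ratio deciding the
#' horizontal-vs-vertical branch.
#'
#' @param e_y1,e_y2 Detection energy thresholds (>= 0).
#' @param cmax_min,auc_min,amp_min,vel_min Feature floors (>= 0); units:
#'   wavelet-coefficient units, microvolt-seconds, microvolts, microvolts/s.
#' @param blink_amp_min Blink amplitude floor, microvolts.
#' @param blink_sym_max Maximum net-to-total area ratio (0..1) for the blink
#'   symmetry test.
#' @param ratio_hv Energy dominance ratio (> 0).
#' @return A list of class `eog_thresholds`.
#' @seealso [calibrate_thresholds()]
#' @export
eog_thresholds <- function(e_y1 = 0, e_y2 = 0, cmax_min = 0, auc_min = 0,
                           amp_min = 0, vel_min = 0, blink_amp_min = 0,
                           blink_sym_max = 0.5, ratio_hv = 1.5) {
  vals <- c(e_y1 = e_y1, e_y2 = e_y2, cmax_min = cmax_min, auc_min = auc_min,
            amp_min = amp_min, vel_min = vel_min,
            blink_amp_min = blink_amp_min, blink_sym_max = blink_sym_max)
  if (any(vals < 0)) abort("all thresholds must be non-negative")
  if (ratio_hv <= 0) abort("ratio_hv must be positive")
  structure(c(as.list(vals), list(ratio_hv = ratio_hv)),
            class = c("eog_thresholds", "list"))
}

#' @export
print.eog_thresholds <- function(x, ...) {
  cat("<eog_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' @rdname eog_thresholds
#' @param x An `eog_thresholds` object.
#' @param ... Unused.
#' @method tidy eog_thresholds
#' @export
tidy.eog_thresholds <- function(x, ...) {
  tibble(parameter = names(x), value = unlist(x, use.names = FALSE))
}

#' Serialize thresholds to/from YAML
#' @param th An [eog_thresholds()] object.
#' @param path File path.
#' @return `read_thresholds()` returns an `eog_thresholds`.
#' @export
write_thresholds <- function(th, path) {
  yaml::write_yaml(unclass(th), path, precision = 12)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) do.call(eog_thresholds, yaml::read_yaml(path))

active_signal <- function(cls) {
  switch(cls, left = "y1", right = "y1", up = "y2", down = "y2",
         blink = "y2", abort(paste0("no active signal for class ", cls)))
}

#' Per-signal scalogram energies and event features for blocks
#'
#' The measurement step shared by calibration and inspection: for every block
#' (row of a [derive_stream()] table) and each derived signal, the Haar
#' scalogram energy and the features extracted at the maximum-coefficient
#' position, regardless of any threshold.
#'
#' @param pairs A tibble from [derive_stream()] (columns `block_index`, `y1`,
#'   `y2`, optionally `label`).
#' @param cfg An [eog_config()].
#' @return A tibble with two rows per block (`signal` = "y1"/"y2"): `energy`,
#'   `c_max`, `auc_pos`, `auc_neg`, `amplitude`, `velocity`, `lead_sign`,
#'   `mono_index`, plus `block_index` and `label` if present.
#' @export
block_features <- function(pairs, cfg = eog_config()) {
  fs <- attr(pairs, "sample_rate") %||% cfg$sample_rate
  scales <- scales_in_samples(cfg$cwt$scales_ms, fs)
  rows <- vector("list", 2L * nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (sig in c("y1", "y2")) {
      x <- pairs[[sig]][[i]]
      sc <- cwt_haar(x, scales)
      pk <- scalogram_peak(sc)
      f <- extract_features(x, pk$b_star, fs, pk$c_max,
                            cfg$features$window_ms, cfg$features$lead_fraction)
      f$signal <- sig
      f$energy <- sc$E
      f$block_index <- pairs$block_index[i]
      if ("label" %in% names(pairs)) f$label <- pairs$label[i]
      rows[[2L * (i - 1L) + (sig == "y2") + 1L]] <- f
    }
  }
  dplyr::bind_rows(rows)
}

#' Compute per-signal features over a labeled synthetic dataset
#'
#' Runs each segment of a [synth_dataset()] through the preprocessing chain,
#' takes the event-centered middle block, and measures both derived signals
#' with [block_features()].
#'
#' @param ds A [synth_dataset()] tibble.
#' @param cfg An [eog_config()].
#' @return A tibble with two rows (signals) per segment, carrying `class`.
#' @export
dataset_features <- function(ds, cfg = eog_config()) {
  seg_s <- attr(ds, "segment_s") %||% 3
  purrr::map_dfr(seq_len(nrow(ds)), function(i) {
    pair <- segment_middle_pair(ds$left[[i]], ds$right[[i]], cfg, seg_s)
    f <- block_features(pair, cfg)
    f$class <- ds$class[i]
    f$trial <- ds$trial[i]
    f
  })
}

midpoint_threshold <- function(pos, noise) {
  lo <- mean(pos) - 2 * stats::sd(pos)
  hi <- mean(noise) + 2 * stats::sd(noise)
  max(0, (lo + hi) / 2)
}

#' Calibrate classification thresholds from labeled features
#'
#' Implements fixed-threshold calibration from class means and standard
#' deviations. Detection energy thresholds are set from noise-only (center)
#' blocks as mean + 4 SD per signal. Each feature floor is the midpoint
#' between the event population's (mean - 2 SD), measured on each class's
#' active signal (Y1 for left/right, Y2 for up/down/blink), and the noise
#' population's (mean + 2 SD), floored at zero. The blink amplitude floor
#' and symmetry ceiling separate two event populations (blink vs up/down on
#' Y2), so they sit at the midpoint of the class means.
#'
#' @param feats A feature table from [dataset_features()] (or any tibble with
#'   columns `class`, `signal`, `energy`, `c_max`, `auc_pos`, `auc_neg`,
#'   `amplitude`, `velocity`, `mono_index`), with at least `min_per_class`
#'   examples of every class including `"center"`.
#' @param cfg An [eog_config()] (supplies `ratio_hv`).
#' @param min_per_class Minimum examples required per class (default 5).
#' @return An [eog_thresholds()] with a `report` attribute (a tibble of the
#'   population statistics behind every threshold).
#' @examples
#' ds <- synth_dataset(5, synth_config(seed = 10))
#' th <- calibrate_thresholds(dataset_features(ds))
#' th$e_y1 > 0
#' @export
calibrate_thresholds <- function(feats, cfg = eog_config(), min_per_class = 5) {
  counts <- table(feats$class[feats$signal == "y1"])
  missing <- setdiff(eye_classes(), names(counts))
  short <- names(counts)[counts < min_per_class]
  if (length(missing) || length(short))
    abort(paste0("calibration needs >= ", min_per_class,
                 " examples per class; missing: ",
                 paste(union(missing, short), collapse = ", ")))

  noise <- feats[feats$class == "center", ]
  e_y1 <- with(noise[noise$signal == "y1", ], mean(energy) + 4 * stats::sd(energy))
  e_y2 <- with(noise[noise$signal == "y2", ], mean(energy) + 4 * stats::sd(energy))

  ev <- feats[feats$class != "center", ]
  ev <- ev[ev$signal == vapply(ev$class, active_signal, character(1)), ]
  feat_val <- function(d, f) switch(f,
    c_max = d$c_max,
    auc = pmax(d$auc_pos, -d$auc_neg),
    amplitude = d$amplitude,
    velocity = d$velocity)

  floors <- vapply(c("c_max", "auc", "amplitude", "velocity"), function(f)
    midpoint_threshold(feat_val(ev, f), feat_val(noise, f)), numeric(1))

  # blink-vs-vertical are two event populations, not event-vs-noise: the
  # symmetric boundary is the midpoint of the class means. Blink sits ABOVE
  # vertical on amplitude and BELOW it on the net-to-total area ratio (the
  # zero-DC front-end balances the blink's hump and undershoot).
  vert <- ev[ev$class %in% c("up", "down"), ]
  blink <- ev[ev$class == "blink", ]
  blink_amp_min <- max(0, (mean(blink$amplitude) + mean(vert$amplitude)) / 2)
  blink_sym_max <- min(1, max(0, (mean(blink$mono_index) + mean(vert$mono_index)) / 2))

  th <- eog_thresholds(
    e_y1 = e_y1, e_y2 = e_y2,
    cmax_min = floors[["c_max"]], auc_min = floors[["auc"]],
    amp_min = floors[["amplitude"]], vel_min = floors[["velocity"]],
    blink_amp_min = blink_amp_min, blink_sym_max = blink_sym_max,
    ratio_hv = cfg$classify$ratio_hv
  )
  report <- dplyr::bind_rows(
    purrr::map_dfr(c("c_max", "auc", "amplitude", "velocity"), function(f)
      tibble(feature = f,
             event_mean = mean(feat_val(ev, f)), event_sd = stats::sd(feat_val(ev, f)),
             noise_mean = mean(feat_val(noise, f)), noise_sd = stats::sd(feat_val(noise, f)),
             threshold = floors[[if (f == "auc") "auc" else f]])),
    tibble(feature = c("blink_amplitude", "blink_sym_index"),
           event_mean = c(mean(blink$amplitude), mean(blink$mono_index)),
           event_sd = c(stats::sd(blink$amplitude), stats::sd(blink$mono_index)),
           noise_mean = c(mean(vert$amplitude), mean(vert$mono_index)),
           noise_sd = c(stats::sd(vert$amplitude), stats::sd(vert$mono_index)),
           threshold = c(blink_amp_min, blink_sym_max))
  )
  attr(th, "report") <- report
  th
}

floors_ok <- function(f, th) {
  f$c_max >= th$cmax_min &&
    max(f$auc_pos, -f$auc_neg) >= th$auc_min &&
    f$amplitude >= th$amp_min &&
    f$velocity >= th$vel_min
}

# the hierarchical decision tree over a pair of detection rows
decide_class <- function(pair, det, th, cfg, fs) {
  d1 <- det[det$signal == "y1", ]; d2 <- det[det$signal == "y2", ]
  if (!d1$detected && !d2$detected) return("center")
  get_feats <- function(sig, d) {
    extract_features(pair[[sig]][[1]], d$b_star, fs, d$c_max,
                     cfg$features$window_ms, cfg$features$lead_fraction)
  }
  f2 <- if (d2$detected) get_feats("y2", d2) else NULL
  if (d2$detected &&
      f2$amplitude >= th$blink_amp_min &&
      f2$mono_index <= th$blink_sym_max &&
      d2$energy >= th$ratio_hv * d1$energy) {
    return(if (floors_ok(f2, th)) "blink" else "center")
  }
  if (d1$detected && (!d2$detected || d1$energy >= th$ratio_hv * d2$energy)) {
    f1 <- get_feats("y1", d1)
    if (!floors_ok(f1, th)) return("center")
    s <- f1$lead_sign * cfg$classify$polarity
    return(if (s > 0) "left" else if (s < 0) "right" else "center")
  }
  if (d2$detected) {
    if (!floors_ok(f2, th)) return("center")
    s <- f2$lead_sign * cfg$classify$polarity
    return(if (s > 0) "up" else if (s < 0) "down" else "center")
  }
  # Y1 event present but not dominant and no Y2 event: treat as horizontal
  f1 <- get_feats("y1", d1)
  if (!floors_ok(f1, th)) return("center")
  s <- f1$lead_sign * cfg$classify$polarity
  if (s > 0) "left" else if (s < 0) "right" else "center"
}

#' Classify one 1-s block
#'
#' Applies the hierarchical threshold tree to one derived-pair block:
#' (1) no supra-threshold scalogram energy on either signal gives `center`;
#' (2) a large, monophasic, Y2-dominant event is a `blink`;
#' (3) Y1 energy dominance gives `left`/`right` by the sign of the leading
#' lobe; (4) otherwise a Y2 event gives `up`/`down` by its leading lobe;
#' (5) an event whose features fall below any floor falls back to `center`.
#' Deterministic given inputs and thresholds.
#'
#' @param pair A one-row `eog_pair` (one block from [derive_stream()]).
#' @param th An [eog_thresholds()].
#' @param cfg An [eog_config()].
#' @return A single class label (character).
#' @export
classify_block <- function(pair, th, cfg = eog_config()) {
  stopifnot(inherits(th, "eog_thresholds"))
  fs <- attr(pair, "sample_rate") %||% cfg$sample_rate
  scales <- scales_in_samples(cfg$cwt$scales_ms, fs)
  det <- detect_event(pair, scales,
                      energy_threshold = list(y1 = th$e_y1, y2 = th$e_y2))
  decide_class(pair, det, th, cfg, fs)
}

#' Classify a whole recording, one decision per 1-s block
#'
#' Streams the recording through the preprocessing chain and emits exactly
#' one decision per block (60 decisions per minute at 256 Hz with 1-s
#' blocks). Each block is analysed with the final `context_ms` of the
#' previous block's derived signals prepended so transients straddling a
#' block boundary are not truncated: detections whose center falls inside the
#' context belong to the previous block and are dropped, and a per-signal
#' refractory period of `refractory_ms` suppresses re-detection of the same
#' transient.
#'
#' @param rec An [eog_recording()].
#' @param th An [eog_thresholds()].
#' @param cfg An [eog_config()].
#' @param mode `"open_6class"` or `"closed_5class"`; the closed-eyes mode
#'   merges `blink` into `up` (their Y2 waveforms are near-identical and the
#'   protocol treats them as one class).
#' @return A tibble of class `eog_decisions`: `block_index`, `t0`,
#'   `decision`, `e_y1`, `e_y2`, plus `label` when the recording is labeled.
#' @examples
#' rec <- synth_trial("open_6class", synth_config(seed = 5))
#' th <- eog_thresholds(e_y1 = 50, e_y2 = 50, ratio_hv = 1.5)
#' dec <- classify_stream(rec, th)
#' nrow(dec)  # 60
#' @export
classify_stream <- function(rec, th, cfg = eog_config(),
                            mode = c("open_6class", "closed_5class")) {
  mode <- match.arg(mode)
  stopifnot(inherits(th, "eog_thresholds"))
  fs <- sample_rate(rec)
  scales <- scales_in_samples(cfg$cwt$scales_ms, fs)
  ctx <- round(cfg$detect$context_ms / 1000 * fs)
  refr <- cfg$detect$refractory_ms / 1000 * fs
  pairs <- derive_stream(rec, cfg)
  if (nrow(pairs) == 0)
    return(structure(tibble(block_index = integer(), t0 = numeric(),
                            decision = character(),
                            e_y1 = numeric(), e_y2 = numeric()),
                     class = c("eog_decisions", class(tibble()))))

  tail1 <- tail2 <- numeric(0)
  last_event <- c(y1 = -Inf, y2 = -Inf)   # absolute sample of last detection
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    y1 <- pairs$y1[[i]]; y2 <- pairs$y2[[i]]
    c1 <- length(tail1)
    py1 <- c(tail1, y1); py2 <- c(tail2, y2)
    pad <- pairs[i, ]
    pad$y1 <- list(py1); pad$y2 <- list(py2)
    det <- detect_event(pad, scales,
                        energy_threshold = list(y1 = th$e_y1, y2 = th$e_y2),
                        context_len = c1)
    blk0 <- pairs$block_index[i] * fs
    for (j in seq_len(nrow(det))) {
      if (!det$detected[j]) next
      sig <- det$signal[j]
      abs_pos <- blk0 + det$b_star[j] - c1
      in_context <- det$b_star[j] < c1
      refractory <- (abs_pos - last_event[[sig]]) < refr
      if (in_context || refractory) {
        det$detected[j] <- FALSE
      } else {
        last_event[[sig]] <- abs_pos
      }
    }
    cls <- decide_class(pad, det, th, cfg, fs)
    if (mode == "closed_5class" && cls == "blink") cls <- "up"
    res <- tibble(block_index = pairs$block_index[i], t0 = pairs$t0[i],
                  decision = cls,
                  e_y1 = det$energy[det$signal == "y1"],
                  e_y2 = det$energy[det$signal == "y2"])
    if ("label" %in% names(pairs)) res$label <- pairs$label[i]
    out[[i]] <- res
    tail1 <- tail(y1, ctx); tail2 <- tail(y2, ctx)
  }
  structure(dplyr::bind_rows(out),
            class = c("eog_decisions", class(tibble())),
            mode = mode, sample_rate = fs)
}

#' Classify the event-centered blocks of a dataset
#'
#' @param ds A [synth_dataset()].
#' @param th An [eog_thresholds()].
#' @param cfg An [eog_config()].
#' @param mode See [classify_stream()].
#' @return The dataset tibble with list-columns dropped and a `decision`
#'   column added (one decision per segment, from its middle block).
#' @export
classify_dataset <- function(ds, th, cfg = eog_config(),
                             mode = c("open_6class", "closed_5class")) {
  mode <- match.arg(mode)
  seg_s <- attr(ds, "segment_s") %||% 3
  dec <- vapply(seq_len(nrow(ds)), function(i) {
    pair <- segment_middle_pair(ds$left[[i]], ds$right[[i]], cfg, seg_s)
    classify_block(pair, th, cfg)
  }, character(1))
  if (mode == "closed_5class") dec[dec == "blink"] <- "up"
  truth <- ds$class
  if (mode == "closed_5class") truth[truth == "blink"] <- "up"
  tibble(trial = ds$trial, class = truth, decision = dec)
}

#' Find triple-blink toggle events in a decision stream
#'
#' Three or more blink decisions within a `window_s` span constitute a
#' "toggle" (the color-change gesture of the cued ball task).
#'
#' @param decisions An `eog_decisions` tibble (or any tibble with
#'   `block_index` and `decision`).
#' @param window_s Span in seconds (default 5).
#' @param n_blinks Number of blinks required (default 3).
#' @return Integer vector of block indices at which a toggle completes.
#' @export
blink_toggles <- function(decisions, window_s = 5, n_blinks = 3) {
  bi <- decisions$block_index[decisions$decision == "blink"]
  if (length(bi) < n_blinks) return(integer(0))
  out <- integer(0)
  used_until <- -Inf
  for (k in seq_along(bi)) {
    if (k < n_blinks) next
    first <- bi[k - n_blinks + 1]
    if (bi[k] - first < window_s && first > used_until) {
      out <- c(out, bi[k])
      used_until <- bi[k]
    }
  }
  out
}
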