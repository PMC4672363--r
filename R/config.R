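#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters for the streaming pipeline as a
#' named nested list. Values mirror the acquisition and processing chain of a
#' two-electrode temporal-EEG eye-movement interface: an 8th-order Butterworth
#' band-pass (0.5--100 Hz) and a 4th-order 48--52 Hz notch in front, a 10 Hz
#' two-band split, per-block baseline correction, and Haar-scalogram event
#' detection with hierarchical threshold classification.
#'
#' @param ... Named overrides, e.g. `eog_config(detect = list(refractory_ms = 400))`.
#'   Overrides are merged recursively into the defaults.
#'
#' @details
#' Keys (units in brackets):
#' \describe{
#'   \item{sample_rate}{acquisition rate \[Hz\], 256.}
#'   \item{bandpass}{`order` (total, 8), `lo` and `hi` cut-offs \[Hz\].}
#'   \item{notch}{`order` (total, 4), `band` stop edges \[Hz\].}
#'   \item{split}{`order` (4), `cutoff` \[Hz\] separating the EOG band
#'     (0.5--10 Hz) from the cortical band (10--100 Hz).}
#'   \item{baseline}{`win_s` \[s\]: moving-average window of the slow baseline
#'     estimate subtracted from the low band.}
#'   \item{y2}{`smooth_s` \[s\]: moving-average window applied to the channel
#'     sum when forming the vertical-axis signal Y2.}
#'   \item{cwt}{`scales_ms`: Haar wavelet support durations \[ms\]; converted
#'     to even sample counts at the configured rate.}
#'   \item{detect}{`energy_threshold` per derived signal (set by calibration),
#'     `refractory_ms`, `context_ms`.}
#'   \item{features}{`window_ms` (200), `lead_fraction` (0.25).}
#'   \item{classify}{`ratio_hv`: scalogram-energy dominance ratio deciding
#'     horizontal vs vertical; `polarity`: +1 means leftward gaze gives a
#'     positive leading lobe on Y1 and upward gaze/blink a positive leading
#'     lobe on Y2.}
#' }
#'
#' @return A named list of class `eog_config`.
#' @examples
#' cfg <- eog_config()
#' cfg$cwt$scales_ms
#' eog_config(baseline = list(win_s = 0.5))$baseline$win_s
#' @export
eog_config <- function(...) {
  cfg <- list(
    sample_rate = 256,
    bandpass = list(order = 8, lo = 0.5, hi = 100),
    notch    = list(order = 4, band = c(48, 52)),
    split    = list(order = 4, cutoff = 10),
    baseline = list(win_s = 1.0),
    y2       = list(smooth_s = 0.1),
    cwt      = list(scales_ms = c(31.25, 46.875, 62.5, 93.75, 125, 156.25, 203.125, 250)),
    detect   = list(energy_threshold = list(y1 = 0, y2 = 0),
                    refractory_ms = 500, context_ms = 250),
    features = list(window_ms = 200, lead_fraction = 0.25),
    classify = list(ratio_hv = 1.5, polarity = 1)
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      abort("overrides to eog_config() must be named")
    cfg <- merge_config(cfg, over)
  }
  structure(cfg, class = c("eog_config", "list"))
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns an `eog_config`; `write_config()` returns
#'   `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_config(eog_config(), p)
#' read_config(p)$sample_rate
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(eog_config, raw)
}

#' @rdname read_config
#' @param cfg An `eog_config` list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12)
  invisible(path)
}

# wavelet support durations (ms) -> even sample counts at fs
scales_in_samples <- function(scales_ms, fs) {
  a <- round(scales_ms * fs / 1000)
  a <- ifelse(a %% 2 == 1, a + 1, a)
  a <- pmax(a, 2L)
  unique(as.integer(a))
}
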