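#' Extract the classification features around a detected event
#'
#' Features are computed over a window of `window_ms` (default 200 ms, i.e. 51
#' samples at 256 Hz: 25 each side of the event, an odd symmetric window)
#' centered on the position of the maximum wavelet coefficient and clipped to
#' the signal bounds:
#' \describe{
#'   \item{auc_pos / auc_neg}{trapezoidal integral of the positive /
#'     negative part of the waveform over the window, in microvolt-seconds
#'     (`auc_neg` is signed, <= 0).}
#'   \item{amplitude}{peak-to-peak range in the window, microvolts.}
#'   \item{velocity}{maximum absolute first difference times the sample rate,
#'     microvolts per second.}
#'   \item{lead_sign}{sign of the waveform at its first excursion beyond
#'     `lead_fraction` of the window's absolute maximum; +1, -1, or 0 for a
#'     flat window. Encodes which lobe comes first and hence the movement
#'     direction.}
#'   \item{mono_index}{\eqn{|auc_{pos}+auc_{neg}|/(auc_{pos}-auc_{neg})}:
#'     1 for a purely monophasic pulse (blink-like), 0 for a balanced
#'     biphasic transient (saccade-like).}
#' }
#'
#' @param x Numeric series the event was detected on (same series that was
#'   passed to the detector, including any context).
#' @param b_star 0-based index of the event center within `x`.
#' @param sample_rate Sampling rate, Hz.
#' @param c_max Maximum absolute wavelet coefficient at the event (carried
#'   through from detection; `NA` if not available).
#' @param window_ms Feature window, milliseconds.
#' @param lead_fraction Threshold fraction for the leading-lobe sign rule.
#' @return A one-row tibble: `c_max`, `auc_pos`, `auc_neg`, `amplitude`,
#'   `velocity`, `lead_sign`, `mono_index`.
#' @examples
#' t <- seq(0, 0.2, by = 1 / 256)
#' pulse <- 10 * sin(pi * t / 0.2)
#' extract_features(pulse, b_star = 25, sample_rate = 256)
#' @export
extract_features <- function(x, b_star, sample_rate = 256, c_max = NA_real_,
                             window_ms = 200, lead_fraction = 0.25) {
  n <- length(x)
  if (b_star < 0 || b_star >= n)
    abort("event position lies outside the signal (detection bug)")
  half <- floor(window_ms / 1000 * sample_rate / 2)   # 25 at 256 Hz / 200 ms
  lo <- max(0L, b_star - half)
  hi <- min(n - 1L, b_star + half)
  w <- x[(lo + 1):(hi + 1)]
  tt <- (lo:hi) / sample_rate
  if (length(w) < 2) abort("feature window degenerate (fewer than 2 samples)")

  auc_pos <- pracma::trapz(tt, pmax(w, 0))
  auc_neg <- pracma::trapz(tt, pmin(w, 0))
  amplitude <- max(w) - min(w)
  velocity <- if (length(w) >= 2) max(abs(diff(w))) * sample_rate else 0

  amax <- max(abs(w))
  lead_sign <- 0
  if (amax > 0) {
    i <- which(abs(w) >= lead_fraction * amax)[1]
    lead_sign <- sign(w[i])
  }
  denom <- auc_pos - auc_neg
  mono_index <- if (denom > 0) abs(auc_pos + auc_neg) / denom else 0

  tibble(c_max = c_max, auc_pos = auc_pos, auc_neg = auc_neg,
         amplitude = amplitude, velocity = velocity,
         lead_sign = lead_sign, mono_index = mono_index)
}
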