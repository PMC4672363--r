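# Causal IIR front-end. All filters run in Direct Form I with input/output
# tails carried across block boundaries, so block-streamed filtering equals
# whole-record filtering exactly.

# One stateful pass of b/a over x; carry holds the previous nb-1 inputs and
# na-1 outputs. Built on stats::filter (C-level convolution + recursion).
iir_step <- function(b, a, x, carry = NULL) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  if (is.null(carry)) carry <- list(x = rep(0, nb - 1), y = rep(0, na - 1))
  if (length(x) == 0) return(list(y = numeric(0), carry = carry))
  xx <- c(carry$x, x)
  u <- stats::filter(xx, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb:length(xx)]
  y <- if (na > 1) {
    as.numeric(stats::filter(u, -a[-1], method = "recursive", init = rev(carry$y)))
  } else u
  list(y = y,
       carry = list(x = tail(xx, nb - 1), y = tail(c(carry$y, y), na - 1)))
}

new_stage <- function(filt) {
  list(b = filt$b, a = filt$a, carry = NULL)
}

run_stage <- function(bank, stage, channel, x) {
  st <- bank$stages[[stage]][[channel]]
  r <- iir_step(st$b, st$a, x, st$carry)
  bank$stages[[stage]][[channel]]$carry <- r$carry
  r$y
}

#' Create the causal filter bank
#'
#' Designs the four Butterworth stages of the front-end and band split:
#' an 8th-order band-pass (0.5--100 Hz), a 4th-order band-stop notch
#' (48--52 Hz) against 50 Hz mains, and the 4th-order low/high pair at 10 Hz
#' that separates the EOG band from cortical activity. The bank is a mutable
#' environment: per-filter, per-channel state persists across consecutive
#' blocks so that streamed and whole-record filtering agree exactly.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param cfg An [eog_config()].
#' @return An environment of class `eog_filter_bank`.
#' @examples
#' bank <- filter_bank(256)
#' blk <- tibble::tibble(block_index = 0L, t0 = 0,
#'                       left = list(rnorm(256)), right = list(rnorm(256)))
#' out <- apply_frontend(blk[1, ], bank)
#' @export
filter_bank <- function(sample_rate = 256, cfg = eog_config()) {
  nyq <- sample_rate / 2
  if (cfg$bandpass$hi >= nyq)
    abort("band-pass upper cut-off must be below the Nyquist frequency")
  designs <- list(
    bandpass = signal::butter(cfg$bandpass$order / 2,
                              c(cfg$bandpass$lo, cfg$bandpass$hi) / nyq, "pass"),
    notch    = signal::butter(cfg$notch$order / 2, cfg$notch$band / nyq, "stop"),
    split_low  = signal::butter(cfg$split$order, cfg$split$cutoff / nyq, "low"),
    split_high = signal::butter(cfg$split$order, cfg$split$cutoff / nyq, "high")
  )
  for (nm in names(designs)) {
    p <- Mod(polyroot(rev(designs[[nm]]$a)))
    if (any(p >= 1)) abort(paste0("designed filter '", nm, "' is unstable"))
  }
  bank <- new.env(parent = emptyenv())
  bank$sample_rate <- sample_rate
  bank$stages <- lapply(designs, function(d)
    list(left = new_stage(d), right = new_stage(d)))
  class(bank) <- "eog_filter_bank"
  bank
}

#' Reset all carried filter state to zero
#' @param bank An [filter_bank()].
#' @return The bank, invisibly.
#' @export
reset_bank <- function(bank) {
  for (stage in names(bank$stages))
    for (ch in c("left", "right"))
      bank$stages[[stage]][[ch]]$carry <- NULL
  invisible(bank)
}

#' Apply the causal front-end to one block
#'
#' Band-passes (0.5--100 Hz) then notch-filters (48--52 Hz) both channels,
#' causally, with filter state carried over from the previous block. Blocks
#' must be fed in order.
#'
#' @param block One row of the tibble returned by [stream_blocks()] (or any
#'   one-row tibble with list-columns `left` and `right`).
#' @param bank An [filter_bank()] initialised at the block's sample rate.
#' @return The block with `left` and `right` replaced by filtered series.
#' @export
apply_frontend <- function(block, bank) {
  stopifnot(inherits(bank, "eog_filter_bank"))
  if (!is_tibble(block) || nrow(block) != 1)
    abort("apply_frontend expects a single block (one-row tibble)")
  l <- block$left[[1]]; r <- block$right[[1]]
  if (length(l) != bank$sample_rate || length(r) != bank$sample_rate)
    abort("block length does not match the bank's sample rate (1-s block contract)")
  for (stage in c("bandpass", "notch")) {
    l <- run_stage(bank, stage, "left", l)
    r <- run_stage(bank, stage, "right", r)
  }
  block$left <- list(l); block$right <- list(r)
  block
}

#' Split a series into the EOG and cortical bands
#'
#' Applies the 4th-order 10 Hz low- and high-pass pair. Only the low band
#' (0.5--10 Hz) feeds event detection and classification downstream; the high
#' band is returned for inspection. State is carried per channel.
#'
#' @param x Numeric series (already front-end filtered).
#' @param bank An [filter_bank()].
#' @param channel `"left"` or `"right"` (selects the carried state).
#' @return A list with numeric vectors `low` and `high`.
#' @export
split_bands <- function(x, bank, channel = c("left", "right")) {
  channel <- match.arg(channel)
  if (length(x) == 0) return(list(low = numeric(0), high = numeric(0)))
  list(low = run_stage(bank, "split_low", channel, x),
       high = run_stage(bank, "split_high", channel, x))
}

# Centered moving average with edge truncation (window shrinks near the
# boundaries); win in samples.
moving_average <- function(x, win) {
  n <- length(x)
  if (n == 0) return(x)
  win <- max(1L, as.integer(round(win)))
  if (win > n) win <- n
  h_lo <- (win - 1L) %/% 2L
  h_hi <- win - 1L - h_lo
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h_lo, 1L)
  hi <- pmin(i + h_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Remove the slow baseline from a series
#'
#' Estimates the baseline as a centered moving average of `smooth_win`
#' seconds (edge-truncated) and subtracts it, then removes the residual mean,
#' so the output mean is exactly zero. This suppresses slow drift while
#' leaving fast EOG transients (saccades, blinks) intact: the moving average
#' of a short zero-net-area transient is close to zero, so the transient
#' passes through the correction almost unchanged.
#'
#' @param x Numeric series, microvolts.
#' @param smooth_win Baseline window in seconds (> 0).
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric series, same length, mean zero.
#' @examples
#' correct_baseline(rep(5, 100), 0.1, 256)  # all zeros
#' @export
correct_baseline <- function(x, smooth_win = 1.0, sample_rate = 256) {
  if (smooth_win <= 0) abort("smooth_win must be positive")
  n <- length(x)
  if (n == 0) return(x)
  win <- round(smooth_win * sample_rate)
  if (win > n) {
    warn(sprintf("baseline window (%d samples) longer than signal (%d); clamped", win, n))
    win <- n
  }
  out <- x - moving_average(x, win)
  out - mean(out)
}

#' Form the derived signal pair Y1/Y2
#'
#' Y1 is the plain channel difference (left minus right): lateral eye
#' movements drive the two temporal electrodes with opposite polarity, so the
#' difference maximises the left/right margin. Y2 is the smoothed channel
#' sum: vertical movements and blinks are common-mode, so the sum amplifies
#' them while the difference cancels them; smoothing (moving average of
#' `y2_smooth_win` s) stabilises the slower vertical waveform. Y1 is not
#' smoothed.
#'
#' @param left_low,right_low Low-band (0.5--10 Hz), baseline-corrected series
#'   of equal length.
#' @param y2_smooth_win Smoothing window in seconds for Y2.
#' @param sample_rate Sampling rate in Hz.
#' @param block_index Ordinal block number carried through for bookkeeping.
#' @return A one-row tibble of class `eog_pair` with list-columns `y1`, `y2`
#'   and column `block_index`.
#' @export
derive_pair <- function(left_low, right_low, y2_smooth_win = 0.1,
                        sample_rate = 256, block_index = 0L) {
  if (length(left_low) != length(right_low))
    abort("left and right series must have equal length")
  y1 <- left_low - right_low
  y2 <- moving_average(left_low + right_low, round(y2_smooth_win * sample_rate))
  structure(tibble(block_index = as.integer(block_index),
                   y1 = list(y1), y2 = list(y2)),
            class = c("eog_pair", class(tibble())),
            sample_rate = sample_rate)
}
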