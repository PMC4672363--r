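#' Run the preprocessing chain over a recording
#'
#' Streams the recording in 1-s blocks and applies, in order: the causal
#' front-end (band-pass 0.5--100 Hz + 48--52 Hz notch, state carried across
#' blocks), the 10 Hz band split (state carried; only the low band continues),
#' block-local baseline correction, and the derived pair Y1 (difference) / Y2
#' (smoothed sum). Baseline correction and Y2 smoothing are block-local
#' (edge-truncated moving averages within each 1-s block), matching a
#' real-time loop that only ever holds one block.
#'
#' @param rec An [eog_recording()].
#' @param cfg An [eog_config()].
#' @param keep_high If `TRUE`, also keep the 10--100 Hz band as list-columns
#'   `high_left` / `high_right` (computed regardless, unused downstream).
#' @return A tibble with one row per block: `block_index`, `t0`, list-columns
#'   `y1`, `y2`, and `label` when the recording is labeled. Rows can be
#'   passed (one at a time) to [classify_block()].
#' @export
derive_stream <- function(rec, cfg = eog_config(), keep_high = FALSE) {
  fs <- sample_rate(rec)
  blocks <- stream_blocks(rec)
  if (nrow(blocks) == 0)
    return(tibble(block_index = integer(), t0 = numeric(),
                  y1 = list(), y2 = list()))
  bank <- filter_bank(fs, cfg)
  win_base <- cfg$baseline$win_s
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    blk <- apply_frontend(blocks[i, ], bank)
    sl <- split_bands(blk$left[[1]], bank, "left")
    sr <- split_bands(blk$right[[1]], bank, "right")
    ll <- correct_baseline(sl$low, win_base, fs)
    rr <- correct_baseline(sr$low, win_base, fs)
    pair <- derive_pair(ll, rr, cfg$y2$smooth_s, fs,
                        block_index = blocks$block_index[i])
    pair$t0 <- blocks$t0[i]
    if (keep_high) {
      pair$high_left <- list(sl$high)
      pair$high_right <- list(sr$high)
    }
    out[[i]] <- pair
  }
  res <- dplyr::bind_rows(out)
  if ("label" %in% names(blocks)) res$label <- blocks$label
  attr(res, "sample_rate") <- fs
  res
}

# derive the middle-block pair of a dataset segment (left/right vectors)
segment_middle_pair <- function(left, right, cfg, segment_s) {
  fs <- cfg$sample_rate
  rec <- eog_recording(left, right, sample_rate = fs)
  pairs <- derive_stream(rec, cfg)
  mid <- segment_s %/% 2
  pairs[pairs$block_index == mid, ]
}
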