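#' Haar continuous wavelet transform and scalogram
#'
#' Computes \eqn{C_{a,b} = a^{-1/2} \sum_t x(t)\,\psi((t-b)/a)} with the Haar
#' mother wavelet (+1 on the first half of the support, -1 on the second),
#' for each scale `a` (wavelet support in samples) and every shift `b` whose
#' support lies fully inside the signal. The per-coefficient energy is
#' \eqn{S = C \circ C} and the block energy \eqn{E = \sum S}. Because the Haar
#' wavelet has zero mean, a constant signal gives all-zero coefficients and
#' `E = 0`.
#'
#' Implemented with cumulative sums (each coefficient is a difference of two
#' half-support box sums), which is exact: it matches the direct double-loop
#' summation to machine precision.
#'
#' @param x Numeric series (one 1-s block, possibly with context prepended).
#' @param scales Integer vector of wavelet supports in samples; must be even
#'   (the two half-supports need equal weight for the zero-mean property) and
#'   no longer than the signal.
#' @return An object of class `eog_scalogram`: a list with `coefs` (matrix,
#'   scales x shifts, `NA` where the support would overrun the signal),
#'   `scales`, `S` (squared coefficients), `E` (total energy) and `n`.
#' @examples
#' sc <- cwt_haar(c(rep(0, 100), rep(1, 100)), scales = c(8, 16, 32))
#' sc$E > 0
#' @export
cwt_haar <- function(x, scales) {
  if (length(scales) == 0) abort("scales must be a non-empty vector")
  scales <- as.integer(scales)
  if (any(scales <= 0)) abort("scales must be positive")
  if (any(scales %% 2 != 0))
    abort("scales must be even sample counts (Haar half-supports must balance)")
  n <- length(x)
  if (any(scales > n)) abort("scales must not exceed the signal length")
  cs <- c(0, cumsum(x))
  coefs <- matrix(NA_real_, nrow = length(scales), ncol = n,
                  dimnames = list(paste0("a", scales), NULL))
  for (k in seq_along(scales)) {
    a <- scales[k]; h <- a %/% 2L
    p <- seq_len(n - a + 1L)          # left edge of support (1-based)
    s1 <- cs[p + h] - cs[p]           # first half-support
    s2 <- cs[p + a] - cs[p + h]       # second half-support
    coefs[k, p] <- (s1 - s2) / sqrt(a)
  }
  S <- coefs^2
  E <- sum(S, na.rm = TRUE)
  structure(list(coefs = coefs, scales = scales, S = S, E = E, n = n),
            class = "eog_scalogram")
}

#' @export
print.eog_scalogram <- function(x, ...) {
  cat(sprintf("<eog_scalogram> %d scales x %d samples, E = %.4g\n",
              length(x$scales), x$n, x$E))
  invisible(x)
}

# Locate the maximum-|coefficient| position of a scalogram. Returns the event
# center (left support edge + half support, 0-based sample index), the scale,
# and |C| there.
scalogram_peak <- function(sc) {
  A <- abs(sc$coefs)
  if (all(is.na(A))) return(NULL)
  idx <- which(A == max(A, na.rm = TRUE), arr.ind = TRUE)[1, ]
  a <- sc$scales[idx[1]]
  b_left <- idx[2] - 1L                 # 0-based left edge
  list(b_star = b_left + a %/% 2L,      # wavelet transition = event center
       a_star = a,
       c_max = A[idx[1], idx[2]])
}

#' Detect an eye-movement event on the derived pair
#'
#' For each of the two derived signals, computes the Haar scalogram and
#' compares its total energy `E` against the per-signal threshold. Energies
#' are accumulated only over coefficients whose center lies inside the block
#' proper (shifts in any prepended context are excluded), so thresholds
#' calibrated on bare blocks transfer to context-padded detection. If the
#' energy clears the threshold, the event is placed at the position of the
#' maximum absolute wavelet coefficient.
#'
#' @param pair An `eog_pair` from [derive_pair()]; `y1`/`y2` may include
#'   `context_len` samples of the previous block prepended.
#' @param scales Wavelet supports in samples (see [cwt_haar()]).
#' @param energy_threshold Named list with elements `y1` and `y2` (>= 0).
#' @param context_len Number of prepended context samples (default 0).
#' @return A tibble with one row per signal: `signal`, `detected`, `b_star`
#'   (0-based index of the event center, relative to the start of the padded
#'   series; can fall inside the context), `a_star`, `c_max`, `energy`.
#' @examples
#' pr <- derive_pair(rnorm(256), rnorm(256))
#' detect_event(pr, scales = c(8, 16, 32),
#'              energy_threshold = list(y1 = 1e6, y2 = 1e6))
#' @export
detect_event <- function(pair, scales, energy_threshold, context_len = 0L) {
  stopifnot(inherits(pair, "eog_pair"))
  th <- energy_threshold
  if (is.null(th$y1) || is.null(th$y2) || th$y1 < 0 || th$y2 < 0)
    abort("energy_threshold must be a list with non-negative y1 and y2")
  one <- function(x, sig, thr) {
    sc <- cwt_haar(x, scales)
    keep <- block_energy(sc, context_len)
    if (keep < thr)
      return(tibble(signal = sig, detected = FALSE, b_star = NA_integer_,
                    a_star = NA_integer_, c_max = NA_real_, energy = keep))
    pk <- scalogram_peak(sc)
    tibble(signal = sig, detected = TRUE, b_star = as.integer(pk$b_star),
           a_star = as.integer(pk$a_star), c_max = pk$c_max, energy = keep)
  }
  dplyr::bind_rows(one(pair$y1[[1]], "y1", th$y1),
                   one(pair$y2[[1]], "y2", th$y2))
}

# Energy over coefficients whose support center is at or after context_len.
block_energy <- function(sc, context_len = 0L) {
  if (context_len <= 0) return(sc$E)
  tot <- 0
  for (k in seq_along(sc$scales)) {
    a <- sc$scales[k]; h <- a %/% 2L
    centers <- (seq_len(sc$n) - 1L) + h    # center for left edge p-1
    v <- sc$S[k, ]
    tot <- tot + sum(v[centers >= context_len], na.rm = TRUE)
  }
  tot
}
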