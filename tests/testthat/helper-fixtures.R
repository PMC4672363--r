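# Shared fixtures, built in code at test time.

fs_default <- 256

# deterministic two-channel noise recording
noise_recording <- function(n_s = 2, seed = 99, sd = 5, fs = fs_default) {
  set.seed(seed)
  eog_recording(rnorm(n_s * fs, sd = sd), rnorm(n_s * fs, sd = sd),
                sample_rate = fs)
}

# brute-force Haar CWT by direct double-loop summation (independent oracle)
cwt_haar_brute <- function(x, scales) {
  n <- length(x)
  coefs <- matrix(NA_real_, length(scales), n)
  for (k in seq_along(scales)) {
    a <- scales[k]
    psi <- c(rep(1, a / 2), rep(-1, a / 2))
    for (b in 0:(n - a)) {
      acc <- 0
      for (t in 1:a) acc <- acc + x[b + t] * psi[t]
      coefs[k, b + 1] <- acc / sqrt(a)
    }
  }
  coefs
}

# direct convolution moving average with edge truncation (oracle)
ma_brute <- function(x, win) {
  n <- length(x)
  h_lo <- (win - 1) %/% 2
  h_hi <- win - 1 - h_lo
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h_lo):min(n, i + h_hi)
    mean(x[idx])
  }, numeric(1))
}

# whole-record filtering via signal::filter (independent of the package's
# state-carrying implementation)
filter_whole <- function(filt, x) as.numeric(signal::filter(filt, x))

default_thresholds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- eog_config()
      ds <- synth_dataset(5, synth_config(seed = 10))
      cache <<- calibrate_thresholds(dataset_features(ds, cfg), cfg)
    }
    cache
  }
})
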