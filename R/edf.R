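# Minimal EDF (European Data Format) support: continuous recordings, 16-bit
# samples. Covers what a two-channel export of this pipeline needs; not a
# general-purpose EDF library (no EDF+ annotations, no discontinuous files).

parse_edf_header <- function(con) {
  fld <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- fld(8)
  patient <- fld(80)
  recording <- fld(80)
  startdate <- fld(8); starttime <- fld(8)
  header_bytes <- as.integer(fld(8))
  fld(44)  # reserved
  n_records <- as.integer(fld(8))
  record_dur <- as.numeric(fld(8))
  ns <- as.integer(fld(4))
  per <- function(n) vapply(seq_len(ns), function(i) fld(n), character(1))
  labels <- per(16)
  transducer <- per(80)
  dim <- per(8)
  phys_min <- as.numeric(per(8))
  phys_max <- as.numeric(per(8))
  dig_min <- as.numeric(per(8))
  dig_max <- as.numeric(per(8))
  prefilter <- per(80)
  nsamp <- as.integer(per(8))
  per(32)  # reserved
  list(version = version, patient = patient, recording = recording,
       startdate = startdate, starttime = starttime,
       header_bytes = header_bytes, n_records = n_records,
       record_dur = record_dur, ns = ns, labels = labels, dim = dim,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, nsamp = nsamp)
}

# physical-dimension string -> multiplier into microvolts
uV_factor <- function(dim) {
  d <- tolower(trimws(dim))
  if (d %in% c("uv", "µv", "microvolt", "microvolts", "")) return(1)
  if (d %in% c("mv", "millivolt", "millivolts")) return(1000)
  if (d %in% c("v", "volt", "volts")) return(1e6)
  warn(sprintf("unknown EDF physical dimension '%s'; assuming microvolts", dim))
  1
}

read_edf_recording <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- parse_edf_header(con)
  if (is.null(channels)) {
    li <- grep("left", h$labels, ignore.case = TRUE)
    ri <- grep("right", h$labels, ignore.case = TRUE)
    if (length(li) < 1 || length(ri) < 1)
      abort("EDF signal labels do not identify 'left' and 'right'; pass explicit channel indices")
    channels <- c(li[1], ri[1])
  }
  if (length(channels) != 2 || any(channels < 1) || any(channels > h$ns))
    abort("channels must be two valid EDF signal indices (left, right)")
  if (h$nsamp[channels[1]] != h$nsamp[channels[2]])
    abort("left and right EDF signals have different sampling rates")
  fs <- h$nsamp[channels[1]] / h$record_dur

  # digital-to-physical affine per selected signal, converted to microvolts
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  offs <- h$phys_min - gain * h$dig_min
  chunks <- vector("list", h$n_records)
  left <- right <- vector("list", h$n_records)
  for (r in seq_len(h$n_records)) {
    for (s in seq_len(h$ns)) {
      dig <- readBin(con, "integer", n = h$nsamp[s], size = 2,
                     signed = TRUE, endian = "little")
      if (s == channels[1])
        left[[r]] <- (dig * gain[s] + offs[s]) * uV_factor(h$dim[s])
      if (s == channels[2])
        right[[r]] <- (dig * gain[s] + offs[s]) * uV_factor(h$dim[s])
    }
  }
  eog_recording(unlist(left), unlist(right), sample_rate = fs,
                meta = list(source = "edf", patient = h$patient,
                            recording = h$recording))
}

# Internal EDF writer (one record per second, 16-bit), used for round-trip
# tests and for exporting synthetic recordings in a standard container.
write_edf_recording <- function(rec, path, dim = "uV") {
  stopifnot(inherits(rec, "eog_recording"))
  fs <- sample_rate(rec)
  if (fs != round(fs)) abort("EDF export requires an integer sample rate")
  nb <- nrow(rec) %/% fs
  if (nb < 1) abort("recording shorter than one EDF record")
  n <- nb * fs
  sig <- list(left = rec$left_uV[1:n], right = rec$right_uV[1:n])
  rng <- range(unlist(sig))
  phys_lo <- floor(rng[1]) - 1; phys_hi <- ceiling(rng[2]) + 1
  dmin <- -32768; dmax <- 32767
  gain <- (phys_hi - phys_lo) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) {
    s <- sprintf(paste0("%-", w, "s"), substr(as.character(x), 1, w))
    writeChar(s, con, eos = NULL)
  }
  put("0", 8); put("X X X X", 80); put("synthetic eogbci export", 80)
  put("01.01.26", 8); put("00.00.00", 8)
  put(256 + 2 * 256, 8); put("", 44); put(nb, 8); put("1", 8); put(2, 4)
  put("EEG left", 16); put("EEG right", 16)
  put("", 80); put("", 80)
  put(dim, 8); put(dim, 8)
  put(phys_lo, 8); put(phys_lo, 8)
  put(phys_hi, 8); put(phys_hi, 8)
  put(dmin, 8); put(dmin, 8)
  put(dmax, 8); put(dmax, 8)
  put("", 80); put("", 80)
  put(fs, 8); put(fs, 8)
  put("", 32); put("", 32)
  for (r in seq_len(nb)) {
    for (ch in c("left", "right")) {
      x <- sig[[ch]][((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((x - phys_lo) / gain + dmin))
      dig <- as.integer(pmax(pmin(dig, dmax), dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
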