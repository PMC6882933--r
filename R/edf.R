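# Minimal EDF (European Data Format) I/O: 16-bit little-endian samples,
# ASCII headers, one data record holding the whole recording. Covers what
# the package needs for biosignal exchange; not a general-purpose EDF
# implementation (no annotations, no EDF+).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF header field too wide: '%s'", x))
  formatC(x, width = -width)
}

# format a number into <= 8 ascii chars, shrinking precision as needed
edf_num8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(signif(x, digits), format = "g", digits = digits)
    if (nchar(s) <= 8) return(s)
  }
  stop(sprintf("cannot format %g into 8 characters", x))
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  dur <- edf_num8(n / rec$rate)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44)
  wr(1, 8)           # one data record spanning the recording
  wr(dur, 8)
  wr(ns, 4)

  rng <- apply(rec$samples, 1, range)
  pmin <- rng[1, ]; pmax <- rng[2, ]
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # encode with the truncated values the header will carry
  pmin_s <- vapply(pmin, edf_num8, character(1))
  pmax_s <- vapply(pmax, edf_num8, character(1))
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  pmax <- pmax + (pmax <= pmin)  # guard against truncation collapse
  dmin <- -32768; dmax <- 32767

  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(pmin_s[i], 8)
  for (i in seq_len(ns)) wr(edf_num8(pmax[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (pmax - pmin) / (dmax - dmin)
  for (i in seq_len(ns)) {
    dig <- round((rec$samples[i, ] - pmin[i]) / scale[i]) + dmin
    dig <- as.integer(pmin(pmax(dig, dmin), dmax))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rdn <- function(width) as.numeric(rd(width))
  version <- rd(8)
  if (version != "0") stop(sprintf("parse error in %s: not an EDF file", path))
  rd(80); rd(80); rd(8); rd(8)
  rdn(8); rd(44)
  n_rec <- rdn(8)
  rec_dur <- rdn(8)
  ns <- as.integer(rdn(4))
  if (is.na(ns) || ns < 1) stop(sprintf("parse error in %s: bad signal count", path))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  for (i in seq_len(ns)) rd(80)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rdn(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  scale <- (pmax - pmin) / (dmax - dmin)
  out <- matrix(0, ns, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < nsamp[i]) {
        stop(sprintf("parse error in %s: truncated data record %d", path, r))
      }
      out[i, (r - 1) * nsamp[i] + seq_len(nsamp[i])] <-
        pmin[i] + (dig - dmin[i]) * scale[i]
    }
  }
  rate <- nsamp[1] / rec_dur
  recording(out, rate = rate, channel_labels = labels)
}
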