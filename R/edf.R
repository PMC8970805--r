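# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a fixed-width ASCII header followed by 16-bit little-endian
# samples, grouped into fixed-duration data records. A trial set maps onto the
# format as one data record per trial; class labels ride on an extra "TRIG"
# status channel (one sample per record), a common convention for paradigm
# triggers. Amplitudes are quantized to the 16-bit digital range, so round
# trips are exact only to quantization precision.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

write_edf <- function(ts, path) {
  d <- dim(ts$data)
  n_trials <- d[1]; m <- d[2]; nsamp <- d[3]
  ns <- m + 1L  # EEG channels + TRIG
  con <- tryCatch(file(path, "wb"), error = function(e)
    mi_stop("io", "cannot open '%s' for writing", path))
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_ascii(x, width), con, eos = NULL)

  phys_min <- phys_max <- numeric(m)
  for (ch in seq_len(m)) {
    r <- max(abs(ts$data[, ch, ]), 1e-6)
    phys_max[ch] <- r; phys_min[ch] <- -r
  }
  header_bytes <- 256L + 256L * ns

  wr("0", 8)                                  # version
  wr("synthetic MI-EEG", 80)                  # patient id
  wr("miclass trial export", 80)              # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)        # start date/time
  wr(header_bytes, 8)
  wr("", 44)
  wr(n_trials, 8)
  wr(format(ts$trial_duration, trim = TRUE), 8)
  wr(ns, 4)

  labels16 <- c(ts$channel_names, "TRIG")
  for (lab in labels16) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)                         # transducer
  for (i in seq_len(ns)) wr(if (i <= m) "uV" else "", 8)    # physical dim
  for (i in seq_len(ns)) wr(if (i <= m) format(signif(phys_min[i], 7)) else "0", 8)
  for (i in seq_len(ns)) wr(if (i <= m) format(signif(phys_max[i], 7)) else "1", 8)
  for (i in seq_len(ns)) wr(if (i <= m) "-32768" else "0", 8)
  for (i in seq_len(ns)) wr(if (i <= m) "32767" else "1", 8)
  for (i in seq_len(ns)) wr("", 80)                         # prefiltering
  for (i in seq_len(ns)) wr(if (i <= m) nsamp else 1L, 8)   # samples/record
  for (i in seq_len(ns)) wr("", 32)

  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(m)) {
      x <- ts$data[tr, ch, ]
      dig <- round((x - phys_min[ch]) / (phys_max[ch] - phys_min[ch]) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2L, endian = "little")
    }
    writeBin(as.integer(ts$labels[tr]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) mi_stop("format", "not a parseable EDF header")

  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  trig <- which(labels == "TRIG")
  eeg <- setdiff(seq_len(ns), trig)
  if (length(eeg) < 1) mi_stop("channels", "EDF holds no EEG channels")
  nsamp <- spr[eeg[1]]
  if (!all(spr[eeg] == nsamp))
    mi_stop("channels", "EEG channels disagree on samples per record")

  data <- array(0, dim = c(n_rec, length(eeg), nsamp))
  labs <- integer(n_rec)
  for (tr in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little", signed = TRUE)
      if (i %in% eeg) {
        ch <- match(i, eeg)
        g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
        data[tr, ch, ] <- (raw - dig_min[i]) * g + phys_min[i]
      } else {
        labs[tr] <- as.integer(round(mean(raw)))
      }
    }
  }
  if (length(trig) == 0)
    mi_stop("labels", "EDF lacks a TRIG label channel")
  eeg_trial_set(data, labs, nsamp / rec_dur, labels[eeg], rec_dur)
}
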