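# Trial-set I/O: rds (R-native named arrays), long-format CSV with a label
# sidecar, and EDF (see edf.R for the low-level format code).

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         rds = "rds", csv = "csv", edf = "edf",
         mi_stop("format", "cannot infer trial format from extension '%s'", ext))
}

#' Write a trial set to disk
#'
#' Formats: `"rds"` (named list: data, labels, fs, channels, trial_duration —
#' exact round-trip), `"csv"` (long format with columns trial, channel,
#' sample_index, value plus a `<path>.labels.csv` sidecar holding trial, label,
#' fs, duration), and `"edf"` (European Data Format; 16-bit quantized, labels
#' carried on an extra TRIG status channel, one data record per trial).
#'
#' @param ts An [eeg_trial_set()].
#' @param path Output file path.
#' @param format One of `"rds"`, `"csv"`, `"edf"`; inferred from the file
#'   extension when omitted.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ts, path, format = infer_format(path)) {
  if (!inherits(ts, "eeg_trial_set"))
    mi_stop("config", "ts must be an eeg_trial_set")
  if (dim(ts$data)[1] == 0L)
    mi_stop("empty", "refusing to write an empty trial set")
  format <- match.arg(format, c("rds", "csv", "edf"))
  switch(format,
    rds = saveRDS(list(data = ts$data, labels = ts$labels, fs = ts$fs,
                       channels = ts$channel_names,
                       trial_duration = ts$trial_duration), path),
    csv = write_trials_csv(ts, path),
    edf = write_edf(ts, path))
  invisible(path)
}

#' Read a trial set from disk
#'
#' Inverse of [write_trials()]; see there for the dialects.
#'
#' @param path File path.
#' @param format One of `"rds"`, `"csv"`, `"edf"`; inferred from the extension
#'   when omitted.
#' @return An [eeg_trial_set()].
#' @export
read_trials <- function(path, format = infer_format(path)) {
  if (!file.exists(path)) mi_stop("io", "file not found: %s", path)
  format <- match.arg(format, c("rds", "csv", "edf"))
  switch(format,
    rds = {
      x <- readRDS(path)
      need <- c("data", "labels", "fs", "channels")
      if (!all(need %in% names(x)))
        mi_stop("format", "rds trial file missing fields: %s",
                paste(setdiff(need, names(x)), collapse = ", "))
      eeg_trial_set(x$data, x$labels, x$fs, x$channels,
                    x$trial_duration %||% (dim(x$data)[3] / x$fs))
    },
    csv = read_trials_csv(path),
    edf = read_edf(path))
}

write_trials_csv <- function(ts, path) {
  d <- dim(ts$data)
  long <- data.table::data.table(
    trial = rep(seq_len(d[1]), each = d[2] * d[3]),
    channel = rep(rep(ts$channel_names, each = d[3]), times = d[1]),
    sample_index = rep(seq_len(d[3]), times = d[1] * d[2]),
    value = as.vector(aperm(ts$data, c(3, 2, 1))))
  data.table::fwrite(long, path)
  side <- data.table::data.table(trial = seq_len(d[1]), label = ts$labels,
                                 fs = ts$fs, duration = ts$trial_duration)
  data.table::fwrite(side, paste0(path, ".labels.csv"))
  invisible(path)
}

read_trials_csv <- function(path) {
  long <- data.table::fread(path)
  need <- c("trial", "channel", "sample_index", "value")
  if (!all(need %in% names(long)))
    mi_stop("format", "trial CSV missing columns: %s",
            paste(setdiff(need, names(long)), collapse = ", "))
  side_path <- paste0(path, ".labels.csv")
  if (!file.exists(side_path))
    mi_stop("labels", "label sidecar not found: %s", side_path)
  side <- data.table::fread(side_path)
  if (!"label" %in% names(side))
    mi_stop("labels", "label sidecar lacks a 'label' column")
  channels <- unique(long$channel)
  trials <- sort(unique(long$trial))
  n <- max(long$sample_index)
  data.table::setorderv(long, c("trial", "channel", "sample_index"))
  # order channels by first appearance, not alphabetically
  long[, channel := factor(channel, levels = channels)]
  data.table::setorderv(long, c("trial", "channel", "sample_index"))
  arr <- aperm(array(long$value, dim = c(n, length(channels), length(trials))),
               c(3, 2, 1))
  side <- side[order(side$trial), ]
  eeg_trial_set(arr, side$label, side$fs[1], channels,
                if ("duration" %in% names(side)) side$duration[1] else n / side$fs[1])
}
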