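#' Read a recording from disk
#'
#' Supports two formats: EDF (European Data Format, 16-bit) and a CSV
#' dialect with one header row of channel labels followed by one row per
#' time sample, values in microvolts.
#'
#' @param path File path.
#' @param format `"edf"` or `"csv"`; inferred from the extension when
#'   `NULL`.
#' @param rate Sampling rate in Hz for CSV input (EDF carries its own).
#' @return A [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = NULL, rate = 250) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- format %||% infer_format(path)
  switch(format,
    csv = read_recording_csv(path, rate),
    edf = read_edf(path),
    stop(sprintf("unknown recording format '%s'", format))
  )
}

#' Write a recording to disk
#'
#' @param rec A [recording()].
#' @param path File path.
#' @param format `"edf"` or `"csv"`; inferred from the extension when
#'   `NULL`. CSV preserves samples to full double precision; EDF quantizes
#'   to 16 bits over the per-channel physical range.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "bci_recording"))
  format <- format %||% infer_format(path)
  switch(format,
    csv = {
      df <- as.data.frame(t(rec$samples))
      names(df) <- rec$channel_labels
      utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    },
    edf = write_edf(rec, path),
    stop(sprintf("unknown recording format '%s'", format))
  )
  invisible(path)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("edf", "csv")) ext else
    stop(sprintf("cannot infer format from extension '.%s'", ext))
}

read_recording_csv <- function(path, rate) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s", path,
                                     conditionMessage(e)))
  )
  if (ncol(df) < 1 || nrow(df) < 1) {
    stop(sprintf("parse error in %s: no data rows", path))
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop(sprintf("parse error in %s: non-numeric column(s) %s",
                 path, paste(bad, collapse = ", ")))
  }
  recording(t(as.matrix(df)), rate = rate, channel_labels = names(df))
}

#' Re-reference a recording
#'
#' Subtracts the reference channel from every other channel samplewise and
#' drops the reference channel, the standard monopolar-to-referenced step
#' (the hardware montage references scalp channels against the right ear
#' lobe, A2).
#'
#' @param rec A [recording()].
#' @param ref_label Reference channel label (default `"A2"`).
#' @return A [recording()] without the reference channel.
#' @export
rereference <- function(rec, ref_label = REF_CHANNEL) {
  stopifnot(inherits(rec, "bci_recording"))
  if (!ref_label %in% rec$channel_labels) {
    stop(sprintf("montage error: reference channel '%s' not present",
                 ref_label))
  }
  ref <- rec$samples[ref_label, ]
  keep <- setdiff(rec$channel_labels, ref_label)
  out <- rec$samples[keep, , drop = FALSE]
  out <- sweep(out, 2, ref, "-")
  recording(out, rec$rate, keep, rec$start_time)
}

#' Band-pass filter a recording
#'
#' 4th-order Butterworth band-pass over the mu/beta band (8-30 Hz by
#' default, the rhythms modulated by motor imagery). Offline mode filters
#' forward-backward for zero phase; online mode is a single causal pass
#' suitable for streaming.
#'
#' @param rec A [recording()].
#' @param lo,hi Band edges in Hz; `0 < lo < hi < rate/2`.
#' @param mode `"offline_zero_phase"` (default) or `"online_causal"`.
#' @param order Butterworth order (default 4).
#' @return A filtered [recording()].
#' @export
bandpass <- function(rec, lo = 8, hi = 30,
                     mode = c("offline_zero_phase", "online_causal"),
                     order = 4) {
  stopifnot(inherits(rec, "bci_recording"))
  mode <- match.arg(mode)
  nyq <- rec$rate / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    stop(sprintf("invalid band [%g, %g] Hz for rate %g Hz", lo, hi, rec$rate))
  }
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  filt_fun <- if (mode == "offline_zero_phase") {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- t(apply(rec$samples, 1, filt_fun))
  recording(out, rec$rate, rec$channel_labels, rec$start_time)
}

#' Create a labeled motor-imagery trial
#'
#' @param X Numeric matrix, channels x samples, band-passed microvolts.
#' @param label `"left"` or `"right"`.
#' @return An object of class `bci_trial`.
#' @export
labeled_trial <- function(X, label = c("left", "right")) {
  label <- match.arg(label)
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("trial must contain at least one sample")
  structure(list(X = X, label = label), class = "bci_trial")
}

#' @export
print.bci_trial <- function(x, ...) {
  cat(sprintf("<bci_trial> %s, %d channels x %d samples\n",
              x$label, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Cut cue-locked trials out of a continuous recording
#'
#' One trial per `cue_left` / `cue_right` event; the window is
#' half-open `[onset + offset, onset + offset + length)` so a trial holds
#' exactly `round(length * rate)` samples.
#'
#' @param rec A [recording()] (typically already referenced and
#'   band-passed).
#' @param events A [event_table()] containing cue events.
#' @param offset Window start relative to the cue onset, seconds.
#' @param length Window length, seconds (default 5, the imagery period).
#' @return A list of [labeled_trial()] objects.
#' @export
extract_trials <- function(rec, events, offset = 0, length = 5) {
  stopifnot(inherits(rec, "bci_recording"))
  cues <- events[events$kind %in% c("cue_left", "cue_right"), , drop = FALSE]
  if (nrow(cues) == 0) return(list())
  n <- round(length * rec$rate)
  start_idx <- round((cues$onset_s - rec$start_time + offset) * rec$rate) + 1
  end_idx <- start_idx + n - 1
  bad <- which(start_idx < 1 | end_idx > ncol(rec$samples))
  if (base::length(bad)) {
    stop(sprintf("trial window out of bounds for event(s) at t = %s s",
                 paste(signif(cues$onset_s[bad], 6), collapse = ", ")))
  }
  purrr::map(seq_len(nrow(cues)), function(i) {
    labeled_trial(
      rec$samples[, start_idx[i]:end_idx[i], drop = FALSE],
      label = if (cues$kind[i] == "cue_left") "left" else "right"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
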