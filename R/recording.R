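#' Default scalp montage
#'
#' The nine sensorimotor EEG channels, the forehead EOG channel, and the
#' right-ear reference used throughout the package.
#'
#' @format Character vectors of channel labels.
#' @name montage
NULL

#' @rdname montage
#' @export
EEG_CHANNELS <- c("FC3", "FCz", "FC4", "C3", "Cz", "C4", "CP3", "CPz", "CP4")

#' @rdname montage
#' @export
EOG_CHANNEL <- "FP2"

#' @rdname montage
#' @export
REF_CHANNEL <- "A2"

#' Create a multichannel recording
#'
#' A `bci_recording` holds a channels-by-time matrix of samples in
#' microvolts together with its sampling rate and channel labels. This is
#' the raw-signal container that every downstream step (referencing,
#' filtering, epoching, online scoring) consumes.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param rate Sampling rate in Hz (default 250).
#' @param channel_labels Character vector of unique channel identifiers,
#'   one per row of `samples`.
#' @param start_time Recording start in seconds (default 0).
#'
#' @return An object of class `bci_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(500), 2, 250),
#'                  channel_labels = c("C3", "C4"))
#' duration(rec)
#' @export
recording <- function(samples, rate = 250, channel_labels = rownames(samples),
                      start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("`samples` must be a numeric matrix")
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples)) {
    stop("one channel label per row of `samples` is required")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("`rate` must be a single positive number")
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, rate = rate, channel_labels = channel_labels,
         start_time = start_time),
    class = "bci_recording"
  )
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, duration(x)))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A `bci_recording`.
#' @return Duration in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "bci_recording"))
  ncol(rec$samples) / rec$rate
}

#' Extract one channel as a numeric vector
#' @param rec A `bci_recording`.
#' @param label Channel label.
#' @return Numeric vector of samples.
#' @export
channel <- function(rec, label) {
  stopifnot(inherits(rec, "bci_recording"))
  if (!label %in% rec$channel_labels) {
    stop(sprintf("montage error: channel '%s' not present", label))
  }
  rec$samples[label, ]
}

#' Keep a subset of channels
#' @param rec A `bci_recording`.
#' @param labels Channel labels to keep, in the order given.
#' @return A `bci_recording` restricted to `labels`.
#' @export
select_channels <- function(rec, labels) {
  stopifnot(inherits(rec, "bci_recording"))
  missing <- setdiff(labels, rec$channel_labels)
  if (length(missing)) {
    stop(sprintf("montage error: missing channel(s): %s",
                 paste(missing, collapse = ", ")))
  }
  recording(rec$samples[labels, , drop = FALSE], rec$rate, labels,
            rec$start_time)
}

#' Convert a recording to a long tibble
#'
#' One row per (channel, sample) with the sample time in seconds, ready for
#' dplyr/ggplot2 pipelines.
#'
#' @param x A `bci_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `channel`, `value_uV`.
#' @method tidy bci_recording
#' @export
tidy.bci_recording <- function(x, ...) {
  t <- x$start_time + (seq_len(ncol(x$samples)) - 1) / x$rate
  tibble::tibble(
    time_s = rep(t, each = nrow(x$samples)),
    channel = rep(x$channel_labels, times = ncol(x$samples)),
    value_uV = as.vector(x$samples)
  )
}

#' Plot a recording as stacked channel traces
#'
#' @param object A `bci_recording`.
#' @param ... Unused.
#' @return A ggplot object, channels facetted in montage order.
#' @method autoplot bci_recording
#' @export
autoplot.bci_recording <- function(object, ...) {
  df <- tidy.bci_recording(object)
  df$channel <- factor(df$channel, levels = object$channel_labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value_uV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = expression(paste("amplitude (", mu, "V)")))
}

#' Create an event table
#'
#' Events mark cue onsets, button flashes, ground-truth ocular events and
#' emitted commands on the recording timeline.
#'
#' @param onset_s Numeric vector of onsets in seconds, non-decreasing.
#' @param kind Character vector: one of `cue_left`, `cue_right`, `flash`,
#'   `blink_truth`, `eyebrow_truth`, `command`.
#' @param label Character vector of free-text labels (button ids, classes).
#' @return A tibble of class `bci_events` with columns
#'   `onset_s`, `kind`, `label`.
#' @export
event_table <- function(onset_s = numeric(), kind = character(),
                        label = character()) {
  kinds <- c("cue_left", "cue_right", "flash", "blink_truth",
             "eyebrow_truth", "command")
  if (length(label) == 0 && length(onset_s) > 0) label <- rep("", length(onset_s))
  bad <- setdiff(unique(kind), kinds)
  if (length(bad)) {
    stop(sprintf("unknown event kind(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.unsorted(onset_s)) stop("event onsets must be non-decreasing")
  out <- tibble::tibble(onset_s = as.numeric(onset_s),
                        kind = as.character(kind),
                        label = as.character(label))
  class(out) <- c("bci_events", class(out))
  out
}

#' Read / write an event table as TSV
#'
#' The on-disk dialect is a tab-separated file with header
#' `onset_s  kind  label`.
#'
#' @param path File path.
#' @return `read_events()` returns a `bci_events` tibble;
#'   `write_events()` returns `path` invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("numeric", "character", "character"))
  if (!identical(names(df), c("onset_s", "kind", "label"))) {
    stop(sprintf("parse error in %s: expected header onset_s\tkind\tlabel", path))
  }
  event_table(df$onset_s, df$kind, df$label)
}

#' @rdname read_events
#' @param events A `bci_events` tibble.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
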