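#' Detect eyebrow-raise events across a stream
#'
#' Slides a window over the EOG channel, applies the duration-based
#' eyebrow check, and deduplicates overlapping detections of the same
#' raise.
#'
#' @param stream A [recording()] with the EOG channel.
#' @param p An [eog_params()].
#' @param channel EOG channel label (ignored for single-channel streams).
#' @param window Analysis window, seconds (must exceed the longest
#'   expected raise).
#' @param hop Window hop, seconds.
#' @return A tibble with column `peak_s`.
#' @export
detect_eyebrow_events <- function(stream, p, channel = EOG_CHANNEL,
                                  window = 1.2, hop = 0.1) {
  x <- if (nrow(stream$samples) == 1) stream$samples[1, ]
       else channel(stream, channel)
  rate <- stream$rate
  win_n <- round(window * rate)
  starts <- seq(0, duration(stream) - window, by = hop)
  peaks <- purrr::map_dbl(starts, function(t0) {
    i0 <- round(t0 * rate) + 1
    seg <- x[i0:(i0 + win_n - 1)]
    if (!detect_eyebrow_raise(seg, p, rate)) return(NA_real_)
    # timestamp by the centre of the above-half-peak run: the raw maximum
    # of a noisy plateau wanders, the run centre does not
    run <- half_peak_run(seg, which.max(seg), rate)
    t0 + ((run$lo + run$hi) / 2 - 1) / rate
  })
  peaks <- sort(unique(peaks[!is.na(peaks)]))
  if (length(peaks) > 1) {
    peaks <- peaks[c(TRUE, diff(peaks) > 0.2)]
  }
  tibble::tibble(peak_s = peaks)
}

#' Replay an EOG stream through the full selection pipeline
#'
#' Detects blinks on the flash-epoch grid, attributes intended blinks to
#' buttons, detects eyebrow raises, and folds the time-ordered event
#' sequence through the preselect-verify-command state machine. This is
#' the software path a live session exercises, minus the screen.
#'
#' @param stream Single-channel EOG [recording()].
#' @param schedule A [build_schedule()].
#' @param p An [eog_params()].
#' @param timeout Verification timeout, seconds (default 3).
#' @return A list with `commands` (tibble `t_s`, `command`, `accepted`,
#'   `reason`), `blinks` and `eyebrows` (the detection tibbles).
#' @export
run_selection <- function(stream, schedule, p = eog_params(), timeout = 3) {
  blinks <- detect_blinks(stream, schedule, p)
  eyebrows <- detect_eyebrow_events(stream, p)
  intended <- blinks[blinks$intended, , drop = FALSE]
  evs <- dplyr::bind_rows(
    tibble::tibble(time = intended$peak_s, type = "intended_blink",
                   button = vapply(intended$flash_onset_s, button_at,
                                   character(1), schedule = schedule)),
    tibble::tibble(time = eyebrows$peak_s, type = "eyebrow",
                   button = NA_character_)
  )
  evs <- dplyr::arrange(evs, .data$time)
  state <- selection_state()
  out <- list()
  for (i in seq_len(nrow(evs))) {
    res <- selection_step(state,
                          list(type = evs$type[i], time = evs$time[i],
                               button = evs$button[i]),
                          timeout = timeout)
    state <- res$state
    if (!is.null(res$command)) {
      out[[length(out) + 1]] <- tibble::tibble(
        t_s = evs$time[i], command = res$command,
        accepted = TRUE, reason = ""
      )
    }
  }
  commands <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(t_s = numeric(), command = character(),
                   accepted = logical(), reason = character())
  list(commands = commands, blinks = blinks, eyebrows = eyebrows)
}

#' Write a command log as TSV
#'
#' @param commands Tibble from [run_selection()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_command_log <- function(commands, path) {
  utils::write.table(as.data.frame(commands), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
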