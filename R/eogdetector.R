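#' Blink / eyebrow detection parameters
#'
#' The multi-threshold waveform check decides whether a 600-ms EOG epoch
#' contains a blink at all (amplitude, slope and duration gates); the
#' intended-blink gate then checks the flash-to-peak latency against a
#' per-user delay window and the peak against the higher intended
#' amplitude threshold `TH_a`. Numeric defaults are calibration choices,
#' not physiological constants; all are per-user configurable.
#'
#' @param amp_min Minimum peak amplitude for any blink, microvolts.
#' @param slope_min Minimum peak first-difference magnitude,
#'   microvolts/sample.
#' @param dur_range Allowed above-half-peak deflection duration, seconds.
#' @param TH_a Intended-blink amplitude threshold, microvolts
#'   (`>= amp_min`).
#' @param delay_window Allowed flash-to-peak latency, seconds (default
#'   280-320 ms; calibrate per user with [calibrate_delay_window()]).
#' @param eyebrow_amp Minimum eyebrow-raise amplitude, microvolts.
#' @param eyebrow_dur_min Minimum eyebrow deflection duration, seconds;
#'   must exceed `dur_range[2]` so duration separates the two movements.
#' @param positive_polarity Blinks deflect positive at the forehead
#'   electrode; set `FALSE` for inverted montages.
#' @return A list of class `eog_params`.
#' @export
eog_params <- function(amp_min = 100, slope_min = 5,
                       dur_range = c(0.1, 0.4), TH_a = 200,
                       delay_window = c(0.28, 0.32),
                       eyebrow_amp = 200, eyebrow_dur_min = 0.4,
                       positive_polarity = TRUE) {
  if (!(TH_a >= amp_min && amp_min > 0)) stop("need TH_a >= amp_min > 0")
  if (diff(dur_range) <= 0) stop("dur_range must be a non-empty interval")
  if (diff(delay_window) <= 0) stop("delay_window must have positive width")
  if (eyebrow_dur_min < dur_range[2]) {
    stop("eyebrow_dur_min must be at least the blink duration maximum")
  }
  structure(
    list(amp_min = amp_min, slope_min = slope_min, dur_range = dur_range,
         TH_a = TH_a, delay_window = delay_window, eyebrow_amp = eyebrow_amp,
         eyebrow_dur_min = eyebrow_dur_min,
         positive_polarity = positive_polarity),
    class = "eog_params"
  )
}

# above-half-peak run around sample `peak_i`: sample bounds and duration
half_peak_run <- function(x, peak_i, rate) {
  half <- x[peak_i] / 2
  lo <- peak_i
  while (lo > 1 && x[lo - 1] >= half) lo <- lo - 1
  hi <- peak_i
  while (hi < length(x) && x[hi + 1] >= half) hi <- hi + 1
  list(lo = lo, hi = hi, duration = (hi - lo + 1) / rate)
}

half_peak_duration <- function(x, peak_i, rate) {
  half_peak_run(x, peak_i, rate)$duration
}

#' Multi-threshold blink waveform check on one epoch
#'
#' Examines one 600-ms EOG epoch (150 samples at 250 Hz) for a blink
#' waveform, intended or not. A blink is present iff the global peak
#' reaches `amp_min`, the maximum absolute first difference reaches
#' `slope_min` (rules out slow drifts), and the above-half-peak duration
#' falls inside `dur_range` (rules out both spikes and sustained
#' deflections).
#'
#' @param epoch Numeric vector of EOG samples, exactly
#'   `round(0.6 * rate)` long, microvolts.
#' @param p An [eog_params()].
#' @param rate Sampling rate in Hz (default 250).
#' @param epoch_start Absolute time of the first sample, seconds (used to
#'   timestamp the peak).
#' @return A one-row tibble (`peak_s`, `amp_uV`, `duration_s`, `intended`,
#'   `flash_onset_s`) or `NULL` when no blink is present.
#' @export
waveform_check <- function(epoch, p, rate = 250, epoch_start = 0) {
  expected <- round(0.6 * rate)
  if (length(epoch) != expected) {
    stop(sprintf("epoch must hold %d samples (600 ms at %g Hz), got %d",
                 expected, rate, length(epoch)))
  }
  x <- if (p$positive_polarity) epoch else -epoch
  peak_i <- which.max(x)
  if (x[peak_i] < p$amp_min) return(NULL)
  if (max(abs(diff(x))) < p$slope_min) return(NULL)
  run <- half_peak_run(x, peak_i, rate)
  # a run clipped at the epoch boundary has an unknown true duration (a
  # longer deflection, e.g. an eyebrow raise, sliced by the epoch grid);
  # the neighbouring epochs see the full waveform, so reject here
  if (run$lo == 1 || run$hi == length(x)) return(NULL)
  dur <- run$duration
  if (dur < p$dur_range[1] || dur > p$dur_range[2]) return(NULL)
  tibble::tibble(
    peak_s = epoch_start + (peak_i - 1) / rate,
    amp_uV = x[peak_i],
    duration_s = dur,
    intended = FALSE,
    flash_onset_s = NA_real_
  )
}

#' Intended-blink gate
#'
#' A detected blink counts as intended iff its flash-to-peak latency lies
#' inside the calibrated delay window AND its peak strictly exceeds the
#' intended amplitude threshold `TH_a`.
#'
#' @param ev One-row blink tibble from [waveform_check()].
#' @param flash_onset Onset of the candidate flash, seconds.
#' @param p An [eog_params()].
#' @return The event with `intended` and `flash_onset_s` filled in.
#' @export
classify_intended <- function(ev, flash_onset, p) {
  lat <- ev$peak_s - flash_onset
  # window bounds inclusive, with a tolerance well under one sample so
  # floating-point representation of the grid cannot flip the decision
  ev$intended <- lat >= p$delay_window[1] - 1e-9 &
    lat <= p$delay_window[2] + 1e-9 &
    ev$amp_uV > p$TH_a
  ev$flash_onset_s <- flash_onset
  ev
}

#' Calibrate the flash-to-peak delay window for one user
#'
#' Blink response latency varies between users but is stable within one,
#' so the window is centered on the median observed latency with a fixed
#' width (default 40 ms, matching the canonical 280-320 ms example).
#'
#' @param flash_onsets,peak_times Paired vectors of flash onsets and
#'   ground-truth blink peaks, seconds; at least 5 pairs.
#' @param width Window width in seconds (default 0.04).
#' @return Length-2 numeric `c(lo, hi)` in seconds.
#' @export
calibrate_delay_window <- function(flash_onsets, peak_times, width = 0.04) {
  if (length(flash_onsets) != length(peak_times)) {
    stop("flash_onsets and peak_times must be paired")
  }
  if (length(flash_onsets) < 5) {
    stop("calibration error: at least 5 training pairs are required")
  }
  med <- stats::median(peak_times - flash_onsets)
  c(med - width / 2, med + width / 2)
}

#' Detect an eyebrow-raise in an EOG segment
#'
#' Same gate family as the blink check (amplitude, slope via the blink
#' slope threshold, duration), but the discriminating feature is duration:
#' an eyebrow raise is a sustained deflection longer than any blink is
#' allowed to be.
#'
#' @param segment Numeric vector of EOG samples, microvolts.
#' @param p An [eog_params()].
#' @param rate Sampling rate in Hz (default 250).
#' @return `TRUE` iff the segment contains an eyebrow-raise deflection.
#' @export
detect_eyebrow_raise <- function(segment, p, rate = 250) {
  if (length(segment) < round(p$eyebrow_dur_min * rate)) {
    stop("segment shorter than the minimum eyebrow duration")
  }
  x <- if (p$positive_polarity) segment else -segment
  peak_i <- which.max(x)
  if (x[peak_i] < p$eyebrow_amp) return(FALSE)
  half_peak_duration(x, peak_i, rate) > p$eyebrow_dur_min
}

#' Detect blinks across a stream on the flash-epoch grid
#'
#' Runs the waveform check on one 600-ms epoch per flash onset (the epoch
#' starts at the flash), applies the intended gate against that flash, and
#' merges duplicate detections of the same physical blink (peaks within
#' `merge_window` of each other) into one event — an intended
#' classification from any contributing epoch wins.
#'
#' @param stream A [recording()] containing the EOG channel.
#' @param schedule A [build_schedule()] flash schedule.
#' @param p An [eog_params()].
#' @param channel EOG channel label (default `"FP2"`; ignored when the
#'   stream has a single channel).
#' @param merge_window Peak-merging window in seconds (default 0.05).
#' @return A tibble of blink events, one row per physical blink.
#' @export
detect_blinks <- function(stream, schedule, p, channel = EOG_CHANNEL,
                          merge_window = 0.05) {
  stopifnot(inherits(stream, "bci_recording"))
  x <- if (nrow(stream$samples) == 1) stream$samples[1, ]
       else channel(stream, channel)
  rate <- stream$rate
  n_epoch <- round(0.6 * rate)
  onsets <- flash_onsets(schedule, duration(stream))
  onsets <- onsets[onsets + 0.6 <= duration(stream) + 1e-9]
  events <- purrr::map(onsets, function(on) {
    i0 <- round(on * rate) + 1
    ep <- x[i0:(i0 + n_epoch - 1)]
    ev <- waveform_check(ep, p, rate = rate, epoch_start = on)
    if (is.null(ev)) return(NULL)
    classify_intended(ev, on, p)
  })
  events <- dplyr::bind_rows(events)
  if (nrow(events) == 0) {
    return(tibble::tibble(peak_s = numeric(), amp_uV = numeric(),
                          duration_s = numeric(), intended = logical(),
                          flash_onset_s = numeric()))
  }
  events <- dplyr::arrange(events, .data$peak_s)
  grp <- cumsum(c(TRUE, diff(events$peak_s) > merge_window))
  merge_group <- function(g) {
    best <- which.max(g$amp_uV)
    hit <- which(g$intended)
    tibble::tibble(
      peak_s = g$peak_s[best],
      amp_uV = g$amp_uV[best],
      duration_s = g$duration_s[best],
      intended = length(hit) > 0,
      flash_onset_s = if (length(hit)) g$flash_onset_s[hit[1]]
                      else g$flash_onset_s[1]
    )
  }
  events |>
    split(grp) |>
    purrr::map(merge_group) |>
    dplyr::bind_rows()
}

#' False positive rate of intended-blink detection
#'
#' Counts blinks classified as intended over an idle stream (no scripted
#' selections) per minute, before the eyebrow verification stage — the
#' pre-verification FPR that the verification step then suppresses.
#'
#' @param idle_stream A [recording()] of idle-state EOG, at least 1 min.
#' @param schedule A [build_schedule()] flash schedule.
#' @param p An [eog_params()].
#' @param ... Passed to [detect_blinks()].
#' @return Intended-blink detections per minute.
#' @export
false_positive_rate <- function(idle_stream, schedule, p, ...) {
  mins <- duration(idle_stream) / 60
  if (mins < 1) stop("idle stream must be at least one minute long")
  ev <- detect_blinks(idle_stream, schedule, p, ...)
  sum(ev$intended) / mins
}

#' Write detected blink events as TSV
#'
#' @param events Tibble from [detect_blinks()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_blink_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
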