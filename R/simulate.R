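#' Synthetic motor-imagery EEG parameters
#'
#' The generator emulates lateralized event-related desynchronization
#' (ERD): mu and beta sinusoids ride on Gaussian broadband noise at the
#' hand-area electrodes C3 and C4, and during imagery the contralateral
#' rhythm amplitude is attenuated by `erd_depth` (C3 for right-hand
#' imagery, C4 for left-hand). No volume-conduction forward model is
#' applied; an optional channel mixing matrix can make the problem harder.
#'
#' @param mu_freq,beta_freq Rhythm frequencies, Hz (defaults 10 and 20).
#' @param rhythm_amp Sinusoid amplitude at rest, microvolts (default 10).
#' @param erd_depth Contralateral amplitude attenuation in \[0, 1\]
#'   (default 0.6, a strong but realistic desynchronization).
#' @param noise_sd Broadband noise SD, microvolts (default 10).
#' @param rate Sampling rate, Hz (default 250).
#' @param mixing Optional 9 x 9 channel mixing matrix.
#' @return A list of class `mi_gen_params`.
#' @export
mi_gen_params <- function(mu_freq = 10, beta_freq = 20, rhythm_amp = 10,
                          erd_depth = 0.6, noise_sd = 10, rate = 250,
                          mixing = NULL) {
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(
    list(mu_freq = mu_freq, beta_freq = beta_freq, rhythm_amp = rhythm_amp,
         erd_depth = erd_depth, noise_sd = noise_sd, rate = rate,
         mixing = mixing),
    class = "mi_gen_params"
  )
}

# mu+beta waveform with random phases, scaled by `atten`
rhythm_wave <- function(n, p, atten = 1) {
  t <- (seq_len(n) - 1) / p$rate
  ph <- stats::runif(2, 0, 2 * pi)
  atten * p$rhythm_amp *
    (sin(2 * pi * p$mu_freq * t + ph[1]) + sin(2 * pi * p$beta_freq * t + ph[2]))
}

#' Generate one synthetic motor-imagery trial
#'
#' @param label `"left"` or `"right"` imagined hand.
#' @param p An [mi_gen_params()].
#' @param n_samples Samples per trial (default 1250 = 5 s at 250 Hz).
#' @param seed Optional integer seed (bit-reproducible when set).
#' @return A [labeled_trial()] over the 9-channel EEG montage.
#' @export
gen_mi_trial <- function(label = c("left", "right"), p = mi_gen_params(),
                         n_samples = 1250, seed = NULL) {
  label <- match.arg(label)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(9 * n_samples, sd = p$noise_sd), 9, n_samples,
              dimnames = list(EEG_CHANNELS, NULL))
  # contralateral attenuation: right-hand imagery suppresses C3 (left
  # hemisphere), left-hand imagery suppresses C4
  att_c3 <- if (label == "right") 1 - p$erd_depth else 1
  att_c4 <- if (label == "left") 1 - p$erd_depth else 1
  X["C3", ] <- X["C3", ] + rhythm_wave(n_samples, p, att_c3)
  X["C4", ] <- X["C4", ] + rhythm_wave(n_samples, p, att_c4)
  if (!is.null(p$mixing)) X <- p$mixing %*% X
  labeled_trial(X, label)
}

#' Generate a full training session recording
#'
#' Reproduces the cue-based offline protocol: each trial is 5 s rest, 2 s
#' fixation cross, then 5 s of cued left/right imagery; labels are
#' balanced and randomly ordered. During rest/cross the C3/C4 rhythms run
#' at full (idle) amplitude; during imagery the contralateral rhythm is
#' attenuated by `erd_depth`. Cue events mark the imagery onsets.
#'
#' @param n_trials Trials in the session (default 40).
#' @param p An [mi_gen_params()].
#' @param seed Optional integer seed.
#' @return A list `(recording, events)`; pipe through [bandpass()] and
#'   [extract_trials()] to recover the labeled trials.
#' @export
gen_training_session <- function(n_trials = 40, p = mi_gen_params(),
                                 seed = NULL) {
  if (n_trials < 1) stop("n_trials must be positive")
  if (!is.null(seed)) set.seed(seed)
  labels <- sample(rep(c("left", "right"), length.out = n_trials))
  trial_len <- 12                      # 5 rest + 2 cross + 5 imagery
  n_total <- round(n_trials * trial_len * p$rate)
  X <- matrix(stats::rnorm(9 * n_total, sd = p$noise_sd), 9, n_total,
              dimnames = list(EEG_CHANNELS, NULL))
  n_img <- round(5 * p$rate)
  for (i in seq_len(n_trials)) {
    t0 <- (i - 1) * trial_len
    idle_n <- round(7 * p$rate)
    idle_idx <- round(t0 * p$rate) + seq_len(idle_n)
    img_idx <- round((t0 + 7) * p$rate) + seq_len(n_img)
    X["C3", idle_idx] <- X["C3", idle_idx] + rhythm_wave(idle_n, p, 1)
    X["C4", idle_idx] <- X["C4", idle_idx] + rhythm_wave(idle_n, p, 1)
    att_c3 <- if (labels[i] == "right") 1 - p$erd_depth else 1
    att_c4 <- if (labels[i] == "left") 1 - p$erd_depth else 1
    X["C3", img_idx] <- X["C3", img_idx] + rhythm_wave(n_img, p, att_c3)
    X["C4", img_idx] <- X["C4", img_idx] + rhythm_wave(n_img, p, att_c4)
  }
  if (!is.null(p$mixing)) X <- p$mixing %*% X
  events <- event_table(
    onset_s = (seq_len(n_trials) - 1) * trial_len + 7,
    kind = ifelse(labels == "left", "cue_left", "cue_right"),
    label = labels
  )
  list(recording = recording(X, rate = p$rate), events = events)
}

#' Synthetic EOG stream parameters
#'
#' Intended blinks are modeled stronger than spontaneous ones (the
#' voluntary movement recruits a firmer lid closure), and eyebrow raises
#' as longer sustained deflections. Defaults place the intended amplitude
#' well above, and the unintended mean below, the default intended
#' threshold `TH_a` of [eog_params()].
#'
#' @param intended_amp Intended blink peak amplitude, microvolts.
#' @param unintended_amp_mean,unintended_amp_sd Spontaneous blink peak
#'   distribution, microvolts.
#' @param blink_dur Blink deflection duration, seconds.
#' @param eyebrow_amp,eyebrow_dur Eyebrow-raise template, microvolts and
#'   seconds (`eyebrow_dur > blink_dur`).
#' @param unintended_rate Spontaneous blink rate, events/min (default 15,
#'   mid normal range).
#' @param latency_mean,latency_sd Flash-to-peak response latency,
#'   seconds.
#' @param noise_sd Ocular background noise SD, microvolts.
#' @param rate Sampling rate, Hz.
#' @return A list of class `eog_gen_params`.
#' @export
eog_gen_params <- function(intended_amp = 400, unintended_amp_mean = 150,
                           unintended_amp_sd = 25, blink_dur = 0.25,
                           eyebrow_amp = 350, eyebrow_dur = 0.55,
                           unintended_rate = 15, latency_mean = 0.30,
                           latency_sd = 0.005, noise_sd = 15, rate = 250) {
  if (intended_amp <= unintended_amp_mean) {
    stop("intended_amp must exceed unintended_amp_mean")
  }
  if (eyebrow_dur <= blink_dur) stop("eyebrow_dur must exceed blink_dur")
  structure(
    list(intended_amp = intended_amp,
         unintended_amp_mean = unintended_amp_mean,
         unintended_amp_sd = unintended_amp_sd, blink_dur = blink_dur,
         eyebrow_amp = eyebrow_amp, eyebrow_dur = eyebrow_dur,
         unintended_rate = unintended_rate, latency_mean = latency_mean,
         latency_sd = latency_sd, noise_sd = noise_sd, rate = rate),
    class = "eog_gen_params"
  )
}

# raised-cosine bump of total duration `dur`, peak `amp`
blink_template <- function(amp, dur, rate) {
  n <- round(dur * rate)
  amp / 2 * (1 - cos(2 * pi * (seq_len(n) - 0.5) / n))
}

# smoothed plateau: raised-cosine ramps around a flat top; narrow ramps
# keep the above-half-peak duration close to the nominal duration
eyebrow_template <- function(amp, dur, rate, ramp_frac = 0.1) {
  n <- round(dur * rate)
  ramp <- round(n * ramp_frac)
  flat <- n - 2 * ramp
  c(amp / 2 * (1 - cos(pi * seq_len(ramp) / ramp)),
    rep(amp, flat),
    amp / 2 * (1 + cos(pi * seq_len(ramp) / ramp)))
}

add_at <- function(x, template, peak_time, rate, align = c("peak", "center")) {
  align <- match.arg(align)
  n <- length(template)
  peak_i <- if (align == "peak") which.max(template) else round(n / 2)
  i0 <- round(peak_time * rate) + 1 - (peak_i - 1)
  idx <- i0:(i0 + n - 1)
  ok <- idx >= 1 & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + template[ok]
  x
}

#' Generate a scripted EOG selection stream
#'
#' Builds a single-channel EOG recording containing, for each scripted
#' selection, an intended blink peaking `latency_mean` after the next
#' flash of the target button, followed (when `verify` is `TRUE`) by an
#' eyebrow raise; spontaneous blinks with unintended amplitudes arrive as
#' a Poisson process uniform over time. Ground truth goes into the event
#' table (`blink_truth` rows carry the target button, `command` rows the
#' expected emission).
#'
#' @param script A data frame / tibble with columns `time_s` (earliest
#'   start of the attempt), `button` (target id) and optionally `verify`
#'   (default `TRUE`). Use `NULL` or zero rows for an idle stream.
#' @param duration_s Stream length, seconds.
#' @param schedule A [build_schedule()].
#' @param p An [eog_gen_params()].
#' @param seed Optional integer seed.
#' @param verify_delay Gap between blink peak and eyebrow peak, seconds.
#' @return A list `(recording, events)`.
#' @export
gen_eog_stream <- function(script, duration_s, schedule,
                           p = eog_gen_params(), seed = NULL,
                           verify_delay = 1.0) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * p$rate)
  x <- stats::rnorm(n, sd = p$noise_sd)
  ev_onset <- numeric(); ev_kind <- character(); ev_label <- character()

  # spontaneous blinks, Poisson over the stream
  n_spont <- stats::rpois(1, p$unintended_rate * duration_s / 60)
  spont_t <- sort(stats::runif(n_spont, 0.5, duration_s - 0.5))
  spont_amp <- pmax(stats::rnorm(n_spont, p$unintended_amp_mean,
                                 p$unintended_amp_sd), 1)
  for (i in seq_len(n_spont)) {
    x <- add_at(x, blink_template(spont_amp[i], p$blink_dur, p$rate),
                spont_t[i], p$rate)
    ev_onset <- c(ev_onset, spont_t[i])
    ev_kind <- c(ev_kind, "blink_truth")
    ev_label <- c(ev_label, "unintended")
  }

  if (!is.null(script) && nrow(script) > 0) {
    if (!"verify" %in% names(script)) script$verify <- TRUE
    for (i in seq_len(nrow(script))) {
      target <- script$button[i]
      k <- match(target, schedule$buttons) - 1
      if (is.na(k)) stop(sprintf("unknown button '%s' for the %s panel",
                                 target, schedule$panel))
      # first flash of the target at or after the scripted time
      r <- ceiling((script$time_s[i] - k * schedule$interval) /
                     schedule$round_period)
      onset <- max(r, 0) * schedule$round_period + k * schedule$interval
      latency <- stats::rnorm(1, p$latency_mean, p$latency_sd)
      peak_t <- onset + latency
      if (peak_t + p$eyebrow_dur + verify_delay > duration_s) {
        stop(sprintf("scripted selection %d does not fit in the stream", i))
      }
      x <- add_at(x, blink_template(p$intended_amp, p$blink_dur, p$rate),
                  peak_t, p$rate)
      ev_onset <- c(ev_onset, peak_t)
      ev_kind <- c(ev_kind, "blink_truth")
      ev_label <- c(ev_label, target)
      ev_onset <- c(ev_onset, onset)
      ev_kind <- c(ev_kind, "flash")
      ev_label <- c(ev_label, target)
      if (isTRUE(script$verify[i])) {
        # centre-aligned so the truth time matches the detector's
        # above-half-run centre timestamp
        x <- add_at(x, eyebrow_template(p$eyebrow_amp, p$eyebrow_dur, p$rate),
                    peak_t + verify_delay, p$rate, align = "center")
        ev_onset <- c(ev_onset, peak_t + verify_delay)
        ev_kind <- c(ev_kind, "eyebrow_truth")
        ev_label <- c(ev_label, target)
        ev_onset <- c(ev_onset, script$time_s[i])
        ev_kind <- c(ev_kind, "command")
        ev_label <- c(ev_label, target)
      }
    }
  }
  ord <- order(ev_onset)
  rec <- recording(matrix(x, 1, n, dimnames = list(EOG_CHANNEL, NULL)),
                   rate = p$rate)
  list(recording = rec,
       events = event_table(ev_onset[ord], ev_kind[ord], ev_label[ord]))
}

#' Advance the plant by one integration step
#'
#' Applies a steering decision (`LEFT`/`RIGHT` engage the fixed
#' 0.1*pi rad/s turn, `NEUTRAL` disengages it) or a verified command (via
#' [dispatch()]), then integrates the kinematics with one explicit Euler
#' step: heading first, then position along the new heading.
#'
#' @param s A [plant_state()].
#' @param input `NULL`, a steering decision string, or a command id.
#' @param dt Step size, seconds (default 0.02; one 0.2-s decoder step is
#'   ten plant steps).
#' @return The advanced [plant_state()].
#' @export
plant_step <- function(s, input = NULL, dt = 0.02) {
  stopifnot(inherits(s, "plant_state"), dt > 0)
  if (!is.null(input)) {
    if (input %in% c("LEFT", "RIGHT", "NEUTRAL")) {
      s$angular_v <- switch(input, LEFT = 0.1 * pi, RIGHT = -0.1 * pi,
                            NEUTRAL = 0)
    } else {
      s <- dispatch(input, s)$plant
    }
  }
  s$heading <- s$heading + s$angular_v * dt
  s$x <- s$x + s$linear_v * cos(s$heading) * dt
  s$y <- s$y + s$linear_v * sin(s$heading) * dt
  s
}

#' Stopping distance from speed and stop latency
#'
#' The wheelchair keeps moving during the interval between the user's
#' stop intent and the command taking effect, so the positional accuracy
#' of a stop is simply `speed * stop_latency` (0.23 m at 0.2 m/s with a
#' 1.15-s stop reaction time).
#'
#' @param speed m/s, `>= 0`.
#' @param stop_latency Seconds, `>= 0`.
#' @return Overshoot distance in meters.
#' @export
stop_distance <- function(speed, stop_latency) {
  stopifnot(speed >= 0, stop_latency >= 0)
  speed * stop_latency
}

#' Closed-loop stop overshoot
#'
#' Drives the plant forward at 0.2 m/s and issues `STOP` once
#' `stop_latency` has elapsed, integrating at `dt`; returns the distance
#' traveled past the intent point. Agrees with [stop_distance()] to
#' within one integration step.
#'
#' @param speed Forward speed, m/s.
#' @param stop_latency Pipeline latency between intent and the STOP
#'   command, seconds.
#' @param dt Euler step, seconds.
#' @return Overshoot in meters.
#' @export
simulate_stop_overshoot <- function(speed = 0.2, stop_latency = 1.15,
                                    dt = 0.02) {
  s <- plant_state()
  s$linear_v <- speed
  t <- 0
  while (s$linear_v != 0) {
    input <- if (t >= stop_latency) "STOP" else NULL
    s <- plant_step(s, input, dt)
    t <- t + dt
  }
  sqrt(s$x^2 + s$y^2)
}

#' Grasp feasibility test
#'
#' The arm can only grasp objects inside a rectangular workspace starting
#' 0.4 m ahead of the wheelchair-mounted camera: 0.8 m deep, 0.4 m wide,
#' 0.6 m tall. Camera frame: x forward, y lateral, z up from the box
#' floor.
#'
#' @param target Numeric `c(x, y, z)` in meters, camera frame.
#' @param depth_start,depth,width,height Box geometry in meters.
#' @return `TRUE` iff the target lies inside the workspace.
#' @export
grasp_feasible <- function(target, depth_start = 0.4, depth = 0.8,
                           width = 0.4, height = 0.6) {
  stopifnot(length(target) == 3)
  target[1] >= depth_start && target[1] <= depth_start + depth &&
    abs(target[2]) <= width / 2 &&
    target[3] >= 0 && target[3] <= height
}

#' Run a scripted closed-loop driving scenario
#'
#' Feeds a timeline of steering decisions and commands to the plant at
#' the decoder cadence (one input per 0.2 s, each integrated as ten Euler
#' steps) and logs the trajectory.
#'
#' @param inputs Character vector of per-step inputs (`"LEFT"`,
#'   `"RIGHT"`, `"NEUTRAL"`, or command ids); one entry per decoder step.
#' @param s0 Initial [plant_state()].
#' @param decoder_step Seconds per input (default 0.2).
#' @param dt Euler step (default 0.02).
#' @return A tibble `t_s, x_m, y_m, heading_rad, linear_v, angular_v`.
#' @export
run_plant <- function(inputs, s0 = plant_state(), decoder_step = 0.2,
                      dt = 0.02) {
  s <- s0
  n_sub <- round(decoder_step / dt)
  rows <- vector("list", length(inputs))
  t <- 0
  for (i in seq_along(inputs)) {
    s <- plant_step(s, inputs[i], dt)
    for (j in seq_len(n_sub - 1)) s <- plant_step(s, NULL, dt)
    t <- t + decoder_step
    rows[[i]] <- tibble::tibble(t_s = t, x_m = s$x, y_m = s$y,
                                heading_rad = s$heading,
                                linear_v = s$linear_v,
                                angular_v = s$angular_v)
  }
  dplyr::bind_rows(rows)
}

#' Plot a plant trajectory
#'
#' @param object Tibble from [run_plant()].
#' @param ... Unused.
#' @return A ggplot object of the planar path.
#' @export
plot_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
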