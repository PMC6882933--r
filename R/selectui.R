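WHEELCHAIR_BUTTONS <- c("MOVE", "BACK", "STOP", "PLUS_L", "MINUS_L",
                        "PLUS_R", "MINUS_R", "RENEW", "SWITCH")
ARM_BUTTONS <- c("ITEM1", "ITEM2", "ITEM3", "INIT", "ARM_BACK", "ARM_SWITCH")

#' Build a panel's cyclic flash schedule
#'
#' Both GUI panels flash their buttons one by one in a fixed order: the
#' wheelchair panel has 9 buttons at a 100-ms onset interval, the robotic
#' arm panel 6 buttons at 150 ms, so a complete round lasts 900 ms on
#' either panel. Button `k` (0-based) of round `r` flashes at
#' `r * round_period + k * interval`.
#'
#' @param panel `"wheelchair"` or `"arm"`.
#' @return A list of class `flash_schedule` with fields `panel`,
#'   `buttons`, `interval`, `round_period`.
#' @export
build_schedule <- function(panel = c("wheelchair", "arm")) {
  panel <- match.arg(panel)
  buttons <- if (panel == "wheelchair") WHEELCHAIR_BUTTONS else ARM_BUTTONS
  interval <- if (panel == "wheelchair") 0.1 else 0.15
  structure(
    list(panel = panel, buttons = buttons, interval = interval,
         round_period = length(buttons) * interval),
    class = "flash_schedule"
  )
}

#' @export
print.flash_schedule <- function(x, ...) {
  cat(sprintf("<flash_schedule> %s panel: %d buttons every %g ms, %g ms round\n",
              x$panel, length(x$buttons), x$interval * 1000,
              x$round_period * 1000))
  invisible(x)
}

#' Enumerate flash onsets up to a horizon
#'
#' @param schedule A [build_schedule()].
#' @param t_max Horizon in seconds; onsets strictly before `t_max`.
#' @return Numeric vector of onset times, seconds.
#' @export
flash_onsets <- function(schedule, t_max) {
  n <- ceiling(t_max / schedule$interval) + 1
  on <- (seq_len(n) - 1) * schedule$interval
  on[on < t_max]
}

#' Button flashed at a given onset
#'
#' @param schedule A [build_schedule()].
#' @param onset Flash onset time, seconds.
#' @return Button id.
#' @export
button_at <- function(schedule, onset) {
  k <- round((onset %% schedule$round_period) / schedule$interval)
  schedule$buttons[(k %% length(schedule$buttons)) + 1]
}

#' Attribute an intended blink to a button
#'
#' Finds the unique flash onset whose latency to the blink peak falls
#' inside the delay window. Uniqueness holds whenever the window is
#' narrower than the flash interval, which the function enforces.
#'
#' @param peak_s Blink peak time, seconds.
#' @param schedule A [build_schedule()].
#' @param delay_window Length-2 numeric, seconds.
#' @return Button id, or `NA_character_` when no flash qualifies.
#' @export
attribute_blink <- function(peak_s, schedule, delay_window) {
  if (diff(delay_window) >= schedule$interval - 1e-9) {
    stop("configuration error: delay window at least as wide as the flash ",
         "interval makes attribution ambiguous")
  }
  # candidate onsets lie in [peak - hi, peak - lo]
  lo_on <- peak_s - delay_window[2]
  hi_on <- peak_s - delay_window[1]
  k <- ceiling(lo_on / schedule$interval - 1e-9)
  cand <- k * schedule$interval
  if (cand < 0 || cand > hi_on + 1e-9) return(NA_character_)
  button_at(schedule, cand)
}

#' Initial selection state
#'
#' @return A list of class `selection_state` in mode `IDLE`.
#' @export
selection_state <- function() {
  structure(
    list(mode = "IDLE", preselected_button = NULL, preselect_time = NULL),
    class = "selection_state"
  )
}

#' Advance the preselect-verify-command state machine
#'
#' An intended blink preselects its button (highlighting it, no command
#' yet); an eyebrow raise within the verification timeout emits that
#' button's command and returns to idle; the timeout elapsing drops the
#' preselection silently; a second intended blink re-preselects, letting
#' the user correct a wrong preselection without waiting.
#'
#' @param state A [selection_state()].
#' @param event A list with `type` (`"intended_blink"`, `"eyebrow"`, or
#'   `"tick"`), `time` (seconds) and, for blinks, `button`.
#' @param timeout Verification timeout in seconds (default 3).
#' @return A list `(state, command)`; `command` is `NULL` or a button id.
#' @export
selection_step <- function(state, event, timeout = 3) {
  stopifnot(inherits(state, "selection_state"))
  cmd <- NULL
  expired <- state$mode == "PRESELECTED" &&
    event$time - state$preselect_time > timeout
  if (expired && event$type != "intended_blink") {
    state <- selection_state()
  }
  if (event$type == "intended_blink") {
    state$mode <- "PRESELECTED"
    state$preselected_button <- event$button
    state$preselect_time <- event$time
  } else if (event$type == "eyebrow" && state$mode == "PRESELECTED") {
    cmd <- state$preselected_button
    state <- selection_state()
  }
  list(state = state, command = cmd)
}

#' New plant state
#'
#' Pose and mode of the simulated wheelchair + robotic-arm plant: planar
#' pose (x, y, heading), commanded velocities (forward speed 0 or
#' +/-0.2 m/s; angular velocity 0 or +/-0.1*pi rad/s, i.e. 18 deg/s), the
#' active GUI panel, and the arm phase.
#'
#' @param x,y Position, meters.
#' @param heading Radians, counterclockwise from +x.
#' @return A list of class `plant_state`.
#' @export
plant_state <- function(x = 0, y = 0, heading = 0) {
  structure(
    list(x = x, y = y, heading = heading, linear_v = 0, angular_v = 0,
         active_panel = "wheelchair", arm_phase = "home"),
    class = "plant_state"
  )
}

#' Dispatch a verified command to the plant
#'
#' Motion commands (`MOVE`, `BACK`, `STOP`) are always accepted. Every
#' other wheelchair-panel command — threshold adjustment, idle-score
#' renewal, panel switch — is accepted only while the wheelchair is fully
#' stopped (both velocities zero); otherwise it is rejected with a reason.
#' Commands from the inactive panel raise a protocol error.
#'
#' @param cmd Command id (a button id).
#' @param plant A [plant_state()].
#' @return A list `(plant, accepted, reason)`.
#' @export
dispatch <- function(cmd, plant) {
  stopifnot(inherits(plant, "plant_state"))
  panel_of <- if (cmd %in% WHEELCHAIR_BUTTONS) "wheelchair"
              else if (cmd %in% ARM_BUTTONS) "arm"
              else stop(sprintf("unknown command '%s'", cmd))
  if (panel_of != plant$active_panel) {
    stop(sprintf("protocol error: command %s arrived while the %s panel is active",
                 cmd, plant$active_panel))
  }
  stopped <- plant$linear_v == 0 && plant$angular_v == 0
  accepted <- TRUE
  reason <- ""
  if (cmd == "MOVE") {
    plant$linear_v <- 0.2
  } else if (cmd == "BACK") {
    plant$linear_v <- -0.2
  } else if (cmd == "STOP") {
    plant$linear_v <- 0
    plant$angular_v <- 0
  } else if (!stopped) {
    accepted <- FALSE
    reason <- "wheelchair must be stopped"
  } else if (cmd %in% c("SWITCH", "ARM_SWITCH")) {
    plant$active_panel <- if (plant$active_panel == "wheelchair") "arm"
                          else "wheelchair"
  } else if (cmd %in% c("ITEM1", "ITEM2", "ITEM3")) {
    plant$arm_phase <- "at_mouth"
  } else if (cmd %in% c("INIT", "ARM_BACK")) {
    plant$arm_phase <- "home"
  }
  # PLUS/MINUS/RENEW act on the decoder model, not the plant; accepted
  # while stopped so the caller can apply adjust_threshold()/renew_idle_score()
  list(plant = plant, accepted = accepted, reason = reason)
}
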