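#' Task and analysis configuration
#'
#' Bundles the geometry, timing and analysis constants of the interception
#' task: a target appears 30 cm to the left of and 20 cm beyond the start
#' point, moves rightward at 50 cm/s, and is perturbed by a +/-2.5 mm
#' lateral random-walk step on every 60 Hz display frame while the finger
#' is tracked at 500 Hz. Analysis constants (the 100 ms step filter, the
#' 250 ms response window, the 40 ms Savitzky-Golay differentiation window
#' and the 2 cm near-path threshold for the movement-end fallback) live
#' here as well, so a single object pins down one study configuration.
#'
#' Coordinates are millimetres in a frame with the origin at the start
#' point, x positive rightward (the target's motion direction, the
#' "lateral" axis) and y positive away from the participant. Times are
#' seconds internally; window lengths are given in milliseconds because
#' that is how they are usually quoted.
#'
#' @param frame_rate Display frame rate, Hz.
#' @param sample_rate Finger position sampling rate, Hz.
#' @param step_amplitude Size of each random-walk jitter step, mm.
#' @param target_speed Rightward target speed, mm/s.
#' @param target_start Target appearance point relative to the start point,
#'   mm, as `c(x, y)`. The target's path is the horizontal line
#'   `y = target_start[2]`.
#' @param target_diameter,cursor_diameter,start_diameter Disc diameters, mm.
#' @param max_trial_duration Maximum trial length, s.
#' @param near_path_threshold Movements that stop short of the target path
#'   by less than this distance (mm) still get a movement end (at maximal
#'   distance from the start); those further away are excluded.
#' @param latency_floor Steps closer than this (ms) to the end of the
#'   movement are never analysed (strictly-greater filter).
#' @param response_window Length of the response kernel after a step, ms.
#' @param savgol_window Width of the Savitzky-Golay differentiation
#'   window, ms.
#' @param savgol_polyorder Polynomial order of the Savitzky-Golay fit.
#'
#' @return An object of class `session_config` (a named list).
#' @examples
#' cfg <- session_config()
#' cfg$step_amplitude * cfg$frame_rate  # equivalent jitter speed, mm/s
#' @export
session_config <- function(frame_rate = 60,
                           sample_rate = 500,
                           step_amplitude = 2.5,
                           target_speed = 500,
                           target_start = c(-300, 200),
                           target_diameter = 27,
                           cursor_diameter = 10,
                           start_diameter = 20,
                           max_trial_duration = 1.5,
                           near_path_threshold = 20,
                           latency_floor = 100,
                           response_window = 250,
                           savgol_window = 40,
                           savgol_polyorder = 2) {
  cfg <- list(
    frame_rate = frame_rate, sample_rate = sample_rate,
    step_amplitude = step_amplitude, target_speed = target_speed,
    target_start = target_start, target_diameter = target_diameter,
    cursor_diameter = cursor_diameter, start_diameter = start_diameter,
    max_trial_duration = max_trial_duration,
    near_path_threshold = near_path_threshold,
    latency_floor = latency_floor, response_window = response_window,
    savgol_window = savgol_window, savgol_polyorder = savgol_polyorder
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  pos <- c(
    "frame_rate", "sample_rate", "target_speed", "target_diameter",
    "cursor_diameter", "start_diameter", "max_trial_duration",
    "near_path_threshold", "latency_floor", "response_window",
    "savgol_window"
  )
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("session_config: `", f, "` must be a single positive number",
        call. = FALSE
      )
    }
  }
  if (!is.numeric(cfg$step_amplitude) || length(cfg$step_amplitude) != 1L ||
    cfg$step_amplitude < 0) {
    stop("session_config: `step_amplitude` must be a single non-negative number",
      call. = FALSE
    )
  }
  if (!is.numeric(cfg$target_start) || length(cfg$target_start) != 2L) {
    stop("session_config: `target_start` must be a length-2 numeric (x, y) in mm",
      call. = FALSE
    )
  }
  n_win <- savgol_half_width(cfg) * 2L + 1L
  if (cfg$savgol_polyorder >= n_win) {
    stop("session_config: `savgol_polyorder` (", cfg$savgol_polyorder,
      ") must be smaller than the number of samples (", n_win,
      ") in a ", cfg$savgol_window, " ms window at ", cfg$sample_rate, " Hz",
      call. = FALSE
    )
  }
  if (cfg$latency_floor >= cfg$response_window) {
    stop("session_config: `latency_floor` must be smaller than `response_window`",
      call. = FALSE
    )
  }
  cfg
}

# Half width (in samples) of the centred SG window: a "40 ms" window at
# 500 Hz is 21 samples, centre +/- 10, spanning 40 ms inclusive.
savgol_half_width <- function(cfg) {
  as.integer(round(cfg$savgol_window / 1000 * cfg$sample_rate / 2))
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf(
    "  display %g Hz, sampling %g Hz, jitter step %g mm (%g mm/s equivalent)\n",
    x$frame_rate, x$sample_rate, x$step_amplitude,
    x$step_amplitude * x$frame_rate
  ))
  cat(sprintf(
    "  target: %g mm disc at (%g, %g) mm moving %g mm/s rightward\n",
    x$target_diameter, x$target_start[1], x$target_start[2], x$target_speed
  ))
  cat(sprintf(
    "  analysis: step filter > %g ms, response window %g ms, SG %g ms order %d\n",
    x$latency_floor, x$response_window, x$savgol_window, x$savgol_polyorder
  ))
  invisible(x)
}

#' Generative feedback-control law for the simulator
#'
#' Describes how a simulated actor converts each jitter step into a
#' corrective lateral response. The law is an invention of this package
#' (the analysis it feeds makes no such assumption): after a fixed visuomotor
#' `latency`, a step of size d (mm) injects a lateral acceleration
#' `d * gain(t_remaining) * h(t)` where `h` is a gamma-density impulse
#' response with unit time-integral (so each step produces a persistent
#' velocity change of `d * gain` mm/s), and `gain` grows as the remaining
#' movement time shrinks. Cursor steps are responded to with the opposite
#' sign (the correction moves the finger away from the displayed
#' displacement) and scaled by `cursor_weight`, reflecting the jitter-free
#' kinaesthetic information that dilutes visual information about the hand.
#'
#' The default gain schedule is `gain_scale / max(t_remaining, gain_floor)`
#' in units of 1/s: it is the velocity change per millimetre of step needed
#' to cancel the step within the remaining time, floored near the end of
#' the movement.
#'
#' @param latency Visuomotor delay from step onset to response onset, ms.
#' @param irf_peak_time Mode of the gamma acceleration impulse response,
#'   ms after response onset.
#' @param irf_duration Practical support (99th percentile) of the impulse
#'   response, ms.
#' @param target_gain Function mapping remaining time (s) to the response
#'   gain (1/s). Vectorised over its argument. The default is
#'   `gain_scale / pmax(t, gain_floor)`.
#' @param gain_scale,gain_floor Parameters of the default gain schedule:
#'   dimensionless scale and the remaining-time floor (s). Ignored when
#'   `target_gain` is supplied.
#' @param cursor_weight Ratio of cursor-step to target-step response
#'   vigour, in `[0, 1]`.
#' @param motor_noise_sd White lateral/forward acceleration noise, mm/s^2
#'   per sample. The default is calibrated so that default synthetic
#'   sessions are hit on roughly 70 percent of trials.
#' @param nominal_duration Mean planned time from target appearance to the
#'   finger crossing the target path, s.
#' @param duration_sd Trial-to-trial standard deviation of the planned
#'   crossing time, s.
#' @param reaction_time Delay from target appearance to movement onset, s.
#'   No behavioural response is produced before movement onset.
#'
#' @return An object of class `feedback_model` (a named list). The gamma
#'   impulse-response shape and rate implied by `irf_peak_time` and
#'   `irf_duration` are stored as `irf_shape` and `irf_rate`.
#' @examples
#' mdl <- feedback_model(cursor_weight = 0.6)
#' mdl$target_gain(c(0.5, 0.25, 0.1)) # gain rises as time runs out
#' @export
feedback_model <- function(latency = 110,
                           irf_peak_time = 90,
                           irf_duration = 300,
                           target_gain = NULL,
                           gain_scale = 1,
                           gain_floor = 0.1,
                           cursor_weight = 0.6,
                           motor_noise_sd = 1600,
                           nominal_duration = 0.58,
                           duration_sd = 0.04,
                           reaction_time = 0.15) {
  if (!is.numeric(latency) || length(latency) != 1L || latency <= 0) {
    stop("feedback_model: `latency` must be a single positive number (ms)",
      call. = FALSE
    )
  }
  if (!is.numeric(cursor_weight) || length(cursor_weight) != 1L ||
    cursor_weight < 0 || cursor_weight > 1) {
    stop("feedback_model: `cursor_weight` must be in [0, 1]", call. = FALSE)
  }
  if (motor_noise_sd < 0 || nominal_duration <= 0 || duration_sd < 0 ||
    reaction_time < 0 || gain_scale < 0 || gain_floor <= 0) {
    stop("feedback_model: noise/duration/gain parameters out of range",
      call. = FALSE
    )
  }
  if (irf_duration <= irf_peak_time || irf_peak_time <= 0) {
    stop("feedback_model: need 0 < irf_peak_time < irf_duration (ms)",
      call. = FALSE
    )
  }
  if (is.null(target_gain)) {
    force(gain_scale)
    force(gain_floor)
    target_gain <- function(t_remaining) {
      gain_scale / pmax(t_remaining, gain_floor)
    }
  }
  if (!is.function(target_gain)) {
    stop("feedback_model: `target_gain` must be a function of remaining time (s)",
      call. = FALSE
    )
  }
  gsamp <- target_gain(seq(0.05, 1, by = 0.05))
  if (any(!is.finite(gsamp)) || any(gsamp < 0)) {
    stop("feedback_model: `target_gain` must return finite non-negative values",
      call. = FALSE
    )
  }
  irf <- gamma_irf_params(irf_peak_time / 1000, irf_duration / 1000)
  mdl <- list(
    latency = latency, irf_peak_time = irf_peak_time,
    irf_duration = irf_duration, irf_shape = irf$shape, irf_rate = irf$rate,
    target_gain = target_gain, cursor_weight = cursor_weight,
    motor_noise_sd = motor_noise_sd, nominal_duration = nominal_duration,
    duration_sd = duration_sd, reaction_time = reaction_time
  )
  class(mdl) <- "feedback_model"
  mdl
}

# Gamma density with mode `peak` (s) and 99th percentile `duration` (s):
# mode = (shape - 1) / rate. Solved for shape by root finding.
gamma_irf_params <- function(peak, duration) {
  f <- function(shape) {
    rate <- (shape - 1) / peak
    stats::qgamma(0.99, shape = shape, rate = rate) - duration
  }
  shape <- stats::uniroot(f, c(1.0001, 500), tol = 1e-10)$root
  list(shape = shape, rate = (shape - 1) / peak)
}

#' @export
print.feedback_model <- function(x, ...) {
  cat("<feedback_model>\n")
  cat(sprintf(
    "  latency %g ms, IRF peak %g ms / duration %g ms (gamma shape %.2f)\n",
    x$latency, x$irf_peak_time, x$irf_duration, x$irf_shape
  ))
  cat(sprintf(
    "  cursor_weight %g, motor noise %g mm/s^2, nominal duration %g s\n",
    x$cursor_weight, x$motor_noise_sd, x$nominal_duration
  ))
  invisible(x)
}
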