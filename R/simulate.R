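# Minimum-jerk position profile on normalised time s in [0, 1].
min_jerk <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

# Normalised time at which a minimum-jerk profile reaches fraction `frac`
# of its extent.
min_jerk_inverse <- function(frac) {
  stats::uniroot(function(s) min_jerk(s) - frac, c(0, 1), tol = 1e-12)$root
}

# Time-integral of the gamma CDF: the position response (per unit velocity
# change) to an acceleration impulse response dgamma(shape, rate).
# integral_0^u pgamma(v) dv = u * F(u; k, r) - (k / r) * F(u; k + 1, r).
gamma_position_response <- function(u, shape, rate) {
  out <- numeric(length(u))
  pos <- u > 0
  up <- u[pos]
  out[pos] <- up * stats::pgamma(up, shape, rate) -
    (shape / rate) * stats::pgamma(up, shape + 1, rate)
  out
}

# How far beyond the target path the baseline reach aims, mm: the finger
# slides through the target rather than stopping on its path.
PATH_OVERSHOOT_MM <- 15

#' Simulate one interception trial
#'
#' Generates the finger trajectory and display record of a single trial:
#' a minimum-jerk baseline reach from the start point through the target's
#' path, planned to cross that path at a per-trial nominal time and at the
#' target's predicted position at that moment, plus a lateral correction
#' term in which every jitter step injects, after the model's latency, a
#' gamma-shaped acceleration response whose size follows the model's
#' remaining-time-dependent gain. Cursor-step responses are scaled by
#' `cursor_weight` and sign-flipped so that both response types are
#' compensatory. White acceleration noise is added from movement onset.
#'
#' @param cfg A [session_config()].
#' @param model A [feedback_model()].
#' @param perturb_type `"target"` (jitter added to the target position) or
#'   `"cursor"` (jitter added to the cursor offset).
#' @param seed Optional integer seed for a reproducible trial.
#' @param trial_id Identifier stored in the trial.
#'
#' @return An `rc_trial`: list with `trial_id`, `perturb_type`,
#'   `samples` (tibble `t`, `x`, `y` at the sample rate, mm),
#'   `frames` (tibble `frame`, `t`, `step_dir`, `jitter`, `target_x`,
#'   `target_y`, `cursor_offset`), `hit`, `hit_position`, and a
#'   `movement_end` slot filled later by [annotate_session()].
#' @export
simulate_trial <- function(cfg, model, perturb_type = c("target", "cursor"),
                           seed = NULL, trial_id = 1L) {
  perturb_type <- match.arg(perturb_type)
  stopifnot(inherits(cfg, "session_config"), inherits(model, "feedback_model"))
  if (model$nominal_duration > cfg$max_trial_duration) {
    stop("simulate_trial: nominal_duration (", model$nominal_duration,
      " s) exceeds max_trial_duration (", cfg$max_trial_duration, " s)",
      call. = FALSE
    )
  }
  run <- function() simulate_trial_impl(cfg, model, perturb_type, trial_id)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_trial_impl <- function(cfg, model, perturb_type, trial_id) {
  dt <- 1 / cfg$sample_rate
  py <- cfg$target_start[2]
  y_end <- py + PATH_OVERSHOOT_MM
  s_cross <- min_jerk_inverse(py / y_end)

  # planned crossing time (from target appearance), truncated normal
  t_cross <- stats::rnorm(1, model$nominal_duration, model$duration_sd)
  lo <- model$reaction_time + 0.2
  hi <- min(model$nominal_duration + 3 * model$duration_sd + 1e-9,
            cfg$max_trial_duration - 0.3)
  t_cross <- min(max(t_cross, lo), max(hi, lo))

  t_on <- model$reaction_time
  D <- (t_cross - t_on) / s_cross # movement duration, onset to stop
  x_end <- (cfg$target_start[1] + cfg$target_speed * t_cross) /
    (py / y_end)

  t_max <- min(cfg$max_trial_duration, t_on + D + 0.25)
  n <- floor(t_max * cfg$sample_rate) + 1L
  times <- (seq_len(n) - 1L) * dt

  n_frames <- floor(t_max * cfg$frame_rate) + 1L
  steps <- generate_step_sequence(n_frames, cfg$step_amplitude,
    frame_rate = cfg$frame_rate
  )

  # corrective lateral response: one gamma step response per frame step
  sgn <- if (perturb_type == "target") 1 else -model$cursor_weight
  rem <- pmax(t_cross - steps$frame_times, 1e-3)
  coef <- sgn * steps$directions * cfg$step_amplitude * model$target_gain(rem)
  onset <- pmax(steps$frame_times + model$latency / 1000, t_on)
  x_corr <- as.vector(
    outer(times, onset, function(t, r) {
      gamma_position_response(t - r, model$irf_shape, model$irf_rate)
    }) %*% coef
  )

  s_arg <- (times - t_on) / D
  base_x <- x_end * min_jerk(s_arg)
  base_y <- y_end * min_jerk(s_arg)

  # white acceleration noise, doubly integrated; finger rests before onset
  moving <- times >= t_on
  noise_pos <- function() {
    a <- stats::rnorm(n, 0, model$motor_noise_sd) * moving
    cumsum(cumsum(a) * dt) * dt
  }
  x <- base_x + x_corr + noise_pos()
  y <- base_y + noise_pos()

  ft <- steps$frame_times
  path_x <- cfg$target_start[1] + cfg$target_speed * ft
  frames <- tibble::tibble(
    frame = seq_len(n_frames) - 1L,
    t = ft,
    step_dir = steps$directions,
    jitter = steps$cumulative_offset,
    target_x = if (perturb_type == "target") path_x + steps$cumulative_offset else path_x,
    target_y = py,
    cursor_offset = if (perturb_type == "cursor") steps$cumulative_offset else 0
  )

  trial <- structure(
    list(
      trial_id = trial_id,
      perturb_type = perturb_type,
      samples = tibble::tibble(t = times, x = x, y = y),
      frames = frames,
      hit = NA,
      hit_position = NULL,
      movement_end = NULL,
      excluded = FALSE
    ),
    class = "rc_trial"
  )
  h <- detect_hit(trial, cfg)
  trial$hit <- h$hit
  trial$hit_position <- h$position
  trial
}

#' Decide whether a trial hit the target
#'
#' The target counts as hit if the interpolated centre of the cursor is
#' ever within the target disc, i.e. if the distance between cursor centre
#' and target centre is at most the target radius at any interpolated
#' moment. Both trajectories are evaluated on the finger sample grid
#' (display quantities are held between frames) and interpolated linearly
#' between samples, so the minimum distance on each inter-sample segment
#' has a closed form.
#'
#' @param trial An `rc_trial`.
#' @param cfg A [session_config()].
#' @return List with `hit` (logical), `time` (s, first moment within the
#'   target, or `NA`), and `position` (target centre `c(x, y)` mm at that
#'   moment, or `NULL`).
#' @export
detect_hit <- function(trial, cfg) {
  stopifnot(inherits(trial, "rc_trial"), inherits(cfg, "session_config"))
  s <- trial$samples
  if (nrow(s) < 2L) {
    stop("detect_hit: trial has no finger samples to interpolate",
      call. = FALSE
    )
  }
  fr <- trial$frames
  # display quantities held from each frame until the next
  idx <- findInterval(s$t + 1e-9, fr$t)
  idx[idx < 1L] <- 1L
  tgt_x <- cfg$target_start[1] + cfg$target_speed * s$t +
    (if (trial$perturb_type == "target") fr$jitter[idx] else 0)
  tgt_y <- rep(cfg$target_start[2], nrow(s))
  cur_x <- s$x + (if (trial$perturb_type == "cursor") fr$cursor_offset[idx] else 0)
  cur_y <- s$y

  r <- cfg$target_diameter / 2
  px <- cur_x - tgt_x
  py <- cur_y - tgt_y
  n <- nrow(s)
  dx <- diff(px)
  dy <- diff(py)
  # per segment: |p + u*d|^2 = r^2, u in [0, 1]
  a <- dx^2 + dy^2
  b <- 2 * (px[-n] * dx + py[-n] * dy)
  cc <- px[-n]^2 + py[-n]^2 - r^2
  u_hit <- rep(NA_real_, n - 1L)
  inside0 <- cc <= 0
  u_hit[inside0] <- 0
  disc <- b^2 - 4 * a * cc
  cand <- which(!inside0 & disc >= 0 & a > 0)
  if (length(cand)) {
    u1 <- (-b[cand] - sqrt(disc[cand])) / (2 * a[cand])
    ok <- u1 >= 0 & u1 <= 1
    u_hit[cand[ok]] <- u1[ok]
  }
  seg <- which(!is.na(u_hit))
  if (!length(seg)) {
    return(list(hit = FALSE, time = NA_real_, position = NULL))
  }
  i <- seg[1L]
  u <- u_hit[i]
  t_hit <- s$t[i] + u * (s$t[i + 1L] - s$t[i])
  pos <- c(
    tgt_x[i] + u * (tgt_x[i + 1L] - tgt_x[i]),
    tgt_y[i]
  )
  list(hit = TRUE, time = t_hit, position = pos)
}

#' Simulate a session of interleaved trials
#'
#' Target-jitter and cursor-jitter trials are interleaved in seeded random
#' order, balanced to within one trial. Each trial receives its own child
#' seed derived from the master seed, so sessions are reproducible and
#' trials are mutually independent.
#'
#' @param cfg A [session_config()].
#' @param model A [feedback_model()].
#' @param n_trials Number of trials (>= 2).
#' @param seed Optional master seed.
#' @param session_id Identifier stored with the session.
#' @return An `rc_session`: list with `session_id`, `config`, `model` and
#'   `trials` (list of `rc_trial`).
#' @examples
#' \donttest{
#' ses <- simulate_session(session_config(), feedback_model(), 10, seed = 1)
#' table(vapply(ses$trials, function(tr) tr$perturb_type, ""))
#' }
#' @export
simulate_session <- function(cfg, model, n_trials, seed = NULL,
                             session_id = "s1") {
  stopifnot(inherits(cfg, "session_config"), inherits(model, "feedback_model"))
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 2) {
    stop("simulate_session: `n_trials` must be at least 2", call. = FALSE)
  }
  if (model$nominal_duration > cfg$max_trial_duration) {
    stop("simulate_session: nominal_duration exceeds max_trial_duration",
      call. = FALSE
    )
  }
  n_trials <- as.integer(n_trials)
  plan <- function() {
    types <- rep(c("target", "cursor"), length.out = n_trials)
    if (n_trials %% 2L == 1L) {
      types[n_trials] <- sample(c("target", "cursor"), 1L)
    }
    list(
      types = sample(types),
      child_seeds = sample.int(.Machine$integer.max - 1L, n_trials)
    )
  }
  p <- if (is.null(seed)) plan() else withr::with_seed(seed, plan())
  trials <- purrr::map(seq_len(n_trials), function(i) {
    simulate_trial(cfg, model, p$types[i],
      seed = p$child_seeds[i], trial_id = i
    )
  })
  structure(
    list(
      session_id = session_id, config = cfg, model = model,
      trials = trials
    ),
    class = "rc_session"
  )
}

#' @export
print.rc_session <- function(x, ...) {
  types <- vapply(x$trials, function(tr) tr$perturb_type, "")
  ann <- vapply(x$trials, function(tr) !is.null(tr$movement_end), TRUE)
  exc <- vapply(x$trials, function(tr) isTRUE(tr$excluded), TRUE)
  cat(sprintf(
    "<rc_session '%s'> %d trials (%d target, %d cursor), %d annotated, %d excluded\n",
    x$session_id, length(x$trials), sum(types == "target"),
    sum(types == "cursor"), sum(ann), sum(exc)
  ))
  invisible(x)
}

#' @export
print.rc_trial <- function(x, ...) {
  cat(sprintf(
    "<rc_trial %s> %s jitter, %d samples, %d frames, hit = %s\n",
    as.character(x$trial_id), x$perturb_type, nrow(x$samples),
    nrow(x$frames), as.character(x$hit)
  ))
  invisible(x)
}
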