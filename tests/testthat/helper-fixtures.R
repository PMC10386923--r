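# Hand-built trial fixtures and independent brute-force oracles used
# across the test files. The oracles deliberately share no code with the
# package internals: accelerations come from lm() quadratic fits and
# curves from explicit group-mean loops.

default_cfg <- session_config()

# A trial with an explicitly given finger path. Display frames carry zero
# jitter unless `jitter` is supplied; `step_dir` defaults to alternating.
make_trial <- function(t, x, y, cfg = default_cfg, perturb_type = "target",
                       trial_id = 1L, jitter = NULL, step_dir = NULL,
                       cursor_offset = NULL, hit = NA) {
  n_frames <- floor(max(t) * cfg$frame_rate) + 1L
  ft <- (seq_len(n_frames) - 1L) / cfg$frame_rate
  if (is.null(step_dir)) step_dir <- rep_len(c(1L, -1L), n_frames)
  if (is.null(jitter)) jitter <- rep(0, n_frames)
  if (is.null(cursor_offset)) {
    cursor_offset <- if (perturb_type == "cursor") jitter else rep(0, n_frames)
  }
  path_x <- cfg$target_start[1] + cfg$target_speed * ft
  structure(
    list(
      trial_id = trial_id, perturb_type = perturb_type,
      samples = tibble::tibble(t = t, x = x, y = y),
      frames = tibble::tibble(
        frame = seq_len(n_frames) - 1L, t = ft, step_dir = step_dir,
        jitter = jitter,
        target_x = if (perturb_type == "target") path_x + jitter else path_x,
        target_y = cfg$target_start[2],
        cursor_offset = cursor_offset
      ),
      hit = hit, hit_position = NULL, movement_end = NULL, excluded = FALSE
    ),
    class = "rc_trial"
  )
}

# Quiet deterministic model for structural tests.
quiet_model <- function(...) {
  feedback_model(motor_noise_sd = 0, duration_sd = 0, ...)
}

# Independent acceleration oracle: least-squares quadratic through the
# 2h+1 samples centred on the sample nearest `center_time`, via lm().
brute_accel <- function(positions, times, center_time, cfg = default_cfg) {
  h <- round(cfg$savgol_window / 1000 * cfg$sample_rate / 2)
  i <- which.min(abs(times - center_time))
  if (i - h < 1 || i + h > length(positions)) {
    return(NA_real_)
  }
  idx <- (i - h):(i + h)
  fit <- stats::lm(positions[idx] ~ stats::poly(times[idx], 2, raw = TRUE))
  2 * stats::coef(fit)[[3L]]
}

# Independent reverse-correlation oracle: explicit per-trial lm
# accelerations and explicit group means, for one (perturb_type, k).
brute_curve <- function(trials, k, perturb_type, cfg = default_cfg) {
  sel <- list()
  dirs <- c()
  for (tr in trials) {
    if (tr$perturb_type != perturb_type || is.null(tr$movement_end)) next
    me <- tr$movement_end
    f <- me$last_sync_frame - k
    if (f < 0) next
    t_frame <- f / cfg$frame_rate
    if (!(me$end_time - t_frame > cfg$latency_floor / 1000)) next
    sel[[length(sel) + 1L]] <- tr
    dirs <- c(dirs, tr$frames$step_dir[tr$frames$frame == f])
  }
  if (!length(sel) || all(dirs > 0) || all(dirs < 0)) {
    return(NULL)
  }
  lags <- seq(0, cfg$response_window / 1000, by = 1 / cfg$sample_rate)
  acc <- matrix(NA_real_, nrow = length(sel), ncol = length(lags))
  for (i in seq_along(sel)) {
    tr <- sel[[i]]
    me <- tr$movement_end
    t_frame <- (me$last_sync_frame - k) / cfg$frame_rate
    for (j in seq_along(lags)) {
      ct <- t_frame + lags[j]
      ci <- round(ct * cfg$sample_rate) + 1
      t_sample <- (ci - 1) / cfg$sample_rate
      if (t_sample > me$end_time + 1e-9) next
      acc[i, j] <- brute_accel(tr$samples$x, tr$samples$t, ct, cfg)
    }
  }
  sgn <- if (perturb_type == "target") 1 else -1
  vals <- numeric(0)
  keep_lags <- numeric(0)
  for (j in seq_along(lags)) {
    l_ok <- !is.na(acc[dirs < 0, j])
    r_ok <- !is.na(acc[dirs > 0, j])
    if (!any(l_ok) || !any(r_ok)) next
    m_l <- mean(acc[dirs < 0, j][l_ok])
    m_r <- mean(acc[dirs > 0, j][r_ok])
    vals <- c(vals, sgn * (m_r - m_l))
    keep_lags <- c(keep_lags, lags[j] * 1000)
  }
  data.frame(lag_ms = keep_lags, value = vals)
}
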