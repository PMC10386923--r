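#' Frame-from-end indices whose steps are analysable
#'
#' Since a visuomotor response takes at least about 100 ms, only steps
#' delivered strictly more than `cfg$latency_floor` ms before the end of
#' the movement are analysed. The filter is evaluated on the actual frame
#' times of the trial, not on the frame-from-end index: the 0-17 ms
#' synchronisation offset shifts frame times relative to the end, so the
#' same `k` can pass in one trial and fail in another.
#'
#' @param trial An annotated `rc_trial`.
#' @param cfg A [session_config()].
#' @return Integer vector of valid frame-from-end indices `k`.
#' @export
valid_step_frames <- function(trial, cfg) {
  stopifnot(inherits(cfg, "session_config"))
  fi <- frame_indices_from_end(trial)
  sort(fi$k[fi$time_before_end > cfg$latency_floor / 1000])
}

#' Split trials by the direction of the step at one synchronised frame
#'
#' Partitions the analysable trials of one perturbation type by whether
#' the jitter step at frame-from-end index `k` was leftward (-1) or
#' rightward (+1). Trials for which `k` is not a valid step frame (too
#' close to, or after, the end of the movement) are omitted from both
#' groups. Because all other steps are independent of the step at `k`,
#' the two groups differ systematically only in the perturbation from
#' frame `k` onward — the premise of the reverse-correlation estimator.
#'
#' @param trials An `rc_session` or list of annotated `rc_trial`s.
#' @param k Frame-from-end index.
#' @param perturb_type `"target"` or `"cursor"`.
#' @param cfg A [session_config()].
#' @return List with `left` and `right`: integer vectors of trial ids.
#' @export
split_by_step_direction <- function(trials, k, perturb_type, cfg) {
  trials <- as_trial_list(trials)
  left <- c()
  right <- c()
  for (tr in trials) {
    if (tr$perturb_type != perturb_type || isTRUE(tr$excluded) ||
      is.null(tr$movement_end)) {
      next
    }
    if (!(k %in% valid_step_frames(tr, cfg))) next
    f <- tr$movement_end$last_sync_frame - k
    d <- tr$frames$step_dir[match(f, tr$frames$frame)]
    if (d < 0) left <- c(left, tr$trial_id) else right <- c(right, tr$trial_id)
  }
  list(left = left, right = right)
}

as_trial_list <- function(trials) {
  if (inherits(trials, "rc_session")) trials$trials else trials
}

# Per-trial quantities reused across all (perturb_type, k) combinations:
# the SG acceleration series is computed once per trial.
trial_cache <- function(trials, cfg) {
  purrr::map(trials, function(tr) {
    if (isTRUE(tr$excluded) || is.null(tr$movement_end)) {
      return(NULL)
    }
    list(
      ptype = tr$perturb_type,
      acc = savgol_series(tr$samples$x, cfg),
      t0 = tr$samples$t[1L],
      n = nrow(tr$samples),
      end_time = tr$movement_end$end_time,
      last_sync = tr$movement_end$last_sync_frame,
      dirs = tr$frames$step_dir
    )
  })
}

# Difference-of-conditional-means curve for one (perturb_type, k), from a
# trial cache. Returns NULL when either direction group is empty.
curve_from_cache <- function(cache, k, perturb_type, cfg) {
  floor_s <- cfg$latency_floor / 1000
  sel <- purrr::keep(cache, function(ci) {
    !is.null(ci) && ci$ptype == perturb_type && ci$last_sync >= k &&
      ci$end_time - (ci$last_sync - k) / cfg$frame_rate > floor_s
  })
  if (!length(sel)) {
    return(NULL)
  }
  dirs <- vapply(sel, function(ci) ci$dirs[ci$last_sync - k + 1L], numeric(1))
  if (all(dirs > 0) || all(dirs < 0)) {
    return(NULL)
  }
  L <- as.integer(round(cfg$response_window / 1000 * cfg$sample_rate))
  V <- vapply(sel, function(ci) {
    t_frame <- (ci$last_sync - k) / cfg$frame_rate
    c0 <- as.integer(round((t_frame - ci$t0) * cfg$sample_rate)) + 1L
    idx <- c0 + 0:L
    v <- rep(NA_real_, L + 1L)
    ok <- idx >= 1L & idx <= ci$n
    # the curve never extends past the end of this trial's movement
    ok[ok] <- ci$t0 + (idx[ok] - 1L) / cfg$sample_rate <= ci$end_time + 1e-9
    v[ok] <- ci$acc[idx[ok]]
    v
  }, numeric(L + 1L))
  left <- dirs < 0
  mstat <- function(M) {
    n <- rowSums(!is.na(M))
    m <- rowMeans(M, na.rm = TRUE)
    ss <- rowSums(M^2, na.rm = TRUE)
    v <- (ss - n * m^2) / pmax(n - 1, 1)
    list(n = n, m = m, v = pmax(v, 0))
  }
  gl <- mstat(V[, left, drop = FALSE])
  gr <- mstat(V[, !left, drop = FALSE])
  keep <- gl$n >= 1 & gr$n >= 1
  if (!any(keep)) {
    return(NULL)
  }
  s <- if (perturb_type == "target") 1 else -1
  tbe <- vapply(
    sel,
    function(ci) ci$end_time - (ci$last_sync - k) / cfg$frame_rate,
    numeric(1)
  )
  tibble::tibble(
    perturb_type = perturb_type,
    k = as.integer(k),
    step_time_before_end_ms = mean(tbe) * 1000,
    lag_ms = (0:L)[keep] / cfg$sample_rate * 1000,
    value = s * (gr$m - gl$m)[keep],
    se = sqrt(gl$v / pmax(gl$n, 1) + gr$v / pmax(gr$n, 1))[keep],
    n_left = as.integer(gl$n[keep]),
    n_right = as.integer(gr$n[keep])
  )
}

#' Response kernel for steps at one moment of the movement
#'
#' The core reverse-correlation computation: for the chosen perturbation
#' type and frame-from-end index `k`, trials are split by the direction of
#' the step at `k`, the Savitzky-Golay lateral acceleration of each trial
#' is read out at every lag of the response window after the step, and the
#' curve is the difference between the unweighted group means
#' (rightward-step group minus leftward-step group). The sign is flipped
#' for cursor trials so that compensatory responses — accelerating in the
#' direction of a target step, or opposite to a cursor step — are positive
#' for both types. Lags whose sample window is unavailable in a trial
#' (past the end of that trial's movement, or without a complete smoothing
#' window) drop that trial from that lag's mean.
#'
#' @param trials An `rc_session` or list of annotated `rc_trial`s.
#' @param k Frame-from-end index of the selected step.
#' @param perturb_type `"target"` or `"cursor"`.
#' @param cfg A [session_config()].
#' @return A tibble with columns `perturb_type`, `k`,
#'   `step_time_before_end_ms` (mean actual time from the step to the end
#'   across contributing trials), `lag_ms`, `value` (mm/s^2,
#'   compensatory-positive), `se` (Monte-Carlo standard error of the
#'   difference of means), `n_left`, `n_right`; or `NULL` when either
#'   direction group is empty (the curve is undefined, not zero).
#' @export
response_curve <- function(trials, k, perturb_type = c("target", "cursor"),
                           cfg = NULL) {
  perturb_type <- match.arg(perturb_type)
  if (is.null(cfg) && inherits(trials, "rc_session")) cfg <- trials$config
  stopifnot(inherits(cfg, "session_config"))
  cache <- trial_cache(as_trial_list(trials), cfg)
  curve_from_cache(cache, k, perturb_type, cfg)
}

#' All response kernels of a session
#'
#' Computes the response curve for every perturbation type and every
#' frame-from-end index at which the curve is defined, reusing the same
#' trials across all step moments. Undefined curves (empty direction
#' group) are simply absent from the output.
#'
#' @param session An annotated `rc_session` (or list of trials).
#' @param cfg A [session_config()].
#' @return A tibble (class `rc_kernels`) stacking the columns of
#'   [response_curve()] for all defined `(perturb_type, k)`.
#' @export
kernel_matrix <- function(session, cfg = NULL) {
  if (is.null(cfg) && inherits(session, "rc_session")) cfg <- session$config
  stopifnot(inherits(cfg, "session_config"))
  trials <- as_trial_list(session)
  cache <- trial_cache(trials, cfg)
  live <- purrr::compact(cache)
  if (!length(live)) {
    stop("kernel_matrix: no annotated, non-excluded trials", call. = FALSE)
  }
  k_max <- max(vapply(live, function(ci) ci$last_sync, numeric(1)))
  out <- list()
  for (ptype in c("target", "cursor")) {
    for (k in 0:k_max) {
      cv <- curve_from_cache(cache, k, ptype, cfg)
      if (!is.null(cv)) out[[length(out) + 1L]] <- cv
    }
  }
  if (!length(out)) {
    stop("kernel_matrix: no response curve is defined for this session",
      call. = FALSE
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("rc_kernels", class(res))
  attr(res, "config") <- cfg
  res
}

#' Average kernels across sessions
#'
#' Unweighted mean of curve values over sessions, by perturbation type,
#' frame-from-end index and lag (the across-participant averaging used
#' when several sessions estimate the same kernels). The standard error
#' column becomes the standard error of the across-session mean.
#'
#' @param kernel_list List of `rc_kernels` tibbles from [kernel_matrix()].
#' @return An `rc_kernels` tibble; `n_sessions` counts contributing
#'   sessions per row.
#' @export
aggregate_kernels <- function(kernel_list) {
  stopifnot(length(kernel_list) >= 1L)
  all <- dplyr::bind_rows(kernel_list, .id = ".session")
  res <- all |>
    dplyr::group_by(.data$perturb_type, .data$k, .data$lag_ms) |>
    dplyr::summarise(
      step_time_before_end_ms = mean(.data$step_time_before_end_ms),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      value = mean(.data$value),
      n_left = sum(.data$n_left),
      n_right = sum(.data$n_right),
      n_sessions = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(
      "perturb_type", "k", "step_time_before_end_ms", "lag_ms",
      "value", "se", "n_left", "n_right", "n_sessions"
    )
  class(res) <- c("rc_kernels", class(res))
  attr(res, "config") <- attr(kernel_list[[1L]], "config")
  res
}
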