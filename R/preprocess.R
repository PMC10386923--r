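#' Find the end of the movement
#'
#' The end of the movement is the (linearly interpolated) first moment the
#' finger crosses the target's path, i.e. the horizontal line through the
#' target centre. When the finger stops short of the path, the moment of
#' maximal Euclidean distance from the start point is used instead,
#' provided the closest approach to the path is within
#' `cfg$near_path_threshold` (2 cm by default); otherwise the trial is
#' excluded because the movement never came close enough to the target's
#' path to define a meaningful remaining time.
#'
#' @param trial An `rc_trial`.
#' @param cfg A [session_config()].
#' @return A `movement_end` list with `end_time` (s), `end_kind`
#'   (`"crossed_path"` or `"max_distance"`) and `last_sync_frame` (index of
#'   the last display frame at or before `end_time`, so 0-17 ms before the
#'   end at 60 Hz), or `NULL` when the trial is excluded.
#' @export
find_movement_end <- function(trial, cfg) {
  stopifnot(inherits(trial, "rc_trial"), inherits(cfg, "session_config"))
  s <- trial$samples
  if (nrow(s) < 2L) {
    stop("find_movement_end: trial needs at least 2 finger samples",
      call. = FALSE
    )
  }
  py <- cfg$target_start[2]
  above <- s$y >= py
  if (any(above)) {
    j <- which(above)[1L]
    if (j == 1L) {
      end_time <- s$t[1L]
    } else {
      # first crossing, linearly interpolated between the two samples
      f <- (py - s$y[j - 1L]) / (s$y[j] - s$y[j - 1L])
      end_time <- s$t[j - 1L] + f * (s$t[j] - s$t[j - 1L])
    }
    kind <- "crossed_path"
  } else {
    if (min(abs(s$y - py)) >= cfg$near_path_threshold) {
      return(NULL)
    }
    end_time <- s$t[which.max(sqrt(s$x^2 + s$y^2))]
    kind <- "max_distance"
  }
  last_frame <- floor(end_time * cfg$frame_rate + 1e-9)
  last_frame <- min(last_frame, max(trial$frames$frame))
  structure(
    list(
      end_time = end_time, end_kind = kind,
      last_sync_frame = as.integer(last_frame)
    ),
    class = "movement_end"
  )
}

#' Annotate every trial of a session with its movement end
#'
#' Every trial is either annotated or explicitly marked excluded; nothing
#' is dropped silently.
#'
#' @param session An `rc_session`.
#' @param cfg A [session_config()]; defaults to the session's own.
#' @return The session with `movement_end` (or `excluded = TRUE`) filled in
#'   on each trial.
#' @export
annotate_session <- function(session, cfg = session$config) {
  stopifnot(inherits(session, "rc_session"))
  session$trials <- purrr::map(session$trials, function(tr) {
    me <- find_movement_end(tr, cfg)
    if (is.null(me)) {
      tr$movement_end <- NULL
      tr$excluded <- TRUE
    } else {
      tr$movement_end <- me
      tr$excluded <- FALSE
    }
    tr
  })
  session
}

#' Index display frames backward from the end of the movement
#'
#' Frames are counted backward from the last frame at or before the end of
#' the movement: `k = 0` is that frame, `k = 1` the one before, and so on
#' down to the frame at target appearance. Synchronising trials on these
#' frame-from-end indices aligns the display steps across trials even
#' though the movement ends themselves fall anywhere within a frame.
#'
#' @param trial An annotated `rc_trial`.
#' @param end A `movement_end` (defaults to the trial's annotation).
#' @return A tibble with columns `k`, `frame`, `t` (s), `step_dir`, and
#'   `time_before_end` (s, `end_time - t`), ordered by increasing `k`.
#' @export
frame_indices_from_end <- function(trial, end = trial$movement_end) {
  stopifnot(inherits(trial, "rc_trial"))
  if (is.null(end)) {
    stop("frame_indices_from_end: trial has no movement end annotation",
      call. = FALSE
    )
  }
  if (end$end_time < trial$frames$t[1L]) {
    stop("frame_indices_from_end: end_time precedes the first frame",
      call. = FALSE
    )
  }
  fr <- trial$frames[trial$frames$frame <= end$last_sync_frame, ]
  tibble::tibble(
    k = end$last_sync_frame - fr$frame,
    frame = fr$frame,
    t = fr$t,
    step_dir = fr$step_dir,
    time_before_end = end$end_time - fr$t
  )[order(end$last_sync_frame - fr$frame), ]
}

#' Savitzky-Golay lateral acceleration at one moment
#'
#' Estimates acceleration by least-squares fitting a second-order
#' polynomial to the position samples within a fixed-width window centred
#' on the moment of interest and taking twice its quadratic coefficient —
#' simultaneous smoothing and double differentiation (a Savitzky-Golay
#' second-derivative filter). Because the quadratic coefficient of a
#' least-squares polynomial is invariant under shifts of the time axis, the
#' window is centred on the sample nearest `center_time`. Moments whose
#' window is not fully covered by samples are dropped (`NA`), never padded.
#'
#' @param positions Lateral positions, mm, sampled at `cfg$sample_rate`.
#' @param times Sample times, s (uniform grid).
#' @param center_time Moment(s) at which to evaluate the acceleration, s.
#'   Vectorised.
#' @param cfg A [session_config()] (supplies `savgol_window`,
#'   `savgol_polyorder`, `sample_rate`).
#' @return Acceleration(s), mm/s^2; `NA` where the window is incomplete.
#' @examples
#' cfg <- session_config()
#' t <- seq(0, 0.2, by = 1 / cfg$sample_rate)
#' savgol_acceleration(100 * t^2, t, 0.1, cfg) # 200 mm/s^2, exact
#' @export
savgol_acceleration <- function(positions, times, center_time, cfg) {
  stopifnot(inherits(cfg, "session_config"))
  n <- length(positions)
  if (length(times) != n) {
    stop("savgol_acceleration: `positions` and `times` lengths differ",
      call. = FALSE
    )
  }
  acc <- savgol_series(positions, cfg)
  idx <- round((center_time - times[1L]) * cfg$sample_rate) + 1L
  out <- rep(NA_real_, length(center_time))
  ok <- idx >= 1L & idx <= n
  out[ok] <- acc[idx[ok]]
  out
}

# Full-series SG second derivative; NA on the `h` edge samples each side
# where no complete window exists.
savgol_series <- function(positions, cfg) {
  h <- savgol_half_width(cfg)
  n_win <- 2L * h + 1L
  n <- length(positions)
  if (n < n_win) {
    return(rep(NA_real_, n))
  }
  flt <- signal::sgolay(
    p = cfg$savgol_polyorder, n = n_win, m = 2,
    ts = 1 / cfg$sample_rate
  )
  acc <- signal::filter(flt, positions)
  # signal::filter applies boundary fits from the sgolay matrix; the edge
  # policy here is to drop instead
  acc[c(seq_len(h), (n - h + 1L):n)] <- NA_real_
  as.numeric(acc)
}

#' Least-squares affine calibration between two point sets
#'
#' Fits the 2-D affine transform (2 x 2 linear part plus translation)
#' mapping measured marker positions onto screen positions, in the
#' least-squares sense — the standard four-point spatial calibration in
#' which participants place their finger on known screen targets.
#'
#' @param measured_points,screen_points Matrices (or data frames) with one
#'   2-D point per row; at least 3 non-collinear correspondences.
#' @return A `calibration_transform`: list with `A` (2 x 2), `b` (length
#'   2), `residuals` (per-point), and `rms` (mm). Apply with
#'   [apply_calibration()].
#' @export
calibrate_affine <- function(measured_points, screen_points) {
  M <- as.matrix(measured_points)
  S <- as.matrix(screen_points)
  if (ncol(M) != 2L || ncol(S) != 2L || nrow(M) != nrow(S)) {
    stop("calibrate_affine: point sets must be n x 2 with equal n",
      call. = FALSE
    )
  }
  if (nrow(M) < 3L) {
    stop("calibrate_affine: need at least 3 point correspondences",
      call. = FALSE
    )
  }
  X <- cbind(M, 1)
  if (qr(X)$rank < 3L) {
    stop("calibrate_affine: calibration points are collinear", call. = FALSE)
  }
  beta <- qr.solve(X, S) # 3 x 2: rows = (a1, a2, b) per output coordinate
  fitted <- X %*% beta
  res <- sqrt(rowSums((S - fitted)^2))
  structure(
    list(
      A = t(beta[1:2, , drop = FALSE]),
      b = as.numeric(beta[3L, ]),
      residuals = res,
      rms = sqrt(mean(res^2))
    ),
    class = "calibration_transform"
  )
}

#' Apply a calibration transform to points
#'
#' @param transform A `calibration_transform` from [calibrate_affine()].
#' @param points An n x 2 matrix of points.
#' @return The transformed n x 2 matrix.
#' @export
apply_calibration <- function(transform, points) {
  P <- as.matrix(points)
  sweep(P %*% t(transform$A), 2L, -transform$b)
}
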