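#' Read a response curve out at one lag after the step
#'
#' @param curve A single-curve tibble from [response_curve()] (or one
#'   `(perturb_type, k)` slice of [kernel_matrix()] output).
#' @param lag Lag after the step, ms. Exact grid points are looked up;
#'   off-grid lags inside the curve are linearly interpolated.
#' @return Acceleration, mm/s^2; `NA` when the lag lies beyond the curve's
#'   truncation (the movement ended before that lag).
#' @export
response_at_lag <- function(curve, lag) {
  if (is.null(curve) || nrow(curve) == 0L) {
    return(NA_real_)
  }
  hit <- which(abs(curve$lag_ms - lag) < 1e-9)
  if (length(hit)) {
    return(curve$value[hit[1L]])
  }
  if (lag < min(curve$lag_ms) || lag > max(curve$lag_ms)) {
    return(NA_real_)
  }
  stats::approx(curve$lag_ms, curve$value, xout = lag)$y
}

#' Through-origin comparison of cursor versus target responses
#'
#' If the vigour of the response grows in the same way during the movement
#' for the cursor as for the target, plotting the cursor response against
#' the target response across step moments gives points on a straight line
#' through the origin, with slope equal to the cursor/target vigour ratio.
#' If the cursor response instead grows disproportionately late in the
#' movement, the points bend upward. This fit quantifies both: the
#' through-origin least-squares slope, and a curvature index — the
#' quadratic coefficient `b` of the through-origin fit
#' `cursor ~ a * target + b * target^2` — with a bootstrap confidence
#' interval from resampling the step-moment pairs.
#'
#' @param pairs A data frame with columns `target` and `cursor` (response
#'   values at one lag, mm/s^2), one row per step moment.
#' @param n_boot Bootstrap replicates for the curvature interval.
#' @param conf Confidence level of the percentile interval.
#' @param seed Optional seed for the bootstrap.
#' @return List with `origin_slope`, `curvature_index`, `curvature_ci`
#'   (length 2), `n_pairs`, and the bootstrap draws `boot_curvature`.
#' @examples
#' p <- data.frame(target = 1:10, cursor = 0.6 * (1:10))
#' origin_line_fit(p, n_boot = 200, seed = 1)$origin_slope # 0.6
#' @export
origin_line_fit <- function(pairs, n_boot = 2000, conf = 0.95, seed = NULL) {
  pairs <- pairs[stats::complete.cases(pairs[, c("target", "cursor")]), ]
  if (nrow(pairs) < 3L) {
    stop("origin_line_fit: need at least 3 (target, cursor) pairs",
      call. = FALSE
    )
  }
  tt <- pairs$target
  cc <- pairs$cursor
  if (all(tt == 0)) {
    stop("origin_line_fit: slope undefined, all target responses are zero",
      call. = FALSE
    )
  }
  slope <- sum(tt * cc) / sum(tt^2)
  quad_b <- function(t, c) {
    X <- cbind(t, t^2)
    as.numeric(qr.solve(crossprod(X), crossprod(X, c))[2L])
  }
  b <- quad_b(tt, cc)
  run_boot <- function() {
    vapply(seq_len(n_boot), function(i) {
      j <- sample.int(length(tt), replace = TRUE)
      if (all(tt[j] == 0) || length(unique(tt[j])) < 2L) {
        return(c(NA_real_, NA_real_))
      }
      c(
        sum(tt[j] * cc[j]) / sum(tt[j]^2),
        tryCatch(quad_b(tt[j], cc[j]), error = function(e) NA_real_)
      )
    }, numeric(2))
  }
  bs <- if (is.null(seed)) run_boot() else withr::with_seed(seed, run_boot())
  ci <- stats::quantile(bs[2L, ], c((1 - conf) / 2, 1 - (1 - conf) / 2),
    na.rm = TRUE, names = FALSE
  )
  list(
    origin_slope = slope, curvature_index = b, curvature_ci = ci,
    slope_se = stats::sd(bs[1L, ], na.rm = TRUE),
    n_pairs = nrow(pairs),
    boot_slope = bs[1L, ], boot_curvature = bs[2L, ]
  )
}

#' Per-step-time vigour values and the cursor-vs-target comparison
#'
#' Reduces a kernel set to vigour read-outs at a few fixed lags after the
#' step (160, 170 and 180 ms by default), pairs the target and cursor
#' values per step moment, and fits the through-origin line and curvature
#' index at each lag. Step moments where either curve is undefined at a
#' lag are dropped pairwise.
#'
#' Step moments contributing very few trials at a lag — those later than
#' most movements ever lasted, or truncated for most trials — produce
#' noise-dominated read-outs. A pair is therefore kept only where, for
#' both perturbation types, the number of trials contributing at that lag
#' is at least `min_count_frac` of the maximum contributing count over
#' step moments for that type and lag (the moments at which responses are
#' clearly estimable).
#'
#' @param kernels An `rc_kernels` tibble from [kernel_matrix()] or
#'   [aggregate_kernels()].
#' @param lags Lags after the step, ms.
#' @param min_count_frac Minimum fraction of the per-lag maximum trial
#'   count required for a step moment to enter the pair set (see Details).
#' @param n_boot,conf,seed Passed to [origin_line_fit()].
#' @return A `vigour_summary`: list with `pairs` (tibble: `lag_ms`, `k`,
#'   `step_time_before_end_ms`, `target`, `cursor`) and `fits` (tibble:
#'   `lag_ms`, `origin_slope`, `slope_se`, `curvature_index`,
#'   `curvature_lo`, `curvature_hi`, `n_pairs`).
#' @export
vigour_summary <- function(kernels, lags = c(160, 170, 180),
                           min_count_frac = 0.5,
                           n_boot = 2000, conf = 0.95, seed = NULL) {
  stopifnot(inherits(kernels, "rc_kernels") || is.data.frame(kernels))
  ks <- sort(unique(kernels$k))
  pair_rows <- list()
  for (lag in lags) {
    rows_at <- function(ptype, k) {
      kernels[kernels$perturb_type == ptype & kernels$k == k, ]
    }
    count_at <- function(cur, lag) {
      i <- which(abs(cur$lag_ms - lag) < 1e-9)
      if (!length(i)) {
        return(0)
      }
      as.numeric(cur$n_left[i[1L]] + cur$n_right[i[1L]])
    }
    counts <- lapply(c(target = "target", cursor = "cursor"), function(pt) {
      vapply(ks, function(k) count_at(rows_at(pt, k), lag), numeric(1))
    })
    min_n <- lapply(counts, function(nn) min_count_frac * max(nn))
    for (ik in seq_along(ks)) {
      k <- ks[ik]
      if (counts$target[ik] < min_n$target ||
        counts$cursor[ik] < min_n$cursor) {
        next
      }
      tcur <- rows_at("target", k)
      ccur <- rows_at("cursor", k)
      tv <- response_at_lag(tcur, lag)
      cv <- response_at_lag(ccur, lag)
      if (is.na(tv) || is.na(cv)) next
      pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
        lag_ms = lag, k = k,
        step_time_before_end_ms = mean(c(
          tcur$step_time_before_end_ms[1L],
          ccur$step_time_before_end_ms[1L]
        )),
        target = tv, cursor = cv
      )
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  fits <- purrr::map_dfr(lags, function(lag) {
    p <- pairs[pairs$lag_ms == lag, ]
    if (nrow(p) < 3L) {
      return(tibble::tibble(
        lag_ms = lag, origin_slope = NA_real_, slope_se = NA_real_,
        curvature_index = NA_real_,
        curvature_lo = NA_real_, curvature_hi = NA_real_,
        n_pairs = nrow(p)
      ))
    }
    f <- origin_line_fit(p, n_boot = n_boot, conf = conf, seed = seed)
    tibble::tibble(
      lag_ms = lag, origin_slope = f$origin_slope, slope_se = f$slope_se,
      curvature_index = f$curvature_index,
      curvature_lo = f$curvature_ci[1L], curvature_hi = f$curvature_ci[2L],
      n_pairs = f$n_pairs
    )
  })
  structure(list(pairs = pairs, fits = fits), class = "vigour_summary")
}

#' @export
print.vigour_summary <- function(x, ...) {
  cat("<vigour_summary>\n")
  print(x$fits)
  invisible(x)
}

#' Session-level performance statistics
#'
#' Hit fraction, end-of-movement time moments and trial counts per
#' perturbation type, over non-excluded trials.
#'
#' @param session An annotated `rc_session`.
#' @param cfg Unused placeholder for interface symmetry.
#' @return A tibble with one row per perturbation type: `n_trials`,
#'   `n_excluded`, `hit_fraction`, `end_time_mean_ms`, `end_time_sd_ms`.
#' @export
session_summary <- function(session, cfg = session$config) {
  stopifnot(inherits(session, "rc_session"))
  trials <- session$trials
  if (!length(trials)) {
    stop("session_summary: session has no trials", call. = FALSE)
  }
  rows <- purrr::map_dfr(c("target", "cursor"), function(ptype) {
    sel <- purrr::keep(trials, function(tr) tr$perturb_type == ptype)
    kept <- purrr::keep(sel, function(tr) !isTRUE(tr$excluded) &&
      !is.null(tr$movement_end))
    ends <- vapply(kept, function(tr) tr$movement_end$end_time, numeric(1))
    hits <- vapply(kept, function(tr) isTRUE(tr$hit), logical(1))
    tibble::tibble(
      perturb_type = ptype,
      n_trials = length(kept),
      n_excluded = length(sel) - length(kept),
      hit_fraction = if (length(kept)) mean(hits) else NA_real_,
      end_time_mean_ms = if (length(kept)) mean(ends) * 1000 else NA_real_,
      end_time_sd_ms = if (length(kept) > 1L) stats::sd(ends) * 1000 else NA_real_
    )
  })
  rows
}
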