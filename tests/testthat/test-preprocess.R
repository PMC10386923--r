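test_that("path crossings are linearly interpolated to the end time", {
  cfg <- default_cfg
  t <- seq(0, 0.6, by = 1 / cfg$sample_rate)
  # linear approach crossing y = 200 exactly midway between 0.548 and 0.550
  y <- approx(c(0, 0.548, 0.550, 0.6), c(0, 195, 205, 240), t)$y
  tr <- make_trial(t, x = -t * 100, y = y)
  me <- find_movement_end(tr, cfg)
  expect_equal(me$end_kind, "crossed_path")
  expect_equal(me$end_time, 0.549, tolerance = 1e-9)
  expect_equal(me$last_sync_frame, 32L) # 32/60 = 0.5333 <= 0.549 < 0.55
})

test_that("movements stopping just short of the path end at maximal distance", {
  cfg <- default_cfg
  t <- seq(0, 0.8, by = 1 / cfg$sample_rate)
  # peak at y = 185 mm (15 mm short of the path) at t = 0.5, then retreat
  y <- 185 * sin(pmin(t / 0.5, 1.4) * pi / 2)
  tr <- make_trial(t, x = rep(0, length(t)), y = y)
  me <- find_movement_end(tr, cfg)
  expect_equal(me$end_kind, "max_distance")
  expect_equal(me$end_time, 0.5, tolerance = 2.1 / cfg$sample_rate)
})

test_that("movements far short of the path are excluded, never silently dropped", {
  cfg <- default_cfg
  t <- seq(0, 0.8, by = 1 / cfg$sample_rate)
  y <- 150 * sin(pmin(t / 0.5, 1.4) * pi / 2) # peaks 50 mm short
  tr <- make_trial(t, x = rep(0, length(t)), y = y)
  expect_null(find_movement_end(tr, cfg))
  ses <- structure(
    list(
      session_id = "s", config = cfg, model = NULL,
      trials = list(tr)
    ),
    class = "rc_session"
  )
  ann <- annotate_session(ses)
  expect_true(ann$trials[[1]]$excluded)
})

test_that("the last synchronised frame is 0-17 ms before the end", {
  cfg <- default_cfg
  ses <- simulate_session(cfg, feedback_model(), 30, seed = 12)
  ses <- annotate_session(ses)
  for (tr in ses$trials) {
    me <- tr$movement_end
    if (is.null(me)) next
    gap <- me$end_time - me$last_sync_frame / cfg$frame_rate
    expect_gte(gap, 0)
    expect_lt(gap, 1 / cfg$frame_rate)
  }
})

test_that("backward frame indexing counts from the last synchronised frame", {
  cfg <- default_cfg
  t <- seq(0, 1, by = 1 / cfg$sample_rate)
  tr <- make_trial(t, x = t, y = 400 * t) # crosses early
  me <- structure(
    list(
      end_time = 0.580, end_kind = "crossed_path",
      last_sync_frame = 34L
    ),
    class = "movement_end"
  )
  fi <- frame_indices_from_end(tr, me)
  expect_equal(fi$k[fi$frame == 34L], 0L)
  expect_equal(fi$t[fi$k == 0L], 34 / 60) # 0.5667 s, 13.3 ms before end
  expect_equal(nrow(fi), 35L) # every frame back to target appearance
  expect_equal(fi$k, 0:34)
  # an end exactly on a frame time makes that frame k = 0
  me2 <- structure(
    list(
      end_time = 30 / 60, end_kind = "crossed_path",
      last_sync_frame = 30L
    ),
    class = "movement_end"
  )
  fi2 <- frame_indices_from_end(tr, me2)
  expect_equal(fi2$time_before_end[fi2$k == 0L], 0)
})

test_that("savgol acceleration is exact on polynomials of degree <= 2", {
  cfg <- default_cfg
  t <- seq(0, 0.4, by = 1 / cfg$sample_rate)
  quad <- 250000 * t^2
  a <- savgol_acceleration(quad, t, c(0.1, 0.2, 0.3), cfg)
  expect_equal(a, rep(500000, 3), tolerance = 1e-9)
  lin <- 5000 * t + 3
  expect_equal(
    savgol_acceleration(lin, t, c(0.1, 0.25), cfg),
    c(0, 0),
    tolerance = 1e-6
  )
  mixed <- 2 + 7 * t - 900 * t^2
  expect_equal(
    savgol_acceleration(mixed, t, 0.2, cfg), -1800,
    tolerance = 1e-9
  )
})

test_that("savgol acceleration matches a normal-equations quadratic fit", {
  cfg <- default_cfg
  t <- seq(0, 0.5, by = 1 / cfg$sample_rate)
  x <- withr::with_seed(4, 30 * sin(12 * t) + rnorm(length(t), 0, 0.5))
  for (ct in c(0.07, 0.2012, 0.333, 0.46)) {
    expect_equal(
      savgol_acceleration(x, t, ct, cfg),
      brute_accel(x, t, ct, cfg),
      tolerance = 1e-8
    )
  }
})

test_that("savgol acceleration is linear in its input", {
  cfg <- default_cfg
  t <- seq(0, 0.3, by = 1 / cfg$sample_rate)
  a <- withr::with_seed(5, rnorm(length(t)))
  b <- withr::with_seed(6, rnorm(length(t)))
  expect_equal(
    savgol_acceleration(2 * a + 3 * b, t, 0.15, cfg),
    2 * savgol_acceleration(a, t, 0.15, cfg) +
      3 * savgol_acceleration(b, t, 0.15, cfg),
    tolerance = 1e-8
  )
})

test_that("incomplete smoothing windows are dropped, not padded", {
  cfg <- default_cfg
  t <- seq(0, 0.1, by = 1 / cfg$sample_rate)
  x <- 100 * t^2
  expect_true(is.na(savgol_acceleration(x, t, 0.002, cfg))) # near start
  expect_true(is.na(savgol_acceleration(x, t, 0.099, cfg))) # near end
  expect_true(is.na(savgol_acceleration(x, t, 0.5, cfg))) # outside
  expect_false(is.na(savgol_acceleration(x, t, 0.05, cfg)))
})

test_that("affine calibration recovers exact transforms", {
  pts <- matrix(c(0, 0, 100, 0, 0, 100, 100, 100), ncol = 2, byrow = TRUE)
  shifted <- sweep(pts, 2, c(-5, 3), FUN = "+")
  cal <- calibrate_affine(pts, shifted)
  expect_equal(cal$A, diag(2), tolerance = 1e-10)
  expect_equal(cal$b, c(-5, 3), tolerance = 1e-10)
  # 90 degree rotation + scale 2
  R <- 2 * matrix(c(0, -1, 1, 0), 2, 2, byrow = TRUE)
  rot <- t(R %*% t(pts))
  cal2 <- calibrate_affine(pts, rot)
  expect_equal(cal2$A, R, tolerance = 1e-10)
  expect_equal(cal2$b, c(0, 0), tolerance = 1e-10)
  expect_equal(apply_calibration(cal2, pts), rot, tolerance = 1e-10)
})

test_that("noisy calibration residuals equal the closed-form least squares", {
  pts <- matrix(c(0, 0, 120, 10, 15, 110, 130, 140), ncol = 2, byrow = TRUE)
  target <- withr::with_seed(
    10,
    t(matrix(c(1.02, 0.05, -0.03, 0.97), 2, 2) %*% t(pts)) +
      matrix(rnorm(8, 0, 2), ncol = 2) + 7
  )
  cal <- calibrate_affine(pts, target)
  # independent normal-equations oracle
  X <- cbind(pts, 1)
  beta <- solve(t(X) %*% X, t(X) %*% target)
  res <- sqrt(rowSums((target - X %*% beta)^2))
  expect_equal(cal$residuals, res, tolerance = 1e-9)
})

test_that("degenerate calibration inputs are rejected", {
  line <- cbind(1:4, 2 * (1:4))
  expect_error(calibrate_affine(line, line), "collinear")
  expect_error(calibrate_affine(line[1:2, ], line[1:2, ]), "at least 3")
  expect_error(calibrate_affine(line, line[1:3, ]), "equal n")
})
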