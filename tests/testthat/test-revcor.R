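# Build a trial whose movement end is pinned exactly, to probe the
# time-based step filter.
pinned_trial <- function(end_time, cfg = default_cfg, step_dir = NULL,
                         trial_id = 1L, perturb_type = "target") {
  t <- seq(0, ceiling(end_time * 10) / 10 + 0.3, by = 1 / cfg$sample_rate)
  y <- cfg$target_start[2] * t / end_time # crosses the path at end_time
  tr <- make_trial(t, x = rep(0, length(t)), y = y,
    cfg = cfg, step_dir = step_dir, trial_id = trial_id,
    perturb_type = perturb_type
  )
  tr$movement_end <- find_movement_end(tr, cfg)
  tr
}

test_that("the step filter is strict at 100 ms and uses actual times", {
  cfg <- default_cfg
  # end exactly on a frame: k frames are k/60 s before the end
  tr <- pinned_trial(30 / 60)
  ks <- valid_step_frames(tr, cfg)
  # k = 6 is exactly 100 ms before the end: excluded (strictly greater)
  expect_false(6 %in% ks)
  expect_true(7 %in% ks) # 116.7 ms
  expect_false(5 %in% ks) # 83 ms
  # end mid-frame: the same k sits further from the end and passes
  tr2 <- pinned_trial(30 / 60 + 0.010)
  expect_equal(tr2$movement_end$last_sync_frame, 30L)
  ks2 <- valid_step_frames(tr2, cfg)
  expect_true(6 %in% ks2) # now 110 ms before the end
})

test_that("the k-based and time-based filters are reconciled per trial", {
  cfg <- default_cfg
  ends <- withr::with_seed(21, runif(300, 0.45, 0.75))
  for (e in ends[1:40]) {
    tr <- pinned_trial(e)
    ks <- valid_step_frames(tr, cfg)
    fi <- frame_indices_from_end(tr)
    expect_setequal(ks, fi$k[fi$time_before_end > 0.1])
  }
})

test_that("trials split by step direction with omissions only for invalid k", {
  cfg <- default_cfg
  dirs <- c(-1, -1, -1, 1, 1, 1, 1, -1, 1, -1)
  trials <- lapply(seq_along(dirs), function(i) {
    sd <- rep_len(c(1L, -1L), 40)
    tr <- pinned_trial(30 / 60, trial_id = i)
    # overwrite the direction at k = 10 (frame 20)
    tr$frames$step_dir[tr$frames$frame == 20L] <- dirs[i]
    tr
  })
  sp <- split_by_step_direction(trials, 10, "target", cfg)
  expect_setequal(sp$left, which(dirs < 0))
  expect_setequal(sp$right, which(dirs > 0))
  # invalid k (too close to the end) omits the trial from both groups
  sp5 <- split_by_step_direction(trials, 5, "target", cfg)
  expect_length(sp5$left, 0)
  expect_length(sp5$right, 0)
})

test_that("a one-sided split leaves the curve undefined, not zero", {
  cfg <- default_cfg
  trials <- lapply(1:6, function(i) {
    tr <- pinned_trial(30 / 60, trial_id = i)
    tr$frames$step_dir[tr$frames$frame == 20L] <- 1L
    tr
  })
  expect_null(response_curve(trials, 10, "target", cfg))
  ses1 <- annotate_session(
    simulate_session(cfg, quiet_model(), 2, seed = 1)
  )
  # a single trial per type can never populate both direction groups
  expect_null(response_curve(ses1$trials[1], 12, "target", cfg))
})

test_that("curves equal the brute-force group-means oracle on toy sessions", {
  cfg <- default_cfg
  ses <- annotate_session(
    simulate_session(cfg, feedback_model(motor_noise_sd = 300), 16, seed = 60)
  )
  km <- kernel_matrix(ses)
  for (ptype in c("target", "cursor")) {
    for (k in c(7, 10, 15, 20)) {
      want <- brute_curve(ses$trials, k, ptype, cfg)
      got <- km[km$perturb_type == ptype & km$k == k, ]
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
        next
      }
      expect_equal(got$lag_ms, want$lag_ms, tolerance = 1e-9)
      expect_equal(got$value, want$value, tolerance = 1e-9)
    }
  }
})

test_that("kernels are invariant under trial order and never cross the end", {
  cfg <- default_cfg
  ses <- annotate_session(
    simulate_session(cfg, feedback_model(), 12, seed = 61)
  )
  km1 <- kernel_matrix(ses, cfg)
  shuffled <- ses
  shuffled$trials <- withr::with_seed(1, sample(ses$trials))
  km2 <- kernel_matrix(shuffled, cfg)
  expect_equal(as.data.frame(km1), as.data.frame(km2))
  # truncation: every lag grid stops within the response window and the
  # latest contributing movement end
  ends <- vapply(
    ses$trials,
    function(tr) if (is.null(tr$movement_end)) NA_real_ else tr$movement_end$end_time,
    numeric(1)
  )
  expect_lte(max(km1$lag_ms), cfg$response_window)
  for (i in which(km1$lag_ms == max(km1$lag_ms))) {
    k <- km1$k[i]
    # some trial must reach this lag before its movement end
    t_f <- (vapply(ses$trials, function(tr) {
      if (is.null(tr$movement_end)) {
        return(-Inf)
      }
      (tr$movement_end$last_sync_frame - k) / cfg$frame_rate
    }, numeric(1)))
    expect_true(any(t_f + km1$lag_ms[i] / 1000 <= ends + 1e-9, na.rm = TRUE))
  }
})

test_that("compensatory responses come out positive for both channels", {
  cfg <- default_cfg
  mdl <- feedback_model(motor_noise_sd = 0, duration_sd = 0, cursor_weight = 0.8)
  ses <- annotate_session(simulate_session(cfg, mdl, 60, seed = 62))
  km <- kernel_matrix(ses)
  for (ptype in c("target", "cursor")) {
    cur <- km[km$perturb_type == ptype & km$k == 12, ]
    peak <- cur$value[which.min(abs(cur$lag_ms - 200))]
    expect_gt(peak, 0)
  }
})

test_that("conditioning on one step leaves the other steps balanced", {
  n_seq <- 5000
  dirs <- withr::with_seed(300, {
    vapply(
      seq_len(n_seq),
      function(i) generate_step_sequence(35, 2.5)$directions,
      numeric(35)
    )
  })
  right <- dirs[20, ] > 0
  for (j in c(5, 19, 21, 34)) {
    # mean direction at other frames within binomial error in both groups
    for (g in list(right, !right)) {
      expect_lt(abs(mean(dirs[j, g])), 4 / sqrt(sum(g)))
    }
  }
})

test_that("known-kernel simulations recover the injected response shape", {
  cfg <- default_cfg
  mdl <- feedback_model(motor_noise_sd = 150, cursor_weight = 0.6)
  ses <- annotate_session(simulate_session(cfg, mdl, 400, seed = 500))
  km <- kernel_matrix(ses)
  k <- 13
  cur <- km[km$perturb_type == "target" & km$k == k, ]
  rem <- cur$step_time_before_end_ms[1] / 1000
  lat <- mdl$latency / 1000
  theory <- 2 * cfg$step_amplitude * mdl$target_gain(rem) *
    dgamma(cur$lag_ms / 1000 - lat, mdl$irf_shape, mdl$irf_rate)
  sel <- cur$lag_ms >= 160 & cur$lag_ms <= 240
  # Monte-Carlo agreement at the meaningful part of the kernel
  expect_true(all(abs(cur$value - theory)[sel] <= 4 * cur$se[sel]))
  # cursor curve is scaled by the cursor weight
  ccur <- km[km$perturb_type == "cursor" & km$k == k, ]
  csel <- ccur$lag_ms >= 160 & ccur$lag_ms <= 240
  expect_true(all(
    abs(ccur$value - 0.6 * theory[match(ccur$lag_ms, cur$lag_ms)])[csel] <=
      4 * ccur$se[csel]
  ))
})
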