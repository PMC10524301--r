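# vmd_analysis: divergence statistic, classification, BH, comparisons

test_that("divergence arithmetic, replay identity and zero-running sentinel", {
  # stimulus 13 deg/s vs running-equivalent 10 deg/s -> +0.30
  expect_equal(compute_vmd(13, 5, gain = 2)$divergence, 0.3)
  expect_equal(compute_vmd(rep(20, 10), rep(10, 10), gain = 2)$divergence, 0)
  z <- compute_vmd(10, 0, gain = 2)
  expect_true(is.infinite(z$divergence) && z$flagged)
  expect_equal(classify_trials(z$divergence), "positive")

  # replay of a coupled trial against its own running trace -> exactly 0
  run <- generate_running_trace(400, seed = 5)
  pr <- generate_coupled_replay_trials(run, 8)
  rec <- vmd_records(pr$trials, pr$stimuli, run)
  coup <- rec[rec$stim_type == "coupled", ]
  expect_true(all(coup$divergence == 0))
  expect_true(all(coup$label == "matched"))
})

test_that("the 25% rule classifies +0.30 / -0.30 / +0.10 correctly", {
  expect_equal(classify_trials(c(0.30, -0.30, 0.10)),
               c("positive", "negative", "matched"))
  expect_equal(classify_trials(c(0.25, -0.25)), c("positive", "negative"))
  expect_error(classify_trials(0.3, threshold = 0), "positive")
})

test_that("Benjamini-Hochberg step-up: worked examples and edge cases", {
  out <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(out$reject))  # p_(4) = 0.04 <= 4/4 * 0.05
  out2 <- benjamini_hochberg(c(0.04, 0.04), alpha = 0.05)
  expect_true(all(out2$reject))  # 0.04 <= (2/2) * 0.05
  empty <- benjamini_hochberg(numeric(0))
  expect_length(empty$reject, 0)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  # adjusted p monotone nondecreasing in rank
  set.seed(4)
  p <- runif(20)
  adj <- benjamini_hochberg(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("BH matches brute-force enumeration and stats::p.adjust", {
  set.seed(10)
  for (i in 1:60) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    out <- benjamini_hochberg(p, alpha = 0.05)
    expect_identical(out$reject, bh_bruteforce(p, 0.05))
    expect_equal(out$adjusted, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("time-course normalisation: scaling, truncation, stimulus fraction", {
  tr <- matrix(2, 4, 30)
  out <- normalize_timecourses(tr, v1_coupled_mean = 2, frame_rate = 10,
                               durations_s = c(2, 2, 1.5, 1))
  expect_equal(ncol(out$traces), 17)  # 1.7 s at 10 Hz
  expect_true(all(out$traces == 1))
  expect_equal(out$stim_present_frac[1], 1)
  expect_equal(out$stim_present_frac[17], 0.5)  # 1.6 s: 2 of 4 trials left
  out2 <- normalize_timecourses(tr, 2, 10, durations_s = rep(3, 4))
  expect_true(all(out2$stim_present_frac == 1))
  expect_error(normalize_timecourses(tr, 0, 10), "positive")
})

test_that("coupled/uncoupled comparison: trivial equality and mouse gating", {
  pm <- lapply(1:3, function(i) {
    list(coupled = matrix(1, 5, 1), uncoupled = matrix(1, 4, 1))
  })
  out <- coupled_uncoupled_comparison(pm)
  expect_equal(out$mean_diff, 0)
  expect_equal(out$p_values, 1)
  expect_false(any(out$bh$reject))
  expect_error(coupled_uncoupled_comparison(pm[1]), "2 mice")
})

test_that("VMD selectivity: sensitive areas flagged, V1-like area quiet", {
  mice <- lapply(1:4, simulate_vmd_mouse, s_pos = 0.5, n_pairs = 20)
  for (a in c("POR", "LI")) {
    cmp <- coupled_uncoupled_comparison(vmd_per_mouse(mice, a))
    expect_lt(cmp$summary$p_value, 0.05)
    expect_gt(sum(cmp$bh$reject), 0)
  }
  v1 <- coupled_uncoupled_comparison(vmd_per_mouse(mice, "V1"))
  expect_gt(v1$summary$p_value, 0.05)
})

test_that("divergence binning: flat curves, shape and empty bins", {
  edges <- seq(-1, 1, by = 0.5)
  out <- bin_by_divergence(c(-0.7, 0.1, 0.6), rep(0, 3), edges)
  expect_true(all(out$mean_diff[out$n > 0] == 0))
  expect_true(is.na(out$mean_diff[out$n == 0][1]))

  # s_pos > 0, s_neg = 0: positive bins elevated, negative bins near zero
  mice <- lapply(5:7, simulate_vmd_mouse, s_pos = 0.6, n_pairs = 20)
  div <- c(); dif <- c()
  for (m in mice) {
    rec <- m$records[m$records$stim_type == "uncoupled" &
                       is.finite(m$records$divergence), ]
    tr <- m$traces$POR
    cmean <- mean(rowMeans(tr[m$coupled_idx, , drop = FALSE], na.rm = TRUE))
    u <- rowMeans(tr[as.character(rec$trial_id), , drop = FALSE], na.rm = TRUE)
    div <- c(div, rec$divergence); dif <- c(dif, u - cmean)
  }
  bb <- bin_by_divergence(div, dif, seq(-1.5, 1.5, by = 0.5))
  pos <- bb$mid > 0.25 & bb$n > 2; neg <- bb$mid < -0.25 & bb$n > 2
  expect_gt(sum(pos), 0); expect_gt(sum(neg), 0)
  expect_gt(mean(bb$mean_diff[pos]), mean(bb$mean_diff[neg]) + 0.05)
})

test_that("running-gain check: null vs positive gain", {
  run <- generate_running_trace(800, seed = 21)
  pr <- generate_coupled_replay_trials(run, 30)
  rec <- vmd_records(pr$trials, pr$stimuli, run)
  coup <- pr$trials$stim_type == "coupled"
  speeds <- rec$mean_run_cm_s[match(pr$trials$trial_id[coup], rec$trial_id)]
  for (gamma in c(0, 0.03)) {
    cfg <- ground_truth_config(areas = tiny_layout(1), dims = c(24, 24),
                               gamma = gamma, h_amp = 0, seed = 31)
    s <- generate_widefield_session(cfg, pr$trials, running = run, seed = 32)
    d <- compute_dff(s$signal, pr$trials)
    # fixed-window peak response: insensitive to the speed-dependent trial
    # duration, which would otherwise correlate with speed on its own
    tr <- area_trial_traces(d, area_masks(cfg)$V1, 10L)
    resp <- apply(tr[coup, ], 1, max, na.rm = TRUE)
    out <- running_gain_check(resp, speeds)
    if (gamma == 0) expect_lt(abs(out$rho), 0.35) else expect_gt(out$rho, 0.5)
  }
  expect_error(running_gain_check(1:5, rep(3, 5)), "one running speed")
})

test_that("eye-position control: null offsets and detectable shifts", {
  set.seed(2)
  a <- data.frame(azimuth_deg = rnorm(100, 0, 4.7),
                  elevation_deg = rnorm(100, 0, 1.2))
  b <- data.frame(azimuth_deg = rnorm(100, 0, 4.7),
                  elevation_deg = rnorm(100, 0, 1.2))
  out <- eye_position_control(a, b)
  expect_equal(out$axis, c("azimuth", "elevation"))
  # null offsets small relative to their spread; p not extreme
  expect_true(all(abs(out$offset_mean) < out$offset_sd))
  expect_gt(min(out$p_value), 0.001)
  b$azimuth_deg <- b$azimuth_deg + 5
  out2 <- eye_position_control(a, b)
  expect_lt(out2$p_value[out2$axis == "azimuth"], 0.001)
  expect_error(eye_position_control(a[1, ], b), "2 samples")
})
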