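# synthetic_data: generators are pure functions of (config, seed) with
# recoverable ground truth

test_that("running trace: zero-noise, determinism and parameter errors", {
  r0 <- generate_running_trace(10, mean_speed = 7, sd = 0, seed = 1)
  expect_true(all(r0$speed == 7))

  a <- generate_running_trace(30, seed = 42)
  b <- generate_running_trace(30, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$speed, generate_running_trace(30, seed = 43)$speed))
  expect_true(all(a$speed >= 0))

  expect_error(generate_running_trace(-1), "duration")
  expect_error(generate_running_trace(10, tau = 0), "tau")
})

test_that("running trace mean is unbiased (Monte Carlo over 20 seeds)", {
  # stationary OU: var of the 600 s time average ~ sd^2 * 2 tau / T
  means <- vapply(1:20, function(s) {
    mean(generate_running_trace(600, mean_speed = 10, sd = 3, tau = 2,
                                seed = s)$speed)
  }, 0)
  se <- sqrt(3^2 * 2 * 2 / 600) / sqrt(20)
  expect_lt(abs(mean(means) - 10), 3 * se + 0.05)  # +0.05 for clipping bias
})

test_that("coupled trials integrate running to exactly 40 degrees", {
  run <- generate_running_trace(300, mean_speed = 10, sd = 0, seed = 1)
  pr <- generate_coupled_replay_trials(run, 5, gain = 2)
  coup <- pr$trials[pr$trials$stim_type == "coupled", ]
  expect_equal(nrow(coup), 5)
  # constant 10 cm/s at gain 2 -> 20 deg/s -> 2 s per trial
  expect_equal(coup$duration_s, rep(2, 5))
  expect_true(all(abs(pr$stimuli[[coup$trial_id[1]]]$dot_speed - 20) < 1e-12))
  # travel is exactly 40 deg for every coupled trial, noisy running included
  run2 <- generate_running_trace(600, seed = 7)
  pr2 <- generate_coupled_replay_trials(run2, 8)
  for (id in pr2$trials$trial_id[pr2$trials$stim_type == "coupled"]) {
    st <- pr2$stimuli[[id]]
    expect_equal(sum(st$dot_speed) * 0.1, 40, tolerance = 1e-9)
  }
})

test_that("uncoupled trials replay their source trace verbatim", {
  run <- generate_running_trace(600, seed = 3)
  pr <- generate_coupled_replay_trials(run, 10)
  unc <- pr$trials[pr$trials$stim_type == "uncoupled", ]
  for (i in seq_len(nrow(unc))) {
    expect_identical(pr$stimuli[[unc$trial_id[i]]]$dot_speed,
                     pr$stimuli[[unc$link_id[i]]]$dot_speed)
  }
})

test_that("running trace exhaustion returns fewer pairs with a warning", {
  run <- generate_running_trace(30, mean_speed = 10, sd = 0, seed = 1)
  expect_warning(pr <- generate_coupled_replay_trials(run, 50), "exhausted")
  expect_true(pr$truncated)
  expect_lt(sum(pr$trials$stim_type == "uncoupled"), 50)
})

test_that("widefield generator: silencing, closed-form peak, determinism", {
  tt <- make_trial_table("dot", 2)
  # g = 1 and silenced => evoked component identically 0
  cfg <- tiny_config(g = 1, sigma_noise = 0, h_amp = 0)
  sil <- generate_widefield_session(cfg, make_trial_table("dot", 2, condition = "TTX"))
  expect_true(all(sil$truth$amplitudes == 0))
  expect_true(all(sil$signal$data == cfg$F0))

  # noiseless single trial: peak pixel dF/F equals A exactly
  cfg0 <- tiny_config(A = 0.07, sigma_noise = 0, h_amp = 0)
  s0 <- generate_widefield_session(cfg0, make_trial_table("dot", 1))
  d0 <- compute_dff(s0$signal, s0$trials)
  expect_equal(max(d0$trials_dff[[1]]$dff), 0.07, tolerance = 1e-12)

  s1 <- generate_widefield_session(cfg0, tt, seed = 5)
  s2 <- generate_widefield_session(cfg0, tt, seed = 5)
  expect_identical(s1$signal$data, s2$signal$data)
})

test_that("hemodynamic-only movie: channels identical, evoked never leaks", {
  cfg <- tiny_config(A = 0, sigma_noise = 0, h_amp = 0.02)
  s <- generate_widefield_session(cfg, make_trial_table("dot", 3), seed = 0)
  expect_equal(s$signal$data, s$isosbestic$data, tolerance = 1e-12)

  # channel contract: correlation of the evoked regressor with the
  # isosbestic channel stays < 0.05 (mean |cor| over 5 seeds, sigma_noise=0)
  cors <- vapply(1:5, function(sd) {
    cfg2 <- tiny_config(dims = c(12, 12), sigma_noise = 0, h_amp = 0.01)
    cfg2$areas <- data.frame(name = "V1", row = 5, col = 5, r_row = 3,
                             r_col = 3, pref_patch = 0L)
    tt <- make_trial_table("dot", 100, gap_s = 3)
    s2 <- generate_widefield_session(cfg2, tt, seed = sd)
    iso_px <- s2$isosbestic$data[, 6, 6]
    abs(stats::cor(s2$truth$coeff[, "V1"], iso_px))
  }, 0)
  expect_lt(mean(cors), 0.05)
})

test_that("masks are disjoint and overlapping configs are rejected", {
  cfg <- ground_truth_config()
  overlap <- Reduce(`+`, lapply(area_masks(cfg), as.numeric))
  expect_true(all(overlap <= 1))
  bad <- tiny_layout(2)
  bad$col <- c(6, 7)  # forces overlap
  expect_error(ground_truth_config(areas = bad, dims = c(24, 24)), "overlap")
  expect_error(tiny_config(g = 1.4), "g")
  expect_error(tiny_config(F0 = -1), "F0")
})

test_that("spike generator: null unit, full reduction, Poisson counts", {
  tt <- make_trial_table("grating", 20, duration_s = 1, gap_s = 2)
  tt$condition <- rep(c("control", "opto"), 10)

  # evoked = baseline -> flat PSTH within sampling error
  null_u <- data.frame(baseline_hz = 20, evoked_hz = 20, reduction = 0.5,
                       class = "RS")
  s <- generate_spike_session(null_u, tt, seed = 1)
  p <- build_psth(s$spikes[[1]], tt$onset_s, c(-0.5, 1), 0.25)
  expect_true(all(abs(p$rate - 20) < 3 * sqrt(20 / (0.25 * 20))))

  # reduction = 1 -> silenced evoked rate equals baseline rate
  red_u <- data.frame(baseline_hz = 5, evoked_hz = 25, reduction = 1,
                      class = "RS")
  s2 <- generate_spike_session(red_u, tt, seed = 2)
  r <- trial_rates(s2$spikes[[1]], tt)
  opto <- tt$condition == "opto"
  expect_lt(abs(mean(r$evoked_hz[opto]) - 5), 3 * sqrt(5 / sum(opto)))
  expect_gt(mean(r$evoked_hz[!opto]), 15)

  # Poisson count check: baseline 5 Hz over ~100 s
  long <- data.frame(trial_id = 1, stim_type = "grating",
                     condition = "control", onset_s = 98, offset_s = 98.1,
                     link_id = NA, patch_index = NA)
  counts <- vapply(1:10, function(sd) {
    ss <- generate_spike_session(
      data.frame(baseline_hz = 5, evoked_hz = 5, reduction = 0, class = "RS"),
      long, seed = sd)
    sum(ss$spikes[[1]] < 100)
  }, 0)
  expect_true(all(abs(counts - 500) < 3 * sqrt(500)))
  expect_error(generate_spike_session(
    data.frame(baseline_hz = -1, evoked_hz = 5, reduction = 0, class = "RS"),
    tt), "non-negative")
})

test_that("anatomy generator: zero amplitude, band recovery, determinism", {
  areas <- data.frame(name = c("A", "B"), amp_gfp = c(0, 80),
                      depth_gfp = c(0.5, 0.3), amp_tdt = c(50, 50),
                      depth_tdt = c(0.6, 0.6))
  s1 <- generate_anatomy_sections(areas, n_sections = 2, seed = 9)
  s2 <- generate_anatomy_sections(areas, n_sections = 2, seed = 9)
  expect_identical(s1[[1]]$images$gfp, s2[[1]]$images$gfp)

  # amplitude 0 -> corrected profile ~ 0
  prof <- depth_density_profile(s1[[1]]$images$gfp, s1[[1]]$boxes$A)
  corr <- subtract_autofluorescence(prof, s1[[1]]$background$gfp)
  expect_lt(max(abs(corr$density)), 1e-9)

  # band at 0.3 -> argmax within one grid step
  prof_b <- depth_density_profile(s1[[1]]$images$gfp, s1[[1]]$boxes$B)
  corr_b <- subtract_autofluorescence(prof_b, s1[[1]]$background$gfp)
  expect_lt(abs(corr_b$depth[which.max(corr_b$density)] - 0.3), 0.011)
  expect_error(generate_anatomy_sections(
    data.frame(name = "A", amp_gfp = -1, depth_gfp = 0.5,
               amp_tdt = 0, depth_tdt = 0.5)), "amplitudes")
})

test_that("photometry generator: null labels and noiseless closed form", {
  run <- generate_running_trace(500, seed = 11)
  pr <- generate_coupled_replay_trials(run, 15)
  rec <- vmd_records(pr$trials, pr$stimuli, run)
  trials <- pr$trials
  trials$vmd_label <- rec$label[match(trials$trial_id, rec$trial_id)]

  # s_pos = 0.5, noiseless: positive-VMD uncoupled response is 1.5x coupled
  ps <- generate_photometry_session(trials, amp = 0.1, s_pos = 0.5,
                                    sigma_noise = 0, h_amp = 0, seed = 1)
  pos <- trials$stim_type == "uncoupled" & trials$vmd_label == "positive"
  coup <- trials$stim_type == "coupled"
  expect_gt(sum(pos), 0)
  expect_equal(ps$truth$amplitudes[pos] / mean(ps$truth$amplitudes[coup]),
               rep(1.5, sum(pos)), tolerance = 1e-12)

  # s_pos = s_neg = 0: all trial amplitudes equal
  ps0 <- generate_photometry_session(trials, amp = 0.1, sigma_noise = 0,
                                     h_amp = 0)
  expect_true(all(ps0$truth$amplitudes == 0.1))
})
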