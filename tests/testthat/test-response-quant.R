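# response_quant: pixel selection, responsiveness, silencing effect sizes

test_that("top-pixel selection: ranks, whole mask, unbiased averaging", {
  img <- matrix(0, 2, 5)
  mask <- matrix(TRUE, 2, 5)
  img[] <- 1:10
  expect_equal(select_top_pixels(img, mask, 0.5), 6:10)
  expect_equal(select_top_pixels(img, mask, 1), 1:10)
  expect_error(select_top_pixels(img, matrix(FALSE, 2, 5)), "empty mask")

  # symmetric conditions: averaging control and treated images keeps the
  # selection balanced between the pixel sets each condition favours;
  # ranking on either condition alone would pick one half exclusively
  ctrl <- matrix(0, 2, 4); trt <- matrix(0, 2, 4)
  ctrl[, 1:2] <- c(18, 14, 10, 6)      # control favours the left half
  trt[, 3:4] <- c(16, 12, 8, 4)        # treated favours the right half
  mask <- matrix(TRUE, 2, 4)
  sel_avg <- select_top_pixels(average_rank_image(list(ctrl, trt)), mask, 0.5)
  expect_equal(sum(sel_avg <= 4), 2)
  expect_equal(sum(sel_avg > 4), 2)
  expect_true(all(select_top_pixels(ctrl, mask, 0.5) <= 4))
})

test_that("trial responses: constants, window length, closed-form kernel mean", {
  arr <- array(100, c(60, 3, 3))
  tt <- data.frame(trial_id = 1L, stim_type = "dot", condition = "control",
                   onset_s = 2, offset_s = 3, link_id = NA, patch_index = NA)
  arr[21:60, , ] <- 100 * (1 + 0.04)  # constant dF/F = 0.04 in window
  d <- compute_dff(widefield_movie(arr, 10), tt)
  # 1 s stimulus -> 1.5 s analysis window -> 15 frames at 10 Hz
  expect_equal(dim(d$trials_dff[[1]]$dff)[1], 15)
  r <- trial_response(d, matrix(TRUE, 3, 3))
  expect_equal(unname(r$responses), 0.04, tolerance = 1e-12)

  # generator pulse: response = A * mean(sampled kernel) over the window
  cfg <- tiny_config(A = 0.05, sigma_noise = 0, h_amp = 0)
  s <- generate_widefield_session(cfg, make_trial_table("dot", 1))
  ds <- compute_dff(s$signal, s$trials)
  k <- calcium_kernel((0:14) / 10, 0.1, 0.8)
  k <- k / max(k)
  rs <- trial_response(ds, area_masks(cfg)$V1)
  expect_equal(rs$mean, 0.05 * mean(k), tolerance = 1e-10)
})

test_that("responsiveness: 2-SD rule and indeterminate baseline", {
  expect_true(area_responsive(2.5, c(-1, 0, 1, 0, -1, 1)))
  expect_false(area_responsive(1.5, c(-1, 0, 1, 0, -1, 1)))
  expect_warning(out <- area_responsive(1, c(0, 0, 0)), "indeterminate")
  expect_true(is.na(out))
  expect_error(area_responsive(1, 0), "baseline")
})

test_that("intra-hemispheric percent change matches printed arithmetic", {
  # control 1.0, treated 0.128 -> 87.2% reduction
  expect_equal(percent_change_intra(1, 0.128)$reduction_pct, 87.2)
  expect_equal(percent_change_intra(2, 2)$reduction_pct, 0)
  # treated above control reports an increase as a negative reduction
  expect_equal(percent_change_intra(1, 1.22)$reduction_pct, -22)
  # reductions > 100% are not clipped
  expect_equal(percent_change_intra(1, -0.338)$reduction_pct, 133.8)
  expect_error(percent_change_intra(0, 1), "positive")
})

test_that("inter-hemispheric comparison: identity, arithmetic, gain invariance", {
  l <- c(V1 = 1, POR = 0.9, LM = 0.5)
  expect_true(all(interhemispheric_compare(l, l)$reduction_pct == 0))

  telc <- c(V1 = 1, POR = 0.2); ctrl <- c(V1 = 1, POR = 1)
  out <- interhemispheric_compare(telc, ctrl)
  expect_equal(out$reduction_pct[out$area == "POR"], 80)

  # any global gain on one hemisphere cancels through the V1 division
  out2 <- interhemispheric_compare(telc * 3.7, ctrl)
  expect_equal(out2$reduction_pct, out$reduction_pct, tolerance = 1e-12)
  expect_error(interhemispheric_compare(c(V1 = 0, POR = 1), ctrl), "V1")
  expect_error(interhemispheric_compare(c(POR = 1), ctrl), "V1")
})

test_that("TeLC-style interhemispheric recovery lands within 10 points", {
  # silencing only the tecto-pulvinar drive of POR (g = 0.8): the estimated
  # POR reduction should recover 80% from 60 trials/hemisphere
  reds <- vapply(1:10, function(seed) {
    est <- lapply(c(telc = TRUE, ctrl = FALSE), function(silenced) {
      cfg <- ground_truth_config(areas = tiny_layout(2), dims = c(24, 24),
                                 g = c(POR = 0.8), seed = seed)
      tt <- make_trial_table("dot", 60,
                             condition = if (silenced) "TeLC" else "control")
      s <- generate_widefield_session(cfg, tt, seed = seed * 101 + silenced)
      corr <- hemodynamic_correct(s$signal, s$isosbestic, tt)
      d <- compute_dff(corr, tt)
      masks <- area_masks(cfg)
      vapply(masks, function(m) trial_response(d, m)$mean, 0)
    })
    out <- interhemispheric_compare(est$telc, est$ctrl)
    out$reduction_pct[out$area == "POR"]
  }, 0)
  expect_true(all(abs(reds - 80) <= 10))
})

test_that("condition comparison: paired guard, power, unequal n", {
  expect_equal(compare_conditions(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p_value, 1)
  set.seed(0)
  a <- rnorm(20); b <- rnorm(20, 3)
  expect_lt(compare_conditions(a, b)$p_value, 0.001)
  out <- compare_conditions(rnorm(5), rnorm(9), paired = FALSE)
  expect_equal(out$test_name, "unpaired t-test")
  expect_error(compare_conditions(1, c(1, 2)), "2 observations")
  expect_error(compare_conditions(c(1, 2, 3), c(1, 2), paired = TRUE), "equal lengths")
})

test_that("rank order of estimated reductions tracks distinct truth g", {
  # smaller-scale version of the SC-dependence recovery invariant
  hits <- vapply(1:3, function(seed) {
    cfg <- ground_truth_config(areas = vmd_layout(), dims = c(32, 32),
                               g = c(POR = 0.8, LI = 0.4), seed = seed)
    dff <- list()
    for (cond in c("control", "TTX")) {
      tt <- make_trial_table("dot", 30, condition = cond)
      s <- generate_widefield_session(cfg, tt, seed = seed * 7 + (cond == "TTX"))
      corr <- hemodynamic_correct(s$signal, s$isosbestic, tt)
      dff[[cond]] <- compute_dff(corr, tt)
    }
    masks <- area_masks(cfg)
    est <- vapply(names(masks), function(a) {
      percent_change_intra(trial_response(dff$control, masks[[a]])$mean,
                           trial_response(dff$TTX, masks[[a]])$mean)$reduction_pct
    }, 0)
    truth <- c(V1 = 0, POR = 80, LI = 40)
    cor(est[names(truth)], truth, method = "spearman") == 1
  }, TRUE)
  expect_true(all(hits))
})
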