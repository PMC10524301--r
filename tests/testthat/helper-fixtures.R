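# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

# minimal single-area world on a small grid (fast paths)
tiny_layout <- function(n = 1) {
  data.frame(name = c("V1", "POR", "LI")[seq_len(n)],
             row = c(6, 6, 18)[seq_len(n)],
             col = c(6, 18, 12)[seq_len(n)],
             r_row = 3, r_col = 3, pref_patch = 0L)
}

tiny_config <- function(n_areas = 1, dims = c(24, 24), ...) {
  ground_truth_config(areas = tiny_layout(n_areas), dims = dims, ...)
}

# three-area proxy world (V1 + two lateral areas) used by the VMD analyses
vmd_layout <- function() {
  data.frame(name = c("V1", "POR", "LI"),
             row = c(8, 8, 24), col = c(8, 24, 16),
             r_row = 4, r_col = 4, pref_patch = 0L)
}

# one synthetic treadmill mouse: coupled/replay trials, widefield session,
# per-area normalised trial traces
simulate_vmd_mouse <- function(seed, s_pos = 0, s_neg = 0, n_pairs = 15,
                               dims = c(32, 32), use_isosbestic = TRUE,
                               areas = vmd_layout()) {
  spv <- stats::setNames(rep(s_pos, 2), c("POR", "LI"))
  snv <- stats::setNames(rep(s_neg, 2), c("POR", "LI"))
  cfg <- ground_truth_config(areas = areas, dims = dims,
                             s_pos = spv, s_neg = snv, seed = seed)
  running <- generate_running_trace(60 + n_pairs * 15, seed = seed)
  pr <- generate_coupled_replay_trials(running, n_pairs)
  rec <- vmd_records(pr$trials, pr$stimuli, running)
  trials <- pr$trials
  trials$vmd_label <- rec$label[match(trials$trial_id, rec$trial_id)]
  sess <- generate_widefield_session(cfg, trials, running = running,
                                     isosbestic = use_isosbestic,
                                     seed = seed + 1000L)
  movie <- if (use_isosbestic) {
    hemodynamic_correct(sess$signal, sess$isosbestic, trials)
  } else {
    sess$signal
  }
  dff <- compute_dff(movie, trials)
  masks <- area_masks(cfg)
  traces <- lapply(masks, function(m) area_trial_traces(dff, m, 17L))
  cid <- trials$stim_type == "coupled"
  v1_mean <- mean(traces$V1[cid, ], na.rm = TRUE)
  list(config = cfg, trials = trials, records = rec, coupled_idx = cid,
       traces = lapply(traces, function(x) x / v1_mean))
}

# per-mouse coupled/uncoupled matrices for one area and VMD label
# (label = NULL takes every uncoupled trial)
vmd_per_mouse <- function(mice, area, label = "positive") {
  lapply(mice, function(m) {
    sel <- m$trials$stim_type == "uncoupled"
    if (!is.null(label)) sel <- sel & m$trials$vmd_label == label
    list(coupled = m$traces[[area]][m$coupled_idx, , drop = FALSE],
         uncoupled = m$traces[[area]][sel, , drop = FALSE])
  })
}

# slow AR(1) smoother local to the tests (independent of the package's)
smooth_ar1_for_test <- function(n, rho = 0.95) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, sd = sqrt(1 - rho^2))
  x
}

# independent brute-force BH oracle: the rejected set is the largest subset
# S (over all 2^m subsets) with max(p[S]) <= |S| * alpha / m, closed under
# taking smaller p
bh_bruteforce <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m == 0) return(logical(0))
  memb <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  vals <- sweep(memb, 2, p, "*")              # p >= 0, so subset max survives
  rmax <- do.call(pmax, as.data.frame(vals))
  sizes <- rowSums(memb)
  valid <- sizes > 0 & rmax <= sizes * alpha / m
  k <- if (any(valid)) max(sizes[valid]) else 0
  if (k == 0) rep(FALSE, m) else p <= k * alpha / m
}

# exact Wilcoxon signed-rank p by enumeration of all sign assignments
wilcoxon_enumerate <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(seq_len(2^n) - 1L, function(bits) {
    s <- bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0
    sum(r[s])
  }, 0)
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}
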