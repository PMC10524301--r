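#' Visuo-motor divergence of an uncoupled trial
#'
#' The divergence is the relative difference between the replayed stimulus
#' speed and the running-equivalent stimulus speed, averaged over the
#' stimulus presentation:
#' `(mean stimulus speed - gain * mean running speed) / (gain * mean running
#' speed)`. A positive value means the stimulus moved faster than the
#' animal was running (the animal slowed down relative to the source trial).
#'
#' @param stim_speed stimulus speed samples over the presentation (deg/s).
#' @param run_speed concurrent running speed samples (cm/s), same sampling.
#' @param gain stimulus gain (deg/s per cm/s).
#' @return list `divergence` (unitless; `Inf` sentinel when mean running is
#'   zero, flagged), `flagged`, `mean_stim`, `mean_run`.
#' @export
compute_vmd <- function(stim_speed, run_speed, gain = 2) {
  ms <- mean(stim_speed)
  mr <- gain * mean(run_speed)
  if (mr == 0) {
    return(list(divergence = Inf, flagged = TRUE, mean_stim = ms, mean_run = 0))
  }
  list(divergence = (ms - mr) / mr, flagged = FALSE,
       mean_stim = ms, mean_run = mr / gain)
}

#' Classify trials by visuo-motor divergence
#'
#' Divergence at or above `+threshold` is labelled `positive`, at or below
#' `-threshold` `negative`, and everything in between `matched` (the 25%
#' rule).
#'
#' @param divergences numeric vector (may contain the `Inf` sentinel, which
#'   is labelled `positive`).
#' @param threshold positive classification threshold (0.25 by default).
#' @return character vector of labels.
#' @export
classify_trials <- function(divergences, threshold = 0.25) {
  if (threshold <= 0) stop_param("threshold must be positive")
  ifelse(divergences >= threshold, "positive",
         ifelse(divergences <= -threshold, "negative", "matched"))
}

#' Build VMD records for a coupled/replay session
#'
#' Computes per-uncoupled-trial divergence against the actual running trace
#' and classifies trials. Coupled trials get divergence 0 / label `matched`
#' by the replay identity (their stimulus is their own running trace times
#' the gain).
#'
#' @param trials trial table from [generate_coupled_replay_trials()] (or the
#'   same schema), with `stim_type` in `coupled`/`uncoupled` and `link_id`
#'   pairing each uncoupled trial to its source.
#' @param stimuli list of per-trial `stimulus_trace`s.
#' @param running the session `running_trace`.
#' @param gain stimulus gain (deg/s per cm/s).
#' @param threshold classification threshold.
#' @return data.frame `trial_id`, `link_id`, `stim_type`, `divergence`,
#'   `label`, `mean_run_cm_s`, `mean_stim_deg_s`, `flagged`.
#' @export
vmd_records <- function(trials, stimuli, running, gain = 2, threshold = 0.25) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    st <- stimuli[[tr$trial_id]]
    # replay identity: a coupled trial's stimulus IS its own running trace
    # times the gain, so its divergence is exactly 0 by construction
    run <- if (tr$stim_type == "coupled") st$dot_speed / gain
           else running_at(running, st$time)
    v <- compute_vmd(st$dot_speed, run, gain)
    data.frame(trial_id = tr$trial_id, link_id = tr$link_id,
               stim_type = tr$stim_type, divergence = v$divergence,
               label = if (tr$stim_type == "coupled") "matched" else
                 classify_trials(v$divergence, threshold),
               mean_run_cm_s = v$mean_run, mean_stim_deg_s = v$mean_stim,
               flagged = v$flagged)
  })
  do.call(rbind, rows)
}

#' Normalise area time courses to the mean V1 coupled response
#'
#' Every trace is divided by one scalar: the mean V1 response across all
#' coupled trials over the analysis window. Traces are truncated at
#' `window_s` (half-open, so 1.7 s at 10 Hz keeps 17 samples), and the
#' fraction of trials whose stimulus is still on screen at each timepoint is
#' reported.
#'
#' @param traces matrix `trials x time` of area delta-F/F (sampled from
#'   stimulus onset).
#' @param v1_coupled_mean scalar normaliser, > 0.
#' @param frame_rate sampling rate (Hz).
#' @param durations_s per-trial stimulus durations (for the stimulus-present
#'   fraction); optional.
#' @param window_s analysis window (s).
#' @return list `traces` (normalised, truncated), `time` (s),
#'   `stim_present_frac` (per-timepoint, `NULL` if durations not given).
#' @export
normalize_timecourses <- function(traces, v1_coupled_mean, frame_rate,
                                  durations_s = NULL, window_s = 1.7) {
  if (v1_coupled_mean <= 0) stop_param("V1 coupled mean must be positive")
  tvec <- (seq_len(ncol(traces)) - 1L) / frame_rate
  keep <- tvec < window_s
  out <- traces[, keep, drop = FALSE] / v1_coupled_mean
  frac <- if (!is.null(durations_s)) {
    vapply(tvec[keep], function(t) mean(durations_s > t), 0)
  } else NULL
  list(traces = out, time = tvec[keep], stim_present_frac = frac)
}

#' Benjamini-Hochberg step-up false-discovery control
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param alpha target false-discovery rate.
#' @return list `reject` (logical mask), `adjusted` (BH-adjusted p values,
#'   monotone nondecreasing in rank), `k` (number of rejections).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) {
    return(list(reject = logical(0), adjusted = numeric(0), k = 0L))
  }
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop_param("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord]
  # step-up: largest k with p_(k) <= k/m * alpha
  below <- which(ranked <= seq_len(m) / m * alpha)
  k <- if (length(below)) max(below) else 0L
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  adj_sorted <- rev(cummin(rev(ranked * m / seq_len(m))))
  adjusted <- numeric(m)
  adjusted[ord] <- pmin(adj_sorted, 1)
  list(reject = reject, adjusted = adjusted, k = as.integer(k))
}

#' Coupled versus uncoupled time-course comparison
#'
#' Per-mouse mean time courses are computed first (each mouse contributes
#' equally, independently of trial counts), then a paired two-sided t test
#' is run at every timepoint across mice and Benjamini-Hochberg correction
#' applied across timepoints. The summary scalar comparison is the per-mouse
#' mean over the window, compared by a paired t test.
#'
#' @param per_mouse list over mice; each element a list with matrices
#'   `coupled` and `uncoupled` (`trials x time`, already normalised).
#' @param alpha significance level.
#' @return list `time_idx`, `mean_diff` (uncoupled - coupled, averaged over
#'   mice), `p_values`, `bh` (mask + adjusted), `summary` (paired t test on
#'   window means, see [compare_conditions()]), `mouse_means`.
#' @export
coupled_uncoupled_comparison <- function(per_mouse, alpha = 0.05) {
  if (length(per_mouse) < 2) stop_param("need >= 2 mice")
  for (m in seq_along(per_mouse)) {
    if (nrow(per_mouse[[m]]$uncoupled) == 0 || nrow(per_mouse[[m]]$coupled) == 0) {
      stop_param("mouse %d contributes no trials to one condition", m)
    }
  }
  cm <- do.call(rbind, lapply(per_mouse, function(m) colMeans(m$coupled, na.rm = TRUE)))
  um <- do.call(rbind, lapply(per_mouse, function(m) colMeans(m$uncoupled, na.rm = TRUE)))
  nT <- ncol(cm)
  # timepoints where some mouse has no surviving trials are reported as NA
  # and excluded from the BH family
  valid <- vapply(seq_len(nT), function(j) {
    all(is.finite(um[, j])) && all(is.finite(cm[, j]))
  }, TRUE)
  p <- rep(NA_real_, nT)
  p[valid] <- vapply(which(valid), function(j) {
    compare_conditions(um[, j], cm[, j], paired = TRUE, alpha = alpha)$p_value
  }, 0)
  bh_v <- benjamini_hochberg(p[valid], alpha)
  bh <- list(reject = logical(nT), adjusted = rep(NA_real_, nT), k = bh_v$k)
  bh$reject[valid] <- bh_v$reject
  bh$adjusted[valid] <- bh_v$adjusted
  summary_test <- compare_conditions(rowMeans(um, na.rm = TRUE),
                                     rowMeans(cm, na.rm = TRUE),
                                     paired = TRUE, alpha = alpha)
  list(time_idx = seq_len(nT), mean_diff = colMeans(um - cm),
       p_values = p, bh = bh, summary = summary_test,
       mouse_means = list(coupled = cm, uncoupled = um))
}

#' Mean response difference binned by divergence
#'
#' Per-trial difference = normalised uncoupled response minus the mean
#' normalised coupled response; trials are binned by their divergence and
#' the mean difference per bin reported. Empty bins are `NA`, not zero.
#'
#' @param divergences per-uncoupled-trial divergence values.
#' @param differences per-trial response differences (same order).
#' @param edges bin edges covering the observed divergences.
#' @return data.frame `bin_lo`, `bin_hi`, `mid`, `mean_diff`, `n`.
#' @export
bin_by_divergence <- function(divergences, differences, edges) {
  stopifnot(length(divergences) == length(differences))
  finite <- is.finite(divergences)
  b <- findInterval(divergences[finite], edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  out$mid <- (out$bin_lo + out$bin_hi) / 2
  out$mean_diff <- vapply(seq_len(nb), function(k) {
    v <- differences[finite][b == k]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  out$n <- vapply(seq_len(nb), function(k) sum(b == k), 0L)
  out
}

#' Response versus running-speed trend (coupled trials)
#'
#' @param responses per-coupled-trial responses.
#' @param speeds per-trial mean running speeds (cm/s).
#' @param n_bins number of equal-width speed bins.
#' @return list `bins` (data.frame `speed_lo`, `speed_hi`, `mean_response`,
#'   `n`), `rho` (Spearman rank correlation of response with speed),
#'   `p_value`.
#' @export
running_gain_check <- function(responses, speeds, n_bins = 5) {
  if (length(unique(speeds)) < 2) stop_param("all trials share one running speed")
  edges <- seq(min(speeds), max(speeds), length.out = n_bins + 1L)
  b <- findInterval(speeds, edges, rightmost.closed = TRUE)
  if (length(unique(b)) < 2) stop_param("fewer than 2 non-empty speed bins")
  bins <- data.frame(speed_lo = edges[-length(edges)], speed_hi = edges[-1])
  bins$mean_response <- vapply(seq_len(n_bins), function(k) {
    v <- responses[b == k]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  bins$n <- vapply(seq_len(n_bins), function(k) sum(b == k), 0L)
  ct <- suppressWarnings(stats::cor.test(responses, speeds, method = "spearman"))
  list(bins = bins, rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Eye-position control between conditions
#'
#' Coupled-minus-uncoupled offset of the eye position per axis, with an
#' unpaired two-sided t test, reported in the `mean +/- SD` format.
#'
#' @param eye_coupled,eye_uncoupled data.frames with `azimuth_deg` and
#'   `elevation_deg` columns.
#' @param alpha significance level.
#' @return data.frame, one row per axis: `axis`, `offset_mean`, `offset_sd`,
#'   `p_value`, `significant`.
#' @export
eye_position_control <- function(eye_coupled, eye_uncoupled, alpha = 0.05) {
  one <- function(axis) {
    a <- eye_coupled[[axis]]
    b <- eye_uncoupled[[axis]]
    if (length(a) < 2 || length(b) < 2) stop_param("need >= 2 samples per condition")
    tt <- compare_conditions(a, b, paired = FALSE, alpha = alpha)
    # pooled SD of the per-trial offsets around their condition means
    data.frame(axis = sub("_deg", "", axis),
               offset_mean = mean(a) - mean(b),
               offset_sd = stats::sd(c(a - mean(a), b - mean(b))),
               p_value = tt$p_value, significant = tt$significant)
  }
  rbind(one("azimuth_deg"), one("elevation_deg"))
}
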