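#' Threshold spike detection
#'
#' Spikes are events where the absolute extracellular signal crosses 4 times
#' the standard deviation of the whole trace. Crossings within the
#' refractory window are merged into one event; event times are reported at
#' the trough (extremum of largest magnitude near the crossing).
#'
#' @param trace voltage samples.
#' @param fs sampling rate (Hz), > 0.
#' @param threshold_sd threshold in trace SDs.
#' @param refractory_s merge window (s).
#' @param min_width_s minimum time the rectified signal must stay above
#'   threshold for an event to count (rejects single-sample noise
#'   excursions, which at 4 SD would otherwise occur every few hundred ms
#'   of white noise).
#' @return numeric vector of spike times (s). A constant trace yields no
#'   spikes, with a warning.
#' @export
detect_spikes <- function(trace, fs, threshold_sd = 4, refractory_s = 0.001,
                          min_width_s = 8e-5) {
  if (fs <= 0) stop_param("fs must be positive")
  if (length(trace) < fs) stop_param("trace must be at least 1 s long for SD estimation")
  s <- stats::sd(trace)
  if (s == 0) {
    warning("constant trace: no spikes detected")
    return(numeric(0))
  }
  th <- threshold_sd * s
  above <- abs(trace) > th
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_w <- max(2L, round(min_width_s * fs))
  run_ok <- r$values & r$lengths >= min_w
  edges <- starts[run_ok]
  if (!length(edges)) return(numeric(0))
  refr <- max(1L, round(refractory_s * fs))
  keep <- c(TRUE, diff(edges) > refr)
  events <- edges[keep]
  half <- max(1L, round(0.0005 * fs))  # trough search: 0.5 ms around crossing
  times <- vapply(events, function(e) {
    w <- e:min(e + 2L * half, length(trace))
    (w[which.max(abs(trace[w]))] - 1L) / fs
  }, 0)
  times
}

waveform_features <- function(waveforms, fs) {
  t(vapply(seq_len(nrow(waveforms)), function(i) {
    w <- waveforms[i, ]
    trough <- which.min(w)
    after <- w[trough:length(w)]
    peak <- trough + which.max(after) - 1L
    t2p <- (peak - trough) / fs
    repol <- if (peak > trough) max(diff(w[trough:peak])) * fs else 0
    c(t2p = t2p, repol = repol)
  }, c(t2p = 0, repol = 0)))
}

#' RS/FS unit classification
#'
#' K-means (k = 2) on z-scored waveform features -- trough-to-peak duration
#' and repolarisation slope -- with deterministic initialisation at the
#' extreme trough-to-peak units. The cluster with the shorter mean
#' trough-to-peak is labelled FS (fast-spiking putative interneurons), the
#' other RS (regular-spiking).
#'
#' @param waveforms matrix `units x samples` of mean waveforms (trough
#'   negative).
#' @param fs waveform sampling rate (Hz).
#' @return list `labels` (character, `"RS"`/`"FS"`), `features` (t2p s,
#'   repolarisation slope).
#' @export
classify_units <- function(waveforms, fs) {
  if (nrow(waveforms) < 2) stop_param("need >= 2 units to classify")
  feat <- waveform_features(waveforms, fs)
  if (all(apply(feat, 2, stats::sd) == 0)) {
    stop_param("degenerate clustering: all waveforms identical")
  }
  z <- scale(feat)
  z[, apply(feat, 2, stats::sd) == 0] <- 0
  centers <- z[c(which.min(feat[, "t2p"]), which.max(feat[, "t2p"])), , drop = FALSE]
  if (all(centers[1, ] == centers[2, ])) stop_param("degenerate clustering: features identical")
  km <- stats::kmeans(z, centers = centers)
  t2p_means <- tapply(feat[, "t2p"], km$cluster, mean)
  fs_cluster <- as.integer(names(which.min(t2p_means)))
  list(labels = ifelse(km$cluster == fs_cluster, "FS", "RS"),
       features = feat)
}

#' Unit responsiveness filter
#'
#' Responsive iff the mean evoked rate exceeds baseline mean by `k` baseline
#' SDs, with `k = 2` for 0.9 s stimulus sessions (700 ms baseline) and
#' `k = 1` for 1.5 s sessions (300 ms baseline).
#'
#' @param evoked_rates per-trial evoked firing rates (Hz).
#' @param baseline_rates per-trial baseline firing rates (Hz).
#' @param stim_duration stimulus duration class: 0.9 or 1.5 (s).
#' @return `TRUE`/`FALSE`, or `NA` with warning when baseline SD is 0.
#' @export
unit_responsive <- function(evoked_rates, baseline_rates, stim_duration = 0.9) {
  if (!stim_duration %in% c(0.9, 1.5)) {
    stop_param("stim_duration must be 0.9 or 1.5 (s)")
  }
  k <- if (stim_duration == 0.9) 2 else 1
  s <- stats::sd(baseline_rates)
  if (s == 0) {
    warning("baseline SD is 0: unit excluded")
    return(NA)
  }
  mean(evoked_rates) > mean(baseline_rates) + k * s
}

#' Preferred grating direction
#'
#' @param rates baseline-subtracted evoked rate per direction.
#' @return index (1-based) of the direction evoking the largest response;
#'   ties go to the lowest index.
#' @export
best_direction <- function(rates) {
  if (!length(rates)) stop_param("need >= 1 direction")
  which.max(rates)
}

#' Z-scored firing rate
#'
#' `(mean evoked rate - mean baseline rate) / SD of the baseline rate`.
#'
#' @param evoked_rates,baseline_rates per-trial firing rates (Hz).
#' @return Z score (scalar).
#' @export
zscore_fr <- function(evoked_rates, baseline_rates) {
  s <- stats::sd(baseline_rates)
  if (s == 0) stop_param("baseline SD is 0: Z undefined")
  (mean(evoked_rates) - mean(baseline_rates)) / s
}

#' Trial-averaged PSTH
#'
#' Rates in fixed bins (50 ms by default) aligned to stimulus onset, tiling
#' the `[pre, post]` window exactly (an error otherwise). Bin rate is the
#' spike count per bin summed over trials divided by `bin * n_trials`, so
#' `sum(rate) * bin * n_trials` conserves the total in-window spike count.
#'
#' @param spike_times spike times of one unit (s).
#' @param onsets trial onset times (s).
#' @param window `c(pre, post)` relative to onset (s).
#' @param bin bin width (s).
#' @return list `t` (bin left edges, s), `rate` (Hz), `n_trials`, `bin`.
#' @export
build_psth <- function(spike_times, onsets, window = c(-0.5, 1.5), bin = 0.05) {
  nb <- (window[2] - window[1]) / bin
  if (abs(nb - round(nb)) > 1e-9) {
    stop_param("bin width %g does not tile the window [%g, %g]",
               bin, window[1], window[2])
  }
  nb <- as.integer(round(nb))
  counts <- numeric(nb)
  for (on in onsets) {
    rel <- spike_times - on
    rel <- rel[rel >= window[1] & rel < window[2]]
    b <- floor((rel - window[1]) / bin) + 1L
    b <- pmin(b, nb)
    counts <- counts + tabulate(b, nb)
  }
  list(t = window[1] + (seq_len(nb) - 1L) * bin,
       rate = counts / (bin * length(onsets)),
       n_trials = length(onsets), bin = bin)
}

#' Population PSTH summary
#'
#' Each unit's control PSTH is normalised by its own maximum bin; the
#' opto-condition PSTH of the same unit is normalised by that same control
#' maximum. The population summary is the unweighted mean across units.
#' Units with a zero control maximum are dropped with a warning.
#'
#' @param control_psths,opto_psths lists of per-unit PSTHs (see
#'   [build_psth()]); `opto_psths` may be `NULL`.
#' @return list `control` (mean normalised PSTH), `opto` (or `NULL`), `t`,
#'   `n_units`.
#' @export
population_psth <- function(control_psths, opto_psths = NULL) {
  maxes <- vapply(control_psths, function(p) max(p$rate), 0)
  keep <- maxes > 0
  if (any(!keep)) warning(sprintf("%d unit(s) dropped: control PSTH max is 0",
                                  sum(!keep)))
  if (!any(keep)) stop_param("no units with nonzero control PSTH")
  cmat <- t(mapply(function(p, m) p$rate / m, control_psths[keep], maxes[keep]))
  out <- list(control = colMeans(cmat), t = control_psths[[which(keep)[1]]]$t,
              n_units = sum(keep))
  if (!is.null(opto_psths)) {
    omat <- t(mapply(function(p, m) p$rate / m, opto_psths[keep], maxes[keep]))
    out$opto <- colMeans(omat)
  }
  out
}

#' Percent reduction of the visual response under silencing
#'
#' `(1 - baseline-subtracted rate during illumination / baseline-subtracted
#' rate in control) * 100`.
#'
#' @param control_evoked,laser_evoked baseline-subtracted evoked rates (Hz).
#' @return percent reduction (may be negative for increases).
#' @export
percent_reduction <- function(control_evoked, laser_evoked) {
  if (control_evoked == 0) stop_param("zero control response: unit excluded")
  (1 - laser_evoked / control_evoked) * 100
}

#' Population silencing summary with Wilcoxon signed-rank test
#'
#' @param control_evoked,laser_evoked per-unit baseline-subtracted evoked
#'   rates (paired). Units with zero control response are excluded.
#' @return list `mean_reduction_pct`, `median_reduction_pct`, `p_value`
#'   (two-sided Wilcoxon signed-rank), `n_units`, `reductions`.
#' @export
silencing_summary <- function(control_evoked, laser_evoked) {
  keep <- control_evoked != 0
  if (!any(keep)) stop_param("no units with nonzero control response")
  red <- mapply(percent_reduction, control_evoked[keep], laser_evoked[keep])
  wt <- stats::wilcox.test(control_evoked[keep], laser_evoked[keep],
                           paired = TRUE, exact = length(red) <= 25)
  list(mean_reduction_pct = mean(red), median_reduction_pct = stats::median(red),
       p_value = wt$p.value, n_units = sum(keep), reductions = red)
}

# --- synthetic ephys -------------------------------------------------------

#' Synthetic mean waveforms with prescribed trough-to-peak durations
#'
#' @param t2p_s vector of trough-to-peak durations (s).
#' @param fs sampling rate (Hz).
#' @return matrix `length(t2p_s) x samples`.
#' @export
synthetic_waveforms <- function(t2p_s, fs = 25000) {
  t(vapply(t2p_s, make_waveform, make_waveform(1e-3, fs), fs = fs))
}

make_waveform <- function(t2p_s, fs, len_s = 0.0025, trough_s = 0.0008,
                          trough_sd = 0.00012, peak_frac = 0.45,
                          peak_sd = 2.8e-4) {
  t <- (seq_len(round(len_s * fs)) - 1L) / fs
  -exp(-(t - trough_s)^2 / (2 * trough_sd^2)) +
    peak_frac * exp(-(t - trough_s - t2p_s)^2 / (2 * peak_sd^2))
}

#' Simulate an extracellular recording session
#'
#' Poisson spiking with piecewise-constant rates: `baseline_hz` outside
#' stimulus windows and `baseline + (evoked - baseline) * tuning(direction) *
#' (1 - reduction * silenced)` inside. RS units carry broad waveforms
#' (trough-to-peak ~0.9 ms), FS units narrow ones (~0.25 ms). A raw voltage
#' trace (unit-SD Gaussian noise with 8-SD spike insertions) is returned on
#' request.
#'
#' @param units data.frame with columns `baseline_hz`, `evoked_hz`,
#'   `reduction` (fraction of the evoked excess lost under silencing),
#'   `class` (`"RS"`/`"FS"`), and optionally `pref_dir`.
#' @param trials trial table with `onset_s`, `offset_s`, `condition`
#'   (`"control"`/`"opto"`) and optionally `direction`.
#' @param fs sampling rate of waveforms/traces (Hz), >= 20 kHz.
#' @param off_dir_gain tuning of non-preferred directions.
#' @param t2p_rs,t2p_fs,t2p_sd trough-to-peak means and within-class SD (s).
#' @param trace also synthesise raw voltage traces?
#' @param seed integer seed.
#' @return list `spikes` (list of spike-time vectors), `waveforms` (matrix
#'   `units x samples`), `units`, `trials`, `fs`, optionally `traces`.
#' @export
generate_spike_session <- function(units, trials, fs = 25000,
                                   off_dir_gain = 0.3,
                                   t2p_rs = 9e-4, t2p_fs = 2.5e-4,
                                   t2p_sd = 4e-5, trace = FALSE, seed = 1) {
  if (any(units$baseline_hz < 0) || any(units$evoked_hz < 0)) {
    stop_param("firing rates must be non-negative")
  }
  if (fs < 20000) stop_param("fs must be >= 20 kHz")
  total <- max(trials$offset_s) + 2
  nU <- nrow(units)
  pref <- if ("pref_dir" %in% names(units)) units$pref_dir else rep(1L, nU)
  dirs <- if ("direction" %in% names(trials)) trials$direction else rep(1L, nrow(trials))
  spikes <- vector("list", nU)
  with_seed(substream_seed(seed, "spikes"), {
    for (u in seq_len(nU)) {
      # baseline Poisson process over the whole session
      n0 <- stats::rpois(1, units$baseline_hz[u] * total)
      st <- sort(stats::runif(n0, 0, total))
      # additional evoked spikes inside each stimulus window
      for (i in seq_len(nrow(trials))) {
        tun <- if (dirs[i] == pref[u]) 1 else off_dir_gain
        sil <- trials$condition[i] == "opto"
        excess <- (units$evoked_hz[u] - units$baseline_hz[u]) * tun *
          (1 - units$reduction[u] * sil)
        dur <- trials$offset_s[i] - trials$onset_s[i]
        if (excess > 0) {
          ne <- stats::rpois(1, excess * dur)
          st <- c(st, stats::runif(ne, trials$onset_s[i], trials$offset_s[i]))
        } else if (excess < 0) {
          # suppression: thin the baseline process inside the window
          w <- st >= trials$onset_s[i] & st < trials$offset_s[i]
          p_keep <- max(0, 1 + excess / units$baseline_hz[u])
          drop <- w & stats::runif(length(st)) > p_keep
          st <- st[!drop]
        }
      }
      spikes[[u]] <- sort(st)
    }
  })
  waveforms <- with_seed(substream_seed(seed, "waveforms"), {
    t(vapply(seq_len(nU), function(u) {
      mu <- if (units$class[u] == "FS") t2p_fs else t2p_rs
      make_waveform(stats::rnorm(1, mu, t2p_sd), fs)
    }, make_waveform(t2p_rs, fs)))
  })
  out <- list(spikes = spikes, waveforms = waveforms, units = units,
              trials = trials, fs = fs)
  if (trace) {
    out$traces <- with_seed(substream_seed(seed, "traces"), {
      lapply(seq_len(nU), function(u) {
        n <- round(total * fs)
        v <- stats::rnorm(n)
        w <- 8 * waveforms[u, ]
        for (tspk in spikes[[u]]) {
          i0 <- round(tspk * fs)
          ii <- i0:min(i0 + length(w) - 1L, n)
          if (i0 >= 1) v[ii] <- v[ii] + w[seq_along(ii)]
        }
        v
      })
    })
  }
  out
}

#' Per-trial evoked and baseline rates of one unit
#'
#' @param spike_times spike times (s).
#' @param trials trial table (`onset_s`, `offset_s`).
#' @param baseline_s pre-onset baseline window (s); 0.7 s for 0.9 s stimuli,
#'   0.3 s for 1.5 s stimuli.
#' @return data.frame `trial_id`, `evoked_hz`, `baseline_hz`.
#' @export
trial_rates <- function(spike_times, trials, baseline_s = 0.7) {
  data.frame(
    trial_id = trials$trial_id,
    evoked_hz = vapply(seq_len(nrow(trials)), function(i) {
      sum(spike_times >= trials$onset_s[i] & spike_times < trials$offset_s[i]) /
        (trials$offset_s[i] - trials$onset_s[i])
    }, 0),
    baseline_hz = vapply(seq_len(nrow(trials)), function(i) {
      sum(spike_times >= trials$onset_s[i] - baseline_s &
            spike_times < trials$onset_s[i]) / baseline_s
    }, 0)
  )
}
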