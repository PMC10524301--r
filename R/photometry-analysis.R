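#' Isosbestic correction of a fiber-photometry trace
#'
#' The 405 nm control channel is least-squares-fitted to the 470 nm signal
#' channel over non-stimulus samples (inter-trial intervals only, so evoked
#' signal is not absorbed), subtracted, and the residual expressed as
#' delta-F/F against the fitted baseline.
#'
#' @param signal,control numeric traces, equal length and rate. `control`
#'   may be `NULL` or constant: the correction is skipped with a warning and
#'   plain delta-F/F against the non-stimulus mean is returned.
#' @param frame_rate sampling rate (Hz).
#' @param trials optional trial table; samples inside
#'   `[onset, offset + 2 s]` are excluded from the fit.
#' @return list `dff` (corrected delta-F/F trace), `corrected` (logical),
#'   `fit` (`alpha`, `beta`) when corrected.
#' @export
isosbestic_correct <- function(signal, control, frame_rate, trials = NULL) {
  if (all(signal == 0)) stop_param("all-zero signal channel")
  n <- length(signal)
  fit_idx <- rep(TRUE, n)
  if (!is.null(trials)) {
    tgrid <- (seq_len(n) - 1L) / frame_rate
    for (i in seq_len(nrow(trials))) {
      fit_idx[tgrid >= trials$onset_s[i] & tgrid < trials$offset_s[i] + 2] <- FALSE
    }
    if (!any(fit_idx)) fit_idx <- rep(TRUE, n)
  }
  if (is.null(control) || stats::sd(control) == 0) {
    warning("control channel missing or constant: correction skipped")
    f0 <- mean(signal[fit_idx])
    return(list(dff = (signal - f0) / f0, corrected = FALSE))
  }
  if (length(control) != n) stop_param("channels differ in length")
  fit <- stats::lm.fit(cbind(1, control[fit_idx]), signal[fit_idx])
  ab <- fit$coefficients
  baseline <- ab[1] + ab[2] * control
  if (any(baseline <= 0)) {
    # guard against a degenerate fit; fall back to the mean baseline level
    baseline <- pmax(baseline, 1e-9)
  }
  list(dff = (signal - baseline) / baseline, corrected = TRUE,
       fit = list(alpha = unname(ab[1]), beta = unname(ab[2])))
}

#' Simulate a fiber-photometry session
#'
#' One-dimensional analogue of the widefield generator: the 470 nm channel
#' carries kernel-shaped evoked responses (amplitude `amp`, boosted by
#' `s_pos`/`s_neg` on positive/negative-VMD uncoupled trials) on a baseline
#' `F0` modulated multiplicatively by a shared hemodynamic process; the
#' 405 nm channel carries the hemodynamic term only.
#'
#' @param trials trial table (coupled/uncoupled), optionally with a
#'   `vmd_label` column.
#' @param amp evoked peak delta-F/F on coupled trials.
#' @param s_pos,s_neg response boosts for positive/negative-VMD trials.
#' @param F0 baseline fluorescence (a.u.).
#' @param sigma_noise per-sample noise SD (a.u.).
#' @param h_amp,hemo_tau hemodynamic amplitude and time constant.
#' @param frame_rate sampling rate (Hz).
#' @param tau_rise,tau_decay kernel time constants (s).
#' @param seed integer seed.
#' @return object of class `photometry_session`: `signal`, `control`,
#'   `frame_rate`, `trials`, `truth` (per-trial amplitude, hemodynamic
#'   trace).
#' @export
generate_photometry_session <- function(trials, amp = 0.05, s_pos = 0,
                                        s_neg = 0, F0 = 100,
                                        sigma_noise = 0.2, h_amp = 0.01,
                                        hemo_tau = 0.5, frame_rate = 20,
                                        tau_rise = 0.1, tau_decay = 0.8,
                                        seed = 1) {
  dt <- 1 / frame_rate
  nT <- as.integer(ceiling((max(trials$offset_s) + 2) * frame_rate))
  tgrid <- (seq_len(nT) - 1L) * dt
  r <- numeric(nT)
  tramp <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    vmd <- if ("vmd_label" %in% names(trials)) trials$vmd_label[i] else "none"
    a <- amp * (1 + s_pos * (vmd == "positive") + s_neg * (vmd == "negative"))
    tramp[i] <- a
    on <- trials$onset_s[i]
    idx <- which(tgrid >= on &
                   tgrid < trials$offset_s[i] + 5 * tau_decay)
    if (!length(idx)) next
    k <- calcium_kernel(tgrid[idx] - on, tau_rise, tau_decay)
    k <- k / max(k)
    r[idx] <- r[idx] + a * k
  }
  h <- if (h_amp > 0) {
    with_seed(substream_seed(seed, "photometry-hemo"),
              h_amp * smooth_ar1(nT, hemo_tau, dt))
  } else numeric(nT)
  noise <- function(tag) {
    if (sigma_noise > 0) {
      with_seed(substream_seed(seed, tag), stats::rnorm(nT, sd = sigma_noise))
    } else numeric(nT)
  }
  structure(list(
    signal = F0 * (1 + r) * (1 + h) + noise("photometry-noise-sig"),
    control = F0 * (1 + h) + noise("photometry-noise-ctrl"),
    frame_rate = frame_rate, trials = trials,
    truth = list(amplitudes = tramp, hemo = h, evoked = r)
  ), class = "photometry_session")
}

#' Per-trial photometry response traces
#'
#' @param dff corrected delta-F/F trace.
#' @param trials trial table.
#' @param frame_rate sampling rate (Hz).
#' @param window_s trace length from onset (s).
#' @param baseline_s pre-onset baseline window subtracted per trial (s);
#'   0 disables baseline correction.
#' @return matrix `trials x samples` (rownames = trial ids).
#' @export
photometry_trial_traces <- function(dff, trials, frame_rate, window_s = 1.7,
                                    baseline_s = 1) {
  # half-open window [0, window_s): 1.7 s at 10 Hz keeps 17 samples
  ns <- as.integer(ceiling(window_s * frame_rate - 1e-9))
  out <- matrix(NA_real_, nrow(trials), ns)
  for (i in seq_len(nrow(trials))) {
    i0 <- floor(trials$onset_s[i] * frame_rate) + 1L
    idx <- i0:(i0 + ns - 1L)
    if (max(idx) > length(dff)) stop_param("trial window exceeds trace length")
    v <- dff[idx]
    if (baseline_s > 0) {
      b <- dff[max(1L, i0 - as.integer(baseline_s * frame_rate)):(i0 - 1L)]
      v <- v - mean(b)
    }
    out[i, ] <- v
  }
  rownames(out) <- as.character(trials$trial_id)
  out
}

#' Photometry coupled/uncoupled VMD summary
#'
#' Per mouse: trial traces are normalised by the mean response across all
#' coupled trials, then baseline corrected. Label-wise average curves,
#' per-timepoint paired t tests across mice with Benjamini-Hochberg
#' correction, and a divergence-binned difference curve (replay-source
#' pairing: each uncoupled trial minus the mean normalised coupled
#' response) are returned.
#'
#' @param sessions list over mice; each element a list with `dff` (corrected
#'   trace), `trials`, `records` (from [vmd_records()]), `frame_rate`.
#' @param label VMD label analysed against coupled trials (`"positive"`,
#'   `"negative"` or `"matched"`).
#' @param window_s analysis window (s).
#' @param bin_edges divergence bin edges for the difference curve.
#' @param alpha significance level.
#' @return list `curves` (per-mouse mean coupled/uncoupled traces),
#'   `comparison` (see [coupled_uncoupled_comparison()]), `bins` (see
#'   [bin_by_divergence()]).
#' @export
photometry_vmd_summary <- function(sessions, label = "positive",
                                   window_s = 1.7,
                                   bin_edges = seq(-1, 1, by = 0.25),
                                   alpha = 0.05) {
  if (length(sessions) < 2) stop_param("need >= 2 mice for statistics")
  per_mouse <- list()
  all_div <- c(); all_diff <- c()
  for (m in seq_along(sessions)) {
    s <- sessions[[m]]
    # normalisation scalar first (mean raw coupled response), baseline
    # correction second
    raw <- photometry_trial_traces(s$dff, s$trials, s$frame_rate,
                                   window_s = window_s, baseline_s = 0)
    rec <- s$records
    coupled_ids <- rec$trial_id[rec$stim_type == "coupled"]
    if (!length(coupled_ids)) stop_param("mouse %d has no coupled trials", m)
    cid <- rownames(raw) %in% as.character(coupled_ids)
    norm <- mean(raw[cid, , drop = FALSE])
    if (norm <= 0) stop_param("non-positive coupled normaliser in mouse %d", m)
    ntr <- photometry_trial_traces(s$dff, s$trials, s$frame_rate,
                                   window_s = window_s) / norm
    lab_ids <- rec$trial_id[rec$stim_type == "uncoupled" & rec$label == label]
    uid <- rownames(ntr) %in% as.character(lab_ids)
    per_mouse[[m]] <- list(coupled = ntr[cid, , drop = FALSE],
                           uncoupled = ntr[uid, , drop = FALSE])
    # replay-source pairing for the binned difference curve
    urec <- rec[rec$stim_type == "uncoupled" & is.finite(rec$divergence), ]
    cmean <- mean(rowMeans(ntr[cid, , drop = FALSE]))
    udiff <- rowMeans(ntr[rownames(ntr) %in% as.character(urec$trial_id), ,
                          drop = FALSE]) - cmean
    all_div <- c(all_div, urec$divergence)
    all_diff <- c(all_diff, udiff)
  }
  list(curves = lapply(per_mouse, function(m) {
         list(coupled = colMeans(m$coupled), uncoupled = colMeans(m$uncoupled))
       }),
       comparison = coupled_uncoupled_comparison(per_mouse, alpha = alpha),
       bins = bin_by_divergence(all_div, all_diff, bin_edges))
}
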