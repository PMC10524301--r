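#' Default cortical area layout
#'
#' Places V1 and eight higher visual areas (HVAs) as disjoint ellipses on a
#' pixel grid. Row 0 is the anterior edge, column 0 the medial edge, mirroring
#' the lateromedial arrangement of the mouse visual cortex (V1 medial, POR/LI
#' most lateral-posterior). Each area carries a preferred retinotopic patch
#' index (0 = centre of the plus sign, 1..4 = the four arms) used by the
#' generator to give areas distinguishable patch maps.
#'
#' @param dims grid size `c(rows, cols)`; the default layout needs >= 48 x 48.
#' @return data.frame with columns `name`, `row`, `col`, `r_row`, `r_col`,
#'   `pref_patch`.
#' @export
default_area_layout <- function(dims = c(48, 48)) {
  stopifnot(all(dims >= 48))
  sr <- dims[1] / 48
  sc <- dims[2] / 48
  d <- data.frame(
    name = c("V1", "AM", "PM", "RL", "AL", "LM", "LI", "P", "POR"),
    row  = c(28, 12, 41, 12, 14, 24, 32, 40, 40),
    col  = c(12, 10, 10, 20, 30, 28, 32, 24, 34),
    r_row = c(7, 3, 3, 3, 3, 3, 3, 3, 3),
    r_col = c(5, 3, 3, 3, 3, 3, 3, 3, 3),
    pref_patch = c(0L, 2L, 2L, 1L, 1L, 0L, 3L, 4L, 3L),
    stringsAsFactors = FALSE
  )
  d$row <- d$row * sr; d$r_row <- d$r_row * sr
  d$col <- d$col * sc; d$r_col <- d$r_col * sc
  d
}

#' Ground-truth configuration for the widefield generator
#'
#' Bundles every parameter of the synthetic widefield world: area geometry,
#' per-area SC-dependence `g` (fraction of the evoked response lost under
#' silencing of the tecto-thalamic drive), VMD sensitivities `s_pos`/`s_neg`
#' (multiplicative response boost on positive/negative visuo-motor-divergence
#' trials), running gain `gamma`, indicator kernel time constants, baseline
#' fluorescence and noise levels.
#'
#' `A`, `g`, `s_pos` and `s_neg` may be scalars or named vectors over area
#' names; unnamed scalars are recycled to all areas.
#'
#' @param areas area layout data.frame (see [default_area_layout()]).
#' @param dims pixel grid `c(rows, cols)`.
#' @param A evoked response amplitude per area (peak delta-F/F), > 0.
#' @param g SC-dependence per area, in \[0, 1\].
#' @param s_pos,s_neg VMD response boosts per area, >= 0.
#' @param gamma running-gain slope (fractional response gain per cm/s).
#'   Defaults to 0; the underlying experiments report only a trend and a
#'   nonzero default would confound coupled/uncoupled comparisons (see the
#'   methods vignette).
#' @param F0 baseline fluorescence (a.u.), > 0.
#' @param sigma_noise pixel noise SD (a.u. of raw fluorescence).
#' @param h_amp hemodynamic artifact amplitude (fractional, multiplicative on
#'   both channels).
#' @param hemo_tau autocorrelation time of the hemodynamic process (s); keeps
#'   its power below 1 Hz.
#' @param frame_rate imaging frame rate per channel (Hz), > 0.
#' @param tau_rise,tau_decay indicator kernel time constants (s).
#' @param hemisphere hemisphere tag.
#' @param seed default seed for sessions generated from this config.
#' @return object of class `ground_truth_config`.
#' @export
ground_truth_config <- function(areas = default_area_layout(dims),
                                dims = c(48, 48),
                                A = 0.05, g = 0, s_pos = 0, s_neg = 0,
                                gamma = 0, F0 = 1000, sigma_noise = 10,
                                h_amp = 0.01, hemo_tau = 0.5,
                                frame_rate = 10, tau_rise = 0.1,
                                tau_decay = 0.8, hemisphere = "left",
                                seed = 1) {
  per_area <- function(x, what, lo = -Inf, hi = Inf) {
    v <- if (is.null(names(x))) {
      stats::setNames(rep_len(x, nrow(areas)), areas$name)
    } else {
      out <- stats::setNames(rep(0, nrow(areas)), areas$name)
      if (!all(names(x) %in% areas$name)) {
        stop_param("unknown area name in %s: %s", what,
                   paste(setdiff(names(x), areas$name), collapse = ", "))
      }
      out[names(x)] <- x
      out
    }
    if (any(v < lo) || any(v > hi)) {
      stop_param("%s must lie in [%g, %g]", what, lo, hi)
    }
    v
  }
  if (F0 <= 0) stop_param("F0 must be positive")
  if (frame_rate <= 0) stop_param("frame_rate must be positive")
  cfg <- structure(list(
    areas = areas, dims = as.integer(dims),
    A = per_area(A, "A", lo = 0),
    g = per_area(g, "g", lo = 0, hi = 1),
    s_pos = per_area(s_pos, "s_pos", lo = 0),
    s_neg = per_area(s_neg, "s_neg", lo = 0),
    gamma = gamma, F0 = F0, sigma_noise = sigma_noise,
    h_amp = h_amp, hemo_tau = hemo_tau, frame_rate = frame_rate,
    tau_rise = tau_rise, tau_decay = tau_decay,
    hemisphere = hemisphere, seed = as.integer(seed)
  ), class = "ground_truth_config")
  m <- area_masks(cfg)
  overlap <- Reduce(`+`, lapply(m, function(x) x * 1L))
  if (any(overlap > 1L)) stop_param("area masks overlap: config error")
  cfg
}

#' Boolean pixel masks for every configured area
#'
#' @param config a `ground_truth_config`.
#' @return named list of logical matrices (`rows x cols`), one per area, with
#'   a `hemisphere` attribute. Masks are pairwise disjoint by construction
#'   (validated in [ground_truth_config()]).
#' @export
area_masks <- function(config) {
  H <- config$dims[1]; W <- config$dims[2]
  rr <- matrix(seq_len(H) - 1L, H, W)
  cc <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  out <- lapply(seq_len(nrow(config$areas)), function(i) {
    a <- config$areas[i, ]
    ((rr - a$row) / a$r_row)^2 + ((cc - a$col) / a$r_col)^2 <= 1
  })
  names(out) <- config$areas$name
  attr(out, "hemisphere") <- config$hemisphere
  out
}

#' Build a trial table for patch-mapping or moving-dot stimuli
#'
#' @param stim_type one of `"patch"`, `"dot"`, `"grating"`.
#' @param n_trials trials per patch location (patch) or total (dot/grating).
#' @param duration_s stimulus duration (s); 1 s per presentation by default.
#' @param gap_s inter-trial interval (s); 4 s as in the treadmill protocol.
#' @param condition condition tag, e.g. `"control"` or `"TTX"`.
#' @param first_onset_s onset of the first trial (s).
#' @return trial table data.frame (schema of [read_trial_table()]).
#' @export
make_trial_table <- function(stim_type = c("dot", "patch", "grating"),
                             n_trials, duration_s = 1, gap_s = 4,
                             condition = "control", first_onset_s = 2) {
  stim_type <- match.arg(stim_type)
  if (stim_type == "patch") {
    patch <- rep(0:4, times = n_trials)
    n <- length(patch)
  } else {
    patch <- rep(NA_integer_, n_trials)
    n <- n_trials
  }
  onset <- first_onset_s + (seq_len(n) - 1L) * (duration_s + gap_s)
  data.frame(
    trial_id = seq_len(n), stim_type = stim_type, condition = condition,
    onset_s = onset, offset_s = onset + duration_s,
    link_id = NA_integer_, patch_index = patch
  )
}

# per-trial sampled kernel, rescaled so its maximum sample is exactly 1
sampled_kernel <- function(trel, config) {
  k <- calcium_kernel(trel, config$tau_rise, config$tau_decay)
  m <- max(k)
  if (m > 0) k / m else k
}

#' Simulate a widefield calcium-imaging session
#'
#' Pixel fluorescence follows
#' `F = F0 * (1 + r(t)) * (1 + h(t)) + noise`, where the evoked field `r`
#' is, inside each area's mask, an indicator kernel scaled by
#' `A * (1 - g * silenced) * (1 + gamma * running) *
#' (1 + s_pos * [positive-VMD] + s_neg * [negative-VMD])`.
#' The isosbestic channel carries the same multiplicative hemodynamic term
#' `h(t)` but never the evoked component.
#'
#' @param config a `ground_truth_config`.
#' @param trials trial table; trials whose `condition` is in
#'   `silenced_conditions` have the evoked amplitude scaled by `(1 - g)`.
#'   An optional `vmd_label` column (values `positive`/`negative`/`matched`)
#'   engages `s_pos`/`s_neg`; an optional `patch_index` column restricts the
#'   response to areas via patch preference (preferred patch responds at full
#'   amplitude, others at `off_patch_gain`).
#' @param running optional `running_trace` (engages `gamma`).
#' @param silenced_conditions condition tags treated as silenced.
#' @param isosbestic also simulate the isosbestic channel?
#' @param off_patch_gain relative response of an area to a non-preferred
#'   patch.
#' @param seed seed; defaults to `config$seed`.
#' @return object of class `widefield_session`: list with `signal` and
#'   (optionally) `isosbestic` movies (see [widefield_movie()]), the `trials`
#'   table, and a `truth` record (per-trial per-area amplitudes, hemodynamic
#'   trace, masks, config).
#' @export
generate_widefield_session <- function(config, trials, running = NULL,
                                       silenced_conditions = c("TTX", "opto", "TeLC"),
                                       isosbestic = TRUE,
                                       off_patch_gain = 0.4,
                                       seed = config$seed) {
  known <- c("patch", "dot", "grating", "coupled", "uncoupled")
  if (!all(trials$stim_type %in% known)) {
    stop_param("unknown stim_type: %s (allowed: %s)",
               paste(setdiff(trials$stim_type, known), collapse = ", "),
               paste(known, collapse = ", "))
  }
  H <- config$dims[1]; W <- config$dims[2]
  dt <- 1 / config$frame_rate
  t_total <- max(trials$offset_s) + 2
  nT <- as.integer(ceiling(t_total * config$frame_rate))
  tgrid <- (seq_len(nT) - 1L) * dt
  masks <- area_masks(config)
  anames <- names(masks)

  # per-trial, per-area evoked amplitude
  amp <- matrix(0, nrow(trials), length(anames), dimnames = list(NULL, anames))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    sil <- tr$condition %in% silenced_conditions
    run_gain <- if (!is.null(running) && config$gamma != 0) {
      w <- running$time >= tr$onset_s & running$time < tr$offset_s
      1 + config$gamma * mean(running$speed[w])
    } else 1
    vmd <- if ("vmd_label" %in% names(trials)) tr$vmd_label else "none"
    vmd_gain <- 1 + config$s_pos * (vmd == "positive") +
      config$s_neg * (vmd == "negative")
    patch_gain <- if (!is.na(tr$patch_index)) {
      ifelse(config$areas$pref_patch == tr$patch_index, 1, off_patch_gain)
    } else 1
    amp[i, ] <- config$A * (1 - config$g * sil) * run_gain * vmd_gain * patch_gain
  }

  # per-area time coefficient: sum of kernel pulses over trials
  coeff <- matrix(0, nT, length(anames), dimnames = list(NULL, anames))
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_s[i]
    idx <- which(tgrid >= on & tgrid < on + 5 * config$tau_decay +
                   (trials$offset_s[i] - on))
    if (!length(idx)) next
    k <- sampled_kernel(tgrid[idx] - on, config)
    coeff[idx, ] <- coeff[idx, ] + outer(k, amp[i, ])
  }

  h <- if (config$h_amp > 0) {
    with_seed(substream_seed(seed, "hemodynamic"),
              config$h_amp * smooth_ar1(nT, config$hemo_tau, dt))
  } else rep(0, nT)

  R <- matrix(0, nT, H * W)
  for (a in anames) {
    mv <- as.vector(masks[[a]])
    R[, mv] <- R[, mv] + coeff[, a]
  }
  sig <- config$F0 * (1 + R) * (1 + h)
  if (config$sigma_noise > 0) {
    sig <- sig + with_seed(substream_seed(seed, "noise-signal"),
                           matrix(stats::rnorm(length(sig), sd = config$sigma_noise),
                                  nrow(sig)))
  }
  out <- list(
    signal = widefield_movie(array(sig, c(nT, H, W)), config$frame_rate, "signal"),
    trials = trials,
    truth = list(config = config, amplitudes = amp, coeff = coeff,
                 hemo = h, masks = masks, time = tgrid)
  )
  if (isosbestic) {
    iso <- matrix(config$F0 * (1 + h), nT, H * W)
    if (config$sigma_noise > 0) {
      iso <- iso + with_seed(substream_seed(seed, "noise-iso"),
                             matrix(stats::rnorm(length(iso), sd = config$sigma_noise),
                                    nT))
    }
    out$isosbestic <- widefield_movie(array(iso, c(nT, H, W)),
                                      config$frame_rate, "isosbestic")
  }
  class(out) <- "widefield_session"
  out
}

#' Per-trial eye-position table
#'
#' Draws per-trial eye positions (degrees) around a condition-specific mean,
#' emulating the eye-tracking control analysis.
#'
#' @param trials trial table.
#' @param mean_az,mean_el mean azimuth/elevation (deg).
#' @param sd_az,sd_el trial-to-trial SD (deg).
#' @param seed integer seed.
#' @return data.frame `trial_id`, `condition`, `azimuth_deg`, `elevation_deg`.
#' @export
generate_eye_positions <- function(trials, mean_az = 0, mean_el = 0,
                                   sd_az = 4.7, sd_el = 1.2, seed = 1) {
  n <- nrow(trials)
  with_seed(substream_seed(seed, "eye"), data.frame(
    trial_id = trials$trial_id,
    condition = trials$stim_type,
    azimuth_deg = stats::rnorm(n, mean_az, sd_az),
    elevation_deg = stats::rnorm(n, mean_el, sd_el)
  ))
}
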