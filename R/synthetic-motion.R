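#' Generate a synthetic running-speed trace
#'
#' Mean-reverting (Ornstein-Uhlenbeck-style) positive process standing in for
#' treadmill running. Speeds are clipped at zero, matching a rotary-encoder
#' readout of a head-fixed mouse on a wheel.
#'
#' @param duration total trace duration (s), > 0.
#' @param mean_speed long-run mean running speed (cm/s), >= 0.
#' @param sd stationary standard deviation of the process (cm/s).
#' @param tau mean-reversion time constant (s), > 0.
#' @param frame_rate sampling rate (Hz).
#' @param seed integer seed; identical seeds give bitwise-identical traces.
#' @return object of class `running_trace`: list with `time` (s) and `speed`
#'   (cm/s, >= 0), uniformly sampled.
#' @export
generate_running_trace <- function(duration, mean_speed = 10, sd = 4, tau = 2,
                                   frame_rate = 10, seed = 1) {
  if (duration <= 0) stop_param("duration must be positive (got %g)", duration)
  if (tau <= 0) stop_param("tau must be positive (got %g)", tau)
  if (mean_speed < 0) stop_param("mean_speed must be >= 0")
  dt <- 1 / frame_rate
  n <- as.integer(ceiling(duration * frame_rate))
  time <- (seq_len(n) - 1L) * dt
  speed <- if (sd == 0) {
    rep(mean_speed, n)
  } else {
    with_seed(substream_seed(seed, "running"), {
      mean_speed + sd * smooth_ar1(n, tau, dt)
    })
  }
  structure(list(time = time, speed = pmax(speed, 0), frame_rate = frame_rate),
            class = "running_trace")
}

running_at <- function(running, t) {
  idx <- pmin(pmax(floor(t * running$frame_rate) + 1L, 1L), length(running$speed))
  running$speed[idx]
}

#' Generate coupled/replay (uncoupled) trial pairs
#'
#' In a coupled trial the dot speed tracks the running speed times `gain`,
#' ending once the cumulative dot travel reaches `travel_deg` (40 degrees by
#' default). Each uncoupled trial replays the speed trace of its paired
#' preceding coupled trial verbatim. Trials are separated by a fixed
#' inter-trial gap.
#'
#' @param running a `running_trace`.
#' @param n_pairs number of coupled/uncoupled pairs requested.
#' @param gain stimulus gain, deg/s per cm/s, > 0.
#' @param travel_deg dot travel per trial (degrees of azimuth).
#' @param gap_s inter-trial interval (s).
#' @param first_onset_s onset of the first coupled trial (s).
#' @param max_trial_s cap on a single coupled trial's duration (protects
#'   against a stationary animal); capped trials are flagged.
#' @return list with `trials` (a trial table, see [read_trial_table()] schema,
#'   plus `duration_s`), `stimuli` (per-trial `stimulus_trace`: `time`,
#'   `dot_speed` deg/s, `dot_position` deg), and `truncated` flag set `TRUE`
#'   with a warning when the running trace was exhausted early.
#' @export
generate_coupled_replay_trials <- function(running, n_pairs, gain = 2,
                                           travel_deg = 40, gap_s = 4,
                                           first_onset_s = 2, max_trial_s = 8) {
  if (gain <= 0) stop_param("gain must be positive")
  dt <- 1 / running$frame_rate
  t_end <- running$time[length(running$time)] + dt
  trials <- list()
  stimuli <- list()
  t <- first_onset_s
  truncated <- FALSE
  id <- 0L
  for (p in seq_len(n_pairs)) {
    # coupled trial: integrate gain * running until travel_deg reached
    speeds <- c()
    travel <- 0
    tc <- t
    while (travel < travel_deg && (tc - t) < max_trial_s) {
      if (tc >= t_end) break
      v <- gain * running_at(running, tc)
      # last sample trimmed so the cumulative travel ends at exactly travel_deg
      if (travel + v * dt >= travel_deg) v <- (travel_deg - travel) / dt
      speeds <- c(speeds, v)
      travel <- travel + v * dt
      tc <- tc + dt
    }
    if (tc >= t_end || length(speeds) == 0L) {
      truncated <- TRUE
      break
    }
    dur <- length(speeds) * dt
    id <- id + 1L
    cid <- id
    trials[[length(trials) + 1L]] <- data.frame(
      trial_id = cid, stim_type = "coupled", condition = "control",
      onset_s = t, offset_s = t + dur, link_id = NA_integer_,
      patch_index = NA_integer_, duration_s = dur
    )
    stimuli[[cid]] <- structure(list(
      time = t + (seq_along(speeds) - 1L) * dt,
      dot_speed = speeds,
      dot_position = cumsum(speeds) * dt
    ), class = "stimulus_trace")
    t <- t + dur + gap_s

    # uncoupled trial: verbatim replay of the coupled speed trace
    if (t + dur >= t_end) {
      truncated <- TRUE
      break
    }
    id <- id + 1L
    trials[[length(trials) + 1L]] <- data.frame(
      trial_id = id, stim_type = "uncoupled", condition = "control",
      onset_s = t, offset_s = t + dur, link_id = cid,
      patch_index = NA_integer_, duration_s = dur
    )
    stimuli[[id]] <- structure(list(
      time = t + (seq_along(speeds) - 1L) * dt,
      dot_speed = speeds,
      dot_position = cumsum(speeds) * dt
    ), class = "stimulus_trace")
    t <- t + dur + gap_s
  }
  if (truncated) {
    warning(sprintf("running trace exhausted: returned %d of %d requested pairs",
                    sum(vapply(trials, function(x) x$stim_type == "uncoupled", TRUE)),
                    n_pairs))
  }
  trials <- if (length(trials)) do.call(rbind, trials) else
    data.frame(trial_id = integer(), stim_type = character(),
               condition = character(), onset_s = numeric(),
               offset_s = numeric(), link_id = integer(),
               patch_index = integer(), duration_s = numeric())
  list(trials = trials, stimuli = stimuli, truncated = truncated)
}
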