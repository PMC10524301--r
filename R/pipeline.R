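PIPELINE_STAGES <- c("simulate", "map", "quantify", "vmd", "ephys",
                     "anatomy", "photometry", "report")

#' Run the end-to-end synthetic pipeline
#'
#' Orchestrates a compact synthetic study: simulate all modalities with
#' known ground truth, delineate areas from the patch-mapping session,
#' quantify silencing effect sizes on the moving-dot sessions, run the
#' coupled/uncoupled VMD analysis, the ephys silencing quantification, the
#' anatomy depth profiling and the photometry summary. Stages run in
#' dependency order; every stage writes tidy CSV outputs under `out_dir` and
#' the report is produced even on partial failure, with failed stages
#' marked.
#'
#' @param out_dir output directory (created if needed).
#' @param config analysis configuration (see [load_config()]); a path or a
#'   list.
#' @param stages subset of stages to run (`"all"` for everything).
#' @param seed master seed for all generators.
#' @param n_trials trials per condition in the silencing experiment.
#' @param n_pairs coupled/uncoupled pairs per mouse in the VMD experiment.
#' @param n_mice number of synthetic mice in the VMD experiment.
#' @param dims pixel grid of the widefield generator.
#' @return `pipeline_report`: list with per-stage `status`, `config_digest`,
#'   `summary` (per-area statistics) and `warnings`.
#' @export
run_pipeline <- function(out_dir, config = default_config(), stages = "all",
                         seed = 1, n_trials = 20, n_pairs = 15, n_mice = 2,
                         dims = c(48, 48)) {
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop_param("unknown stage(s): %s", paste(bad, collapse = ", "))
  status <- stats::setNames(rep("skipped", length(PIPELINE_STAGES)), PIPELINE_STAGES)
  warns <- character(0)
  summary_rows <- list()
  state <- new.env(parent = emptyenv())
  digest <- sprintf("%08x", sum(utf8ToInt(paste(
    names(config), unlist(lapply(config, paste, collapse = ",")),
    collapse = ";")) * 7) %% 4294967291)

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    res <- tryCatch({
      withCallingHandlers(fun(), warning = function(w) {
        warns <<- c(warns, sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
      status[name] <<- "ok"
    }, error = function(e) {
      status[name] <<- paste("failed:", conditionMessage(e))
    })
    invisible(res)
  }

  run_stage("simulate", function() {
    state$cfg <- ground_truth_config(
      dims = dims, g = c(POR = 0.85, LI = 0.7, P = 0.55, LM = 0.35),
      seed = seed)
    patch_trials <- make_trial_table("patch", 6, duration_s = 1, gap_s = 2)
    state$patch_session <- generate_widefield_session(state$cfg, patch_trials,
                                                      seed = substream_seed(seed, "patch"))
    log_stage("simulate", seed = seed, digest = digest)
  })

  run_stage("map", function() {
    if (is.null(state$patch_session)) stop("run the simulate stage first")
    dff <- compute_dff(state$patch_session$signal, state$patch_session$trials,
                       baseline_s = config$baseline_window_s,
                       pad_s = config$response_pad_s)
    maps <- map_patch_responses(dff)
    state$masks <- delineate_areas(maps, state$cfg$areas,
                                   threshold_frac = config$delineation_threshold)
    jsonlite::write_json(lapply(state$masks, function(m) sum(m)),
                         file.path(out_dir, "area_mask_sizes.json"),
                         auto_unbox = TRUE)
  })

  run_stage("quantify", function() {
    if (is.null(state$masks)) stop("run the map stage first")
    for (cond in c("control", "TTX")) {
      tt <- make_trial_table("dot", n_trials, condition = cond)
      state[[paste0("dot_", cond)]] <- generate_widefield_session(
        state$cfg, tt, seed = substream_seed(seed, paste0("dot-", cond)))
    }
    dffc <- compute_dff(state$dot_control$signal, state$dot_control$trials)
    dfft <- compute_dff(state$dot_TTX$signal, state$dot_TTX$trials)
    rows <- lapply(names(state$masks), function(a) {
      rank_img <- average_rank_image(list(mean_response_image(dffc),
                                          mean_response_image(dfft)))
      px <- select_top_pixels(rank_img, state$masks[[a]],
                              config$top_pixel_fraction)
      rc <- trial_response(dffc, px)
      rt <- trial_response(dfft, px)
      pc <- percent_change_intra(rc$mean, rt$mean)
      data.frame(area = a, condition = "TTX", n_trials = n_trials,
                 mean_control = rc$mean, mean_treated = rt$mean,
                 remaining_fraction = pc$remaining,
                 reduction_pct = pc$reduction_pct)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "silencing_effects.csv"),
                     row.names = FALSE)
    summary_rows[[length(summary_rows) + 1L]] <<- tab
  })

  run_stage("vmd", function() {
    if (is.null(state$masks)) stop("run the map stage first")
    per_mouse <- list()
    for (m in seq_len(n_mice)) {
      mseed <- substream_seed(seed, paste0("vmd-mouse-", m))
      running <- generate_running_trace(60 + n_pairs * 15, seed = mseed)
      sess <- generate_coupled_replay_trials(running, n_pairs)
      rec <- vmd_records(sess$trials, sess$stimuli, running,
                         threshold = config$vmd_threshold)
      trials <- sess$trials
      trials$vmd_label <- rec$label[match(trials$trial_id, rec$trial_id)]
      wf <- generate_widefield_session(state$cfg, trials, running = running,
                                       seed = mseed)
      dff <- compute_dff(wf$signal, trials)
      ns <- as.integer(config$timecourse_window_s * state$cfg$frame_rate)
      v1 <- area_trial_traces(dff, state$masks$V1, ns)
      cid <- trials$stim_type == "coupled"
      v1_mean <- mean(v1[cid, ], na.rm = TRUE)
      por <- area_trial_traces(dff, state$masks$POR, ns) / v1_mean
      # analyse the best-populated divergence label of this session set
      lab <- names(which.max(table(trials$vmd_label[trials$stim_type == "uncoupled"])))
      per_mouse[[m]] <- list(coupled = por[cid, , drop = FALSE],
                             uncoupled = por[trials$stim_type == "uncoupled" &
                                               trials$vmd_label == lab, ,
                                             drop = FALSE])
      utils::write.csv(rec, file.path(out_dir, sprintf("vmd_records_m%d.csv", m)),
                       row.names = FALSE)
    }
    cmp <- coupled_uncoupled_comparison(per_mouse, alpha = config$alpha)
    utils::write.csv(
      data.frame(time_idx = cmp$time_idx, mean_diff = cmp$mean_diff,
                 p_value = cmp$p_values, bh_reject = cmp$bh$reject),
      file.path(out_dir, "vmd_timecourse_stats.csv"), row.names = FALSE)
  })

  run_stage("ephys", function() {
    units <- data.frame(baseline_hz = rep(4, 6), evoked_hz = rep(16, 6),
                        reduction = rep(0.7, 6),
                        class = rep(c("RS", "FS"), 3))
    tt <- make_trial_table("grating", 2 * n_trials, duration_s = 0.9, gap_s = 2)
    tt$condition <- rep(c("control", "opto"), n_trials)
    sess <- generate_spike_session(units, tt, seed = substream_seed(seed, "ephys"))
    cls <- classify_units(sess$waveforms, sess$fs)
    rows <- lapply(seq_len(nrow(units)), function(u) {
      rates <- trial_rates(sess$spikes[[u]], tt)
      ctrl <- tt$condition == "control"
      ce <- mean(rates$evoked_hz[ctrl]) - mean(rates$baseline_hz[ctrl])
      le <- mean(rates$evoked_hz[!ctrl]) - mean(rates$baseline_hz[!ctrl])
      data.frame(unit = u, class = cls$labels[u],
                 z_control = zscore_fr(rates$evoked_hz[ctrl], rates$baseline_hz[ctrl]),
                 reduction_pct = percent_reduction(ce, le))
    })
    utils::write.csv(do.call(rbind, rows), file.path(out_dir, "units.csv"),
                     row.names = FALSE)
  })

  run_stage("anatomy", function() {
    areas <- data.frame(name = c("POR", "LI", "LM"),
                        amp_gfp = c(100, 70, 20), depth_gfp = c(0.3, 0.3, 0.35),
                        amp_tdt = c(20, 40, 90), depth_tdt = c(0.4, 0.4, 0.45))
    secs <- generate_anatomy_sections(areas, seed = substream_seed(seed, "anat"))
    totals <- sapply(c("gfp", "tdt"), function(f) {
      sapply(areas$name, function(a) {
        sum(vapply(secs, function(s) {
          area_total_fluorescence(s$images[[f]], s$boxes[[a]],
                                  s$background[[f]],
                                  corrected = config$fraction_on_corrected)
        }, 0))
      })
    })
    frac <- apply(totals, 2, fraction_of_total)
    utils::write.csv(data.frame(area = rownames(frac), frac),
                     file.path(out_dir, "afferent_fractions.csv"),
                     row.names = FALSE)
  })

  run_stage("photometry", function() {
    sessions <- lapply(seq_len(n_mice), function(m) {
      mseed <- substream_seed(seed, paste0("phot-mouse-", m))
      running <- generate_running_trace(60 + n_pairs * 15, seed = mseed)
      pr <- generate_coupled_replay_trials(running, n_pairs)
      rec <- vmd_records(pr$trials, pr$stimuli, running,
                         threshold = config$vmd_threshold)
      trials <- pr$trials
      trials$vmd_label <- rec$label[match(trials$trial_id, rec$trial_id)]
      ps <- generate_photometry_session(trials, s_pos = 0.5, seed = mseed)
      corr <- isosbestic_correct(ps$signal, ps$control, ps$frame_rate, trials)
      list(dff = corr$dff, trials = trials, records = rec,
           frame_rate = ps$frame_rate)
    })
    ph <- photometry_vmd_summary(sessions, label = "positive",
                                 window_s = config$timecourse_window_s,
                                 alpha = config$alpha)
    utils::write.csv(ph$bins, file.path(out_dir, "photometry_bins.csv"),
                     row.names = FALSE)
  })

  report <- list(status = as.list(status), config_digest = digest,
                 summary = if (length(summary_rows)) do.call(rbind, summary_rows) else NULL,
                 warnings = warns)
  class(report) <- "pipeline_report"
  if ("report" %in% stages) {
    status["report"] <- "ok"
    report$status <- as.list(status)
    lines <- c("# Pipeline report", "",
               sprintf("- config digest: %s", digest),
               sprintf("- %s: %s", names(status), status))
    writeLines(lines, file.path(out_dir, "report.md"))
    jsonlite::write_json(report[c("status", "config_digest", "warnings")],
                         file.path(out_dir, "report.json"), auto_unbox = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (s in names(x$status)) cat(sprintf("  %-10s %s\n", s, x$status[[s]]))
  if (length(x$warnings)) cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  invisible(x)
}

#' Command-line entry point
#'
#' `tectovis_main(c("all", "--out", "results", "--seed", "7"))` runs the
#' requested stages. Used by the `tectovis` script; exposed for testing.
#'
#' @param args character vector of CLI arguments.
#' @return the pipeline report, invisibly. Exits nonzero (by returned
#'   status) on any stage error.
#' @export
tectovis_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1L] else default
  }
  stages <- setdiff(args[!startsWith(args, "--")],
                    args[which(startsWith(args, "--")) + 1L])
  if (!length(stages) || identical(stages, "all")) stages <- "all"
  rep <- run_pipeline(out_dir = get_opt("--out", "results"),
                      config = get_opt("--config", NULL) %||% default_config(),
                      stages = stages,
                      seed = as.integer(get_opt("--seed", "1")))
  failed <- grepl("^failed", unlist(rep$status))
  attr(rep, "exit_status") <- if (any(failed)) 1L else 0L
  invisible(rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
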