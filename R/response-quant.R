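#' Select the most responsive pixels of an area
#'
#' For moving-dot analyses only the top fraction of responding pixels inside
#' the area mask is used. For intra-hemispheric comparisons the ranking image
#' must be the average of the control and experimental mean-response images,
#' so pixel selection is unbiased between conditions (see
#' [average_rank_image()]).
#'
#' @param rank_image matrix of ranking values (mean response per pixel).
#' @param mask logical matrix; the area mask.
#' @param fraction fraction of mask pixels to keep, in (0, 1].
#' @return integer vector of linear pixel indices (row-major consistent with
#'   R's column-major linear indexing of the image matrix), the
#'   `ceiling(fraction * sum(mask))` highest-ranked pixels; ties broken by
#'   lower linear index.
#' @export
select_top_pixels <- function(rank_image, mask, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop_param("fraction must be in (0, 1]")
  idx <- which(mask)
  if (!length(idx)) stop_param("empty mask")
  n <- ceiling(fraction * length(idx))
  ord <- idx[order(-rank_image[idx], idx)]
  sort(ord[seq_len(n)])
}

#' @rdname select_top_pixels
#' @param mean_images list of per-condition mean response images.
#' @export
average_rank_image <- function(mean_images) {
  Reduce(`+`, mean_images) / length(mean_images)
}

#' Mean response image of a dff object
#'
#' @param dff a `dff_trials` object.
#' @param trial_ids optional subset of trial ids.
#' @return matrix: per-pixel response averaged over the response window and
#'   over trials.
#' @export
mean_response_image <- function(dff, trial_ids = NULL) {
  keep <- if (is.null(trial_ids)) seq_along(dff$trials_dff) else {
    which(vapply(dff$trials_dff, function(x) x$trial$trial_id, 1L) %in% trial_ids)
  }
  imgs <- lapply(dff$trials_dff[keep], function(x) {
    apply(x$dff, c(2, 3), mean)
  })
  Reduce(`+`, imgs) / length(imgs)
}

#' Per-trial scalar responses over a pixel subset
#'
#' The response of a trial is the delta-F/F averaged over the selected pixels
#' and over the analysis window (stimulus onset until 0.5 s after offset; the
#' window is fixed when the `dff_trials` object is built).
#'
#' @param dff a `dff_trials` object.
#' @param pixels linear pixel indices (from [select_top_pixels()]) or a
#'   logical mask matrix.
#' @param trial_ids optional subset of trial ids.
#' @return list with `responses` (one scalar per trial, named by trial id)
#'   and `mean`.
#' @export
trial_response <- function(dff, pixels, trial_ids = NULL) {
  if (is.matrix(pixels)) pixels <- which(pixels)
  if (!length(pixels)) stop_param("empty pixel subset")
  keep <- if (is.null(trial_ids)) seq_along(dff$trials_dff) else {
    which(vapply(dff$trials_dff, function(x) x$trial$trial_id, 1L) %in% trial_ids)
  }
  res <- vapply(dff$trials_dff[keep], function(x) {
    nt <- dim(x$dff)[1]
    m <- matrix(x$dff, nt)
    mean(m[, pixels])
  }, 0)
  names(res) <- vapply(dff$trials_dff[keep], function(x) as.character(x$trial$trial_id), "")
  list(responses = res, mean = mean(res))
}

#' Per-trial area response time courses
#'
#' @param dff a `dff_trials` object.
#' @param mask logical area mask or linear pixel indices.
#' @param n_samples number of time samples to keep from onset (trials shorter
#'   than this are right-padded with `NA`).
#' @return matrix `trials x n_samples` of delta-F/F averaged over the mask;
#'   rownames are trial ids.
#' @export
area_trial_traces <- function(dff, mask, n_samples) {
  pixels <- if (is.matrix(mask)) which(mask) else mask
  out <- matrix(NA_real_, length(dff$trials_dff), n_samples)
  for (i in seq_along(dff$trials_dff)) {
    x <- dff$trials_dff[[i]]
    w <- which(x$time >= 0)
    nt <- min(length(w), n_samples)
    m <- matrix(x$dff, dim(x$dff)[1])
    out[i, seq_len(nt)] <- rowMeans(m[w[seq_len(nt)], pixels, drop = FALSE])
  }
  rownames(out) <- vapply(dff$trials_dff, function(x) as.character(x$trial$trial_id), "")
  out
}

#' Area responsiveness filter
#'
#' An area is responsive when its mean response exceeds the baseline mean by
#' `k` baseline sample standard deviations (sample SD, n-1 denominator).
#' Non-responsive areas are excluded from downstream silencing comparisons.
#'
#' @param responses per-trial responses under control conditions.
#' @param baseline_samples per-trial baseline values (same units).
#' @param k number of SDs (2 by default).
#' @return `TRUE`/`FALSE`, or `NA` with a warning when the baseline SD is 0
#'   (indeterminate; excluded).
#' @export
area_responsive <- function(responses, baseline_samples, k = 2) {
  if (length(baseline_samples) < 2) stop_param("need >= 2 baseline samples")
  s <- stats::sd(baseline_samples)
  if (s == 0) {
    warning("baseline SD is 0: responsiveness indeterminate; area excluded")
    return(NA)
  }
  mean(responses) >= mean(baseline_samples) + k * s
}

#' Intra-hemispheric silencing effect size
#'
#' Remaining fraction and percent reduction of the visual response after
#' silencing, normalised by the control response. Negative treated means are
#' not clipped, so reductions above 100% (or negative reductions, i.e.
#' increases) are reported as computed.
#'
#' @param control_mean,treated_mean mean responses; `control_mean` must be
#'   positive.
#' @return list with `remaining` (`treated/control`) and `reduction_pct`
#'   (`(1 - remaining) * 100`).
#' @export
percent_change_intra <- function(control_mean, treated_mean) {
  if (control_mean <= 0) stop_param("control mean must be positive")
  remaining <- treated_mean / control_mean
  list(remaining = remaining, reduction_pct = (1 - remaining) * 100)
}

#' Inter-hemispheric silencing comparison
#'
#' Each area's response is first normalised to the V1 response of the same
#' hemisphere (cancelling any global gain difference between hemispheres);
#' the relative response is the ratio of the silenced-hemisphere normalised
#' value to the control-hemisphere normalised value.
#'
#' @param treated,control named numeric vectors of per-area mean responses,
#'   one per hemisphere, both containing `"V1"`.
#' @return data.frame `area`, `relative`, `reduction_pct` (V1 row included
#'   with relative 1 by construction of the normalisation).
#' @export
interhemispheric_compare <- function(treated, control) {
  for (v in list(treated, control)) {
    if (!"V1" %in% names(v)) stop_param("both hemispheres need a V1 entry")
  }
  if (treated[["V1"]] <= 0 || control[["V1"]] <= 0) {
    stop_param("V1 mean must be positive in both hemispheres")
  }
  areas <- intersect(names(treated), names(control))
  rel <- (treated[areas] / treated[["V1"]]) / (control[areas] / control[["V1"]])
  data.frame(area = areas, relative = as.numeric(rel),
             reduction_pct = (1 - as.numeric(rel)) * 100,
             row.names = NULL)
}

#' Two-condition comparison by t test
#'
#' Paired t tests for intra-hemispheric comparisons, unpaired for
#' inter-hemispheric ones. A paired comparison of identical vectors (all
#' differences zero, t undefined) reports p = 1.
#'
#' @param group_a,group_b numeric vectors (>= 2 observations each; equal
#'   length when `paired`).
#' @param paired paired comparison?
#' @param alpha significance level for the `significant` flag.
#' @return list `statistic`, `p_value`, `significant`, `test_name`.
#' @export
compare_conditions <- function(group_a, group_b, paired = FALSE, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_param("need >= 2 observations per group")
  }
  if (paired && length(group_a) != length(group_b)) {
    stop_param("paired comparison requires equal lengths")
  }
  if (paired && stats::sd(group_a - group_b) == 0) {
    d <- mean(group_a - group_b)
    # zero-difference guard: t undefined, report p = 1; a constant nonzero
    # difference has infinite t
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0,
                significant = d != 0, test_name = "paired t-test"))
  }
  tt <- stats::t.test(group_a, group_b, paired = paired)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value <= alpha,
       test_name = if (paired) "paired t-test" else "unpaired t-test")
}
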