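#' Per-trial delta-F/F
#'
#' For each trial, the baseline map `F0` is the pixelwise mean over the 1 s
#' window preceding stimulus onset; delta-F/F is `(F - F0) / F0` for frames
#' from onset until `pad_s` after offset.
#'
#' @param movie a `widefield_movie` (signal channel, optionally hemodynamic-
#'   corrected).
#' @param trials trial table.
#' @param baseline_s pre-onset baseline window length (s).
#' @param pad_s post-offset padding of the response window (s).
#' @return object of class `dff_trials`: list of per-trial records, each with
#'   `time` (s relative to onset), `dff` (frames x rows x cols), `f0`
#'   (baseline map) and the trial row; plus `frame_rate` and `trials`.
#' @export
compute_dff <- function(movie, trials, baseline_s = 1, pad_s = 0.5) {
  fr <- movie$frame_rate
  nT <- dim(movie)[1]
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_s[i]; off <- trials$offset_s[i]
    b0 <- floor((on - baseline_s) * fr) + 1L
    b1 <- floor(on * fr)
    if (b0 < 1L) stop_param("trial %d lacks %g s of pre-stimulus frames",
                            trials$trial_id[i], baseline_s)
    r0 <- floor(on * fr) + 1L
    r1 <- min(floor((off + pad_s) * fr), nT)
    f0 <- apply(movie$data[b0:b1, , , drop = FALSE], c(2, 3), mean)
    nbad <- sum(f0 <= 0)
    if (nbad > 0) {
      stop_param("degenerate baseline: F0 <= 0 at %d pixel(s) in trial %d",
                 nbad, trials$trial_id[i])
    }
    fr_idx <- r0:r1
    dff <- sweep(sweep(movie$data[fr_idx, , , drop = FALSE], c(2, 3), f0, "-"),
                 c(2, 3), f0, "/")
    out[[i]] <- list(time = (fr_idx - 1L) / fr - on, dff = dff, f0 = f0,
                     trial = trials[i, ])
  }
  structure(list(trials_dff = out, frame_rate = fr, trials = trials),
            class = "dff_trials")
}

#' Hemodynamic correction of a widefield movie
#'
#' The isosbestic channel is scaled pixelwise to the signal channel by a
#' least-squares fit over non-stimulus frames, then its fluctuation is
#' subtracted from the signal, preserving the signal baseline:
#' `corrected = signal - beta * (iso - mean(iso_fit))`.
#'
#' @param signal,isosbestic `widefield_movie`s of identical shape.
#' @param trials optional trial table; frames inside
#'   `[onset, offset + 2 s]` are excluded from the fit so evoked signal is
#'   not absorbed into the scaling.
#' @return corrected `widefield_movie`. If the isosbestic channel has zero
#'   variance everywhere the correction is skipped with a warning and the
#'   signal is returned unchanged, with attribute `corrected = FALSE`.
#' @export
hemodynamic_correct <- function(signal, isosbestic, trials = NULL) {
  if (!identical(dim(signal), dim(isosbestic))) {
    stop_param("signal and isosbestic channels differ in shape")
  }
  nT <- dim(signal)[1]
  fit_idx <- rep(TRUE, nT)
  if (!is.null(trials)) {
    tgrid <- (seq_len(nT) - 1L) / signal$frame_rate
    for (i in seq_len(nrow(trials))) {
      fit_idx[tgrid >= trials$onset_s[i] & tgrid < trials$offset_s[i] + 2] <- FALSE
    }
    if (!any(fit_idx)) fit_idx <- rep(TRUE, nT)
  }
  d <- dim(signal)
  S <- matrix(signal$data, nT)
  I <- matrix(isosbestic$data, nT)
  If <- I[fit_idx, , drop = FALSE]
  Sf <- S[fit_idx, , drop = FALSE]
  im <- colMeans(If)
  sm <- colMeans(Sf)
  iv <- colSums(sweep(If, 2, im)^2)
  if (all(iv == 0)) {
    warning("isosbestic channel has zero variance; correction skipped")
    out <- signal
    attr(out, "corrected") <- FALSE
    return(out)
  }
  beta <- ifelse(iv > 0, colSums(sweep(If, 2, im) * sweep(Sf, 2, sm)) / iv, 0)
  corr <- S - sweep(sweep(I, 2, im), 2, beta, "*")
  out <- widefield_movie(array(corr, d), signal$frame_rate, signal$channel)
  attr(out, "corrected") <- TRUE
  out
}

#' Trial-averaged response maps per patch location
#'
#' One mean-response image per patch position of the plus-sign mapping
#' stimulus, averaged over the stimulus window and over trials.
#'
#' @param dff a `dff_trials` object containing patch trials.
#' @param patch_indices patch positions expected (default 0:4).
#' @return named list of `rows x cols` response images (`patch0` ... ).
#' @export
map_patch_responses <- function(dff, patch_indices = 0:4) {
  patch_of <- vapply(dff$trials_dff, function(x) {
    p <- x$trial$patch_index
    if (is.na(p)) -1L else as.integer(p)
  }, 1L)
  maps <- lapply(patch_indices, function(p) {
    idx <- which(patch_of == p)
    if (!length(idx)) stop_param("no trials for patch %d", p)
    imgs <- lapply(idx, function(i) {
      x <- dff$trials_dff[[i]]
      w <- x$time >= 0  # stimulus window plus pad
      apply(x$dff[w, , , drop = FALSE], c(2, 3), mean)
    })
    Reduce(`+`, imgs) / length(imgs)
  })
  names(maps) <- paste0("patch", patch_indices)
  maps
}

# 4-connected component labelling of a logical matrix
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  H <- nrow(mask); W <- ncol(mask)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% H + 1L
      c <- (q - 1L) %/% H + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1L && d[1] <= H && d[2] >= 1L && d[2] <= W) {
          j <- (d[2] - 1L) * H + d[1]
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

#' Delineate visual areas from patch response maps
#'
#' Each patch map is binarised at `threshold_frac` of its own maximum; the
#' binary maps are overlaid and the union partitioned into connected
#' components. Components are labelled via a template of expected area
#' centres (nearest centre wins, greedy by distance, each name used once).
#' Pixels claimed by several patch maps are assigned to the map with the
#' larger response there; exact ties go to the lower patch index.
#'
#' @param patch_maps named list of response images (see
#'   [map_patch_responses()]).
#' @param template data.frame `name`, `row`, `col` of expected area centres
#'   (0-based pixel coordinates), e.g. `default_area_layout()`.
#' @param threshold_frac binarisation fraction in (0, 1).
#' @return `area_mask_set`: named list of disjoint logical masks, with
#'   attributes `threshold_frac` and `patch_winner` (matrix of winning patch
#'   index per pixel, NA outside the union).
#' @export
delineate_areas <- function(patch_maps, template, threshold_frac = 0.5) {
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop_param("threshold_frac must be in (0, 1)")
  }
  bins <- lapply(seq_along(patch_maps), function(i) {
    m <- patch_maps[[i]]
    mx <- max(m)
    if (mx <= 0) stop_param("no responsive pixels in map %s", names(patch_maps)[i])
    m >= threshold_frac * mx
  })
  union <- Reduce(`|`, bins)
  # winning patch per pixel: larger response wins, ties -> lower patch index
  winner <- matrix(NA_integer_, nrow(union), ncol(union))
  best <- matrix(-Inf, nrow(union), ncol(union))
  for (i in seq_along(patch_maps)) {
    m <- patch_maps[[i]]
    take <- bins[[i]] & (m > best)
    winner[take] <- i - 1L
    best[take] <- m[take]
  }
  lab <- label_components(union)
  ncomp <- max(lab)
  if (ncomp == 0L) stop_param("no responsive pixels")
  comp_centre <- t(vapply(seq_len(ncomp), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    colMeans(idx) - 1  # 0-based
  }, c(0, 0)))
  # greedy assignment of component -> template name by distance
  dist <- outer(seq_len(ncomp), seq_len(nrow(template)),
                Vectorize(function(k, j) {
                  sqrt((comp_centre[k, 1] - template$row[j])^2 +
                       (comp_centre[k, 2] - template$col[j])^2)
                }))
  masks <- list()
  used_comp <- rep(FALSE, ncomp)
  used_tpl <- rep(FALSE, nrow(template))
  for (step in seq_len(min(ncomp, nrow(template)))) {
    d <- dist
    d[used_comp, ] <- Inf
    d[, used_tpl] <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    masks[[template$name[ij[2]]]] <- lab == ij[1]
    used_comp[ij[1]] <- TRUE
    used_tpl[ij[2]] <- TRUE
  }
  masks <- masks[order(match(names(masks), template$name))]
  structure(masks, class = "area_mask_set",
            threshold_frac = threshold_frac, patch_winner = winner)
}

#' Rigid translation registration of two session images
#'
#' Finds the integer pixel shift of `moving` relative to `reference` that
#' maximises the normalised cross-correlation of the overlapping region.
#'
#' @param reference,moving matrices (e.g. mean vascular images).
#' @param max_shift search radius in pixels.
#' @param min_cor registration fails below this correlation peak.
#' @return integer vector `c(dr, dc)`: `moving[r, c]` corresponds to
#'   `reference[r + dr, c + dc]`.
#' @export
register_sessions <- function(reference, moving, max_shift = 10, min_cor = 0.2) {
  stopifnot(identical(dim(reference), dim(moving)))
  H <- nrow(reference); W <- ncol(reference)
  best <- c(0L, 0L); best_cor <- -Inf
  for (dr in -max_shift:max_shift) {
    for (dc in -max_shift:max_shift) {
      r_ref <- max(1, 1 + dr):min(H, H + dr)
      c_ref <- max(1, 1 + dc):min(W, W + dc)
      r_mov <- r_ref - dr
      c_mov <- c_ref - dc
      a <- reference[r_ref, c_ref]
      b <- moving[r_mov, c_mov]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      cc <- stats::cor(as.vector(a), as.vector(b))
      if (cc > best_cor) {
        best_cor <- cc
        best <- c(dr, dc)
      }
    }
  }
  if (best_cor < min_cor) {
    stop_param("registration failure: correlation peak %.3f < %.2f",
               best_cor, min_cor)
  }
  structure(as.integer(best), correlation = best_cor)
}

#' Apply an integer shift to a mask set
#'
#' @param masks `area_mask_set` or list of logical matrices.
#' @param shift `c(dr, dc)` from [register_sessions()].
#' @return shifted masks (pixels shifted out of frame are dropped).
#' @export
shift_masks <- function(masks, shift) {
  out <- lapply(masks, function(m) {
    H <- nrow(m); W <- ncol(m)
    res <- matrix(FALSE, H, W)
    idx <- which(m, arr.ind = TRUE)
    idx[, 1] <- idx[, 1] + shift[1]
    idx[, 2] <- idx[, 2] + shift[2]
    keep <- idx[, 1] >= 1 & idx[, 1] <= H & idx[, 2] >= 1 & idx[, 2] <= W
    res[idx[keep, , drop = FALSE]] <- TRUE
    res
  })
  attributes(out) <- attributes(masks)
  out
}
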