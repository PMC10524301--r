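#' Raw fluorescence density versus cortical depth
#'
#' Within a bounding box aligned so that the x axis (image columns) spans
#' pia to white matter and the y axis (rows) the area's tangential extent,
#' the density at each depth is the mean fluorescence across y.
#'
#' @param image numeric matrix (rows x cols).
#' @param box list with integer vectors `rows` and `cols` (1-based).
#' @return data.frame `depth` (normalised \[0, 1\], bin midpoints) and
#'   `density`.
#' @export
depth_density_profile <- function(image, box) {
  if (!length(box$rows) || !length(box$cols)) stop_param("empty bounding box")
  sub <- image[box$rows, box$cols, drop = FALSE]
  n <- ncol(sub)
  data.frame(depth = (seq_len(n) - 0.5) / n, density = colMeans(sub))
}

#' Subtract the autofluorescence baseline from a depth profile
#'
#' The baseline is estimated per section and per fluorophore from sample
#' points with no visible labelling, interpolated piecewise-linearly along
#' depth, and subtracted. Negative corrected densities are retained (no
#' clipping).
#'
#' @param profile data.frame `depth`, `density` from
#'   [depth_density_profile()].
#' @param background data.frame `depth`, `value`: background sample points.
#'   Their depth span must cover at least half of \[0, 1\].
#' @return data.frame `depth`, `density` (corrected), `baseline`.
#' @export
subtract_autofluorescence <- function(profile, background) {
  if (is.null(background) || nrow(background) < 2) {
    stop_param("background sample points required")
  }
  span <- diff(range(background$depth))
  if (span < 0.5) {
    stop_param("background points cover %.0f%% of the depth range (< 50%%)",
               100 * span)
  }
  base <- stats::approx(background$depth, background$value,
                        xout = profile$depth, rule = 2)$y
  data.frame(depth = profile$depth, density = profile$density - base,
             baseline = base)
}

#' Normalise corrected profiles within a mouse
#'
#' Division by the maximum corrected density across all of a mouse's
#' sections, independently per fluorophore, so profiles are comparable
#' across areas while preserving relative magnitudes within a fluorophore.
#'
#' @param profiles list of corrected profile data.frames (one fluorophore,
#'   one mouse).
#' @return list of the same profiles with `density` divided by the shared
#'   maximum.
#' @export
normalize_profiles <- function(profiles) {
  if (!length(profiles)) stop_param("need >= 1 profile")
  mx <- max(vapply(profiles, function(p) max(p$density), 0))
  if (mx <= 0) stop_param("maximum corrected density is <= 0: cannot normalise")
  lapply(profiles, function(p) {
    p$density <- p$density / mx
    p
  })
}

#' Concatenate multi-section profiles by per-bin maximum density
#'
#' The depth axis is broken into `n_bins` equal-width half-open bins; bin
#' `b` of the output is taken from the section whose mean density within
#' that bin is greatest (ties to the lowest section id).
#'
#' @param profiles list of profile data.frames on the same normalised depth
#'   grid (one per section).
#' @param n_bins number of depth bins (10 by default).
#' @return data.frame `bin`, `depth_lo`, `depth_hi`, `density` (mean within
#'   the chosen bin), `section`.
#' @export
concatenate_bins <- function(profiles, n_bins = 10) {
  if (!length(profiles)) stop_param("need >= 1 section")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  rows <- lapply(seq_len(n_bins), function(b) {
    means <- vapply(profiles, function(p) {
      w <- p$depth >= edges[b] & (p$depth < edges[b + 1L] | b == n_bins)
      if (!any(w)) return(-Inf)
      mean(p$density[w])
    }, 0)
    sec <- which.max(means)  # ties -> lowest section id
    data.frame(bin = b, depth_lo = edges[b], depth_hi = edges[b + 1L],
               density = means[sec], section = sec)
  })
  do.call(rbind, rows)
}

#' Fraction of total fluorescence per area
#'
#' @param totals named numeric vector of per-area total fluorescence (one
#'   fluorophore, one mouse).
#' @return named vector of fractions summing to 1.
#' @export
fraction_of_total <- function(totals) {
  s <- sum(totals)
  if (s <= 0) stop_param("all area totals are <= 0")
  totals / s
}

#' Total (baseline-corrected) fluorescence of an area box
#'
#' Sum of pixels across the full box after per-depth baseline subtraction
#' (or raw, when `corrected = FALSE`).
#'
#' @param image section image.
#' @param box bounding box (see [depth_density_profile()]).
#' @param background background sample points (required when `corrected`).
#' @param corrected subtract the autofluorescence baseline first?
#' @return scalar total fluorescence.
#' @export
area_total_fluorescence <- function(image, box, background = NULL,
                                    corrected = TRUE) {
  sub <- image[box$rows, box$cols, drop = FALSE]
  if (corrected) {
    n <- ncol(sub)
    depth <- (seq_len(n) - 0.5) / n
    if (is.null(background)) stop_param("background points required for corrected totals")
    base <- stats::approx(background$depth, background$value,
                          xout = depth, rule = 2)$y
    sub <- sweep(sub, 2, base)
  }
  sum(sub)
}

#' Simulate coronal sections with laminar axonal fluorescence
#'
#' Each section carries, per fluorophore, a depth-dependent autofluorescence
#' baseline (linear ramp), one Gaussian laminar band per area box, and
#' optional pixel noise. Per-section brightness varies so multi-section
#' concatenation is exercised. A label-free background strip provides the
#' autofluorescence sample points.
#'
#' @param areas data.frame with `name` and, per fluorophore `f` in
#'   `fluorophores`, columns `amp_<f>` (band amplitude >= 0) and
#'   `depth_<f>` (laminar peak depth in \[0, 1\], pia to white matter).
#' @param n_sections number of sections.
#' @param fluorophores fluorophore tags (GFP labels tecto-recipient pulvinar
#'   afferents, tdTomato labels V1 afferents in the motivating experiment).
#' @param depth_px pixels along the depth axis.
#' @param box_px tangential height of each area box (pixels).
#' @param band_sd laminar band SD (normalised depth units).
#' @param autofl_base,autofl_slope autofluorescence at the pia and its
#'   linear increase toward white matter.
#' @param noise_sd pixel noise SD.
#' @param seed integer seed; identical seeds give identical images.
#' @return list of sections; each has `images` (named list per fluorophore),
#'   `boxes` (named list of `rows`/`cols` per area), `background` (named
#'   list of `depth`/`value` data.frames per fluorophore) and `scale`
#'   (per-section brightness). A `truth` attribute records the inputs.
#' @export
generate_anatomy_sections <- function(areas, n_sections = 3,
                                      fluorophores = c("gfp", "tdt"),
                                      depth_px = 100, box_px = 30,
                                      band_sd = 0.08, autofl_base = 20,
                                      autofl_slope = 10, noise_sd = 0,
                                      seed = 1) {
  for (f in fluorophores) {
    amp <- areas[[paste0("amp_", f)]]
    dep <- areas[[paste0("depth_", f)]]
    if (is.null(amp) || is.null(dep)) {
      stop_param("areas must carry amp_%s and depth_%s columns", f, f)
    }
    if (any(amp < 0)) stop_param("band amplitudes must be >= 0")
    if (any(dep < 0 | dep > 1)) stop_param("band depths must lie in [0, 1]")
  }
  nA <- nrow(areas)
  gap <- 4L
  H <- nA * (box_px + gap) + box_px  # area boxes + background strip
  depth <- (seq_len(depth_px) - 0.5) / depth_px
  scales <- with_seed(substream_seed(seed, "anatomy-scales"),
                      matrix(stats::runif(n_sections * nA, 0.5, 1),
                             n_sections, nA))
  sections <- with_seed(substream_seed(seed, "anatomy-noise"), {
    lapply(seq_len(n_sections), function(s) {
      boxes <- list()
      images <- lapply(fluorophores, function(f) {
        img <- matrix(rep(autofl_base + autofl_slope * depth, each = H), H, depth_px)
        for (a in seq_len(nA)) {
          r0 <- (a - 1L) * (box_px + gap) + 1L
          rows <- r0:(r0 + box_px - 1L)
          boxes[[areas$name[a]]] <<- list(rows = rows, cols = seq_len(depth_px))
          band <- areas[[paste0("amp_", f)]][a] * scales[s, a] *
            exp(-(depth - areas[[paste0("depth_", f)]][a])^2 / (2 * band_sd^2))
          img[rows, ] <- img[rows, ] + rep(band, each = box_px)
        }
        if (noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), sd = noise_sd), H)
        img
      })
      names(images) <- fluorophores
      bg_rows <- (H - box_px + 1L):H  # label-free strip
      background <- lapply(fluorophores, function(f) {
        data.frame(depth = depth,
                   value = colMeans(images[[f]][bg_rows, , drop = FALSE]))
      })
      names(background) <- fluorophores
      list(images = images, boxes = boxes, background = background,
           scale = scales[s, ])
    })
  })
  attr(sections, "truth") <- list(areas = areas, scales = scales,
                                  band_sd = band_sd, seed = seed)
  sections
}
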