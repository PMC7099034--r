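#' Nuclear and perinuclear-ring intensity series
#'
#' Segments the nucleus within the ROI at the first frame (Otsu threshold
#' on the ROI sub-volume, largest 26-connected component of at least
#' `min_volume` voxels) and tracks it frame to frame as the component with
#' maximal overlap with the previous mask (ties broken by larger volume;
#' if nothing overlaps, the previous mask is carried over). Reports the
#' mean intensity inside the nuclear mask and inside a surrounding
#' xy ring of width `ring_width_px`, separated from the mask by a gap of
#' `ring_gap_px` (the half-max segmentation mask underestimates the true
#' nuclear boundary, so a flush ring would sit on the nuclear intensity
#' tail and confound leakage with nuclear shape changes). The ring spans
#' the full z-range by default (`ring_z = "all"`): the nuclear z-extent
#' changes abruptly at flattening, and a ring tied to it would jump for
#' geometric rather than photometric reasons; `ring_z = "nucleus"`
#' restricts it to the nucleus' slices. The ring stays inside the ROI
#' footprint and excludes any `exclude` masks such as other nuclei — the
#' readout in which leaked DNA dye appears.
#'
#' @param stack an [image_stack()].
#' @param roi a [cell_roi()].
#' @param nucleus_channel channel name or index.
#' @param ring_width_px ring width in pixels (default 3).
#' @param ring_gap_px gap between the mask footprint and the ring (default 3).
#' @param min_volume minimum nuclear component size in voxels (default 30).
#' @param exclude optional list of `(Y, X)` logical masks to exclude from
#'   the ring.
#' @param t_range optional 1-based inclusive frame range to restrict the
#'   series to (e.g. a window around flattening).
#' @param ring_z `"all"` (default) or `"nucleus"` (see above).
#' @return a `nuclear_series`: data frame `(time_min, nuc_mean, ring_mean,
#'   nuc_voxels)`; `NULL` (with a warning) if the nucleus is never
#'   segmentable — the per-cell failure record.
#' @export
nuclear_series <- function(stack, roi, nucleus_channel, ring_width_px = 3L,
                           ring_gap_px = 3L, min_volume = 30L, exclude = NULL,
                           t_range = NULL, ring_z = c("all", "nucleus")) {
  ring_z <- match.arg(ring_z)
  d <- dim(stack$data)
  ch <- channel_index(stack, nucleus_channel)
  foot <- roi_mask(roi, d[4], d[5])
  times <- frame_times(stack)
  foot3 <- aperm(array(foot, c(d[4], d[5], d[3])), c(3, 1, 2))
  prev_mask <- NULL
  prev_mean <- NA_real_
  t_range <- t_range %||% c(1L, d[1])
  frames <- max(1L, t_range[1]):min(d[1], t_range[2])
  nuc_mean <- ring_mean <- nvox <- rep(NA_real_, length(frames))
  for (ii in seq_along(frames)) {
    t <- frames[ii]
    vol <- get_vol(stack, t, ch)
    vals <- vol[foot3]
    thr <- otsu_threshold(vals)
    # diffuse leaked dye can drag the Otsu split below the nucleus/halo
    # boundary; keep the tracked mask anchored to the nuclear brightness
    if (!is.null(prev_mask)) thr <- max(thr, 0.4 * prev_mean)
    mask <- foot3 & (vol > thr)
    lab <- label_components_3d(mask)
    keep <- which(vapply(lab$voxels, nrow, 0L) >= min_volume)
    sel <- NULL
    if (length(keep)) {
      if (is.null(prev_mask)) {
        sel <- keep[which.max(vapply(lab$voxels[keep], nrow, 0L))]
      } else {
        ov <- vapply(keep, function(k) sum(prev_mask[lab$voxels[[k]]]), 0)
        vsz <- vapply(lab$voxels[keep], nrow, 0L)
        best <- which(ov == max(ov))
        if (max(ov) > 0) sel <- keep[best[which.max(vsz[best])]]
        else sel <- NULL
      }
    }
    if (is.null(sel)) {
      if (is.null(prev_mask)) next  # not yet segmentable
      cur <- prev_mask
    } else {
      cur <- array(FALSE, d[c(3, 4, 5)])
      cur[lab$voxels[[sel]]] <- TRUE
      prev_mask <- cur
    }
    nuc_mean[ii] <- mean(vol[cur])
    prev_mean <- nuc_mean[ii]
    nvox[ii] <- sum(cur)
    ring_mean[ii] <- ring_intensity(vol, cur, foot, ring_width_px,
                                    ring_gap_px, exclude, ring_z)
  }
  if (all(is.na(nuc_mean))) {
    warning("nucleus never segmentable in ROI ", format(roi$cell_id))
    return(NULL)
  }
  out <- data.frame(time_min = times[frames], nuc_mean = nuc_mean,
                    ring_mean = ring_mean, nuc_voxels = nvox)
  class(out) <- c("nuclear_series", "data.frame")
  out
}

# mean intensity in the xy ring of given width around the nuclear
# footprint (separated by a gap)
ring_intensity <- function(vol, nuc_mask, foot, width, gap, exclude,
                           ring_z = "all") {
  zsel <- if (ring_z == "all") seq_len(dim(vol)[1]) else
    which(apply(nuc_mask, 1, any))
  nfoot <- apply(nuc_mask, c(2, 3), any)
  inner <- dilate_mask(nfoot, gap)
  ring2d <- dilate_mask(inner, width) & !inner & foot
  if (!is.null(exclude)) for (ex in exclude) ring2d <- ring2d & !ex
  if (!any(ring2d) || !length(zsel)) return(NA_real_)
  sub <- vol[zsel, , , drop = FALSE]
  m <- matrix(sub, length(zsel), length(nfoot))
  mean(m[, c(ring2d), drop = FALSE])
}

# binary dilation of a 2D mask by a chebyshev radius (small, loop-based)
dilate_mask <- function(m, r) {
  out <- m
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    sh <- shift_mask(m, dy, dx)
    out <- out | sh
  }
  out
}

shift_mask <- function(m, dy, dx) {
  n_y <- nrow(m); n_x <- ncol(m)
  out <- matrix(FALSE, n_y, n_x)
  ys <- seq_len(n_y) - dy; xs <- seq_len(n_x) - dx
  oky <- ys >= 1 & ys <= n_y; okx <- xs >= 1 & xs <= n_x
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Detect DNA leakage from the perinuclear ring series
#'
#' The ring baseline (mean, SD) is taken over pre-flattening frames;
#' leakage is the first frame at/after flattening where the ring mean
#' exceeds `baseline + max(k_sd * SD, min_rise)` sustained `sustain`
#' frames. `min_rise` guards against a near-zero baseline variance making
#' the threshold degenerate. With `refine = TRUE` the reported time is the
#' midpoint between the last quiet and first elevated frame.
#'
#' @param series a [nuclear_series()].
#' @param t_flattened flattening time in minutes (required).
#' @param k_sd baseline-SD multiplier (default 3).
#' @param sustain consecutive frames required (default 2).
#' @param min_rise minimum absolute rise over baseline (default 0.5).
#' @param refine midpoint refinement (default `TRUE`).
#' @return `t_leakage` in minutes, or `NA` if absent.
#' @export
detect_leakage <- function(series, t_flattened, k_sd = 3, sustain = 2L,
                           min_rise = 0.5, refine = TRUE) {
  if (is.na(t_flattened)) stop("t_flattened must be present to detect leakage")
  pre <- series$time_min < t_flattened & !is.na(series$ring_mean)
  if (sum(pre) < 3L) stop("need at least 3 pre-flattening frames for the ring baseline")
  mu <- mean(series$ring_mean[pre]); s <- sd(series$ring_mean[pre])
  thr <- mu + max(k_sd * s, min_rise)
  start <- which(series$time_min >= t_flattened)[1]
  if (is.na(start)) return(NA_real_)
  i <- first_sustained(series$ring_mean > thr, sustain, start = start)
  if (is.na(i)) return(NA_real_)
  if (refine && i > 1L) {
    (series$time_min[i - 1L] + series$time_min[i]) / 2
  } else series$time_min[i]
}
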