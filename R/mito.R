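#' Segment mitochondrial signal within a cell ROI at one frame
#'
#' Otsu threshold on the ROI sub-volume, 26-connected 3D components,
#' components smaller than `min_volume` voxels removed.
#'
#' @param stack an [image_stack()].
#' @param roi a [cell_roi()].
#' @param channel the mitochondria channel.
#' @param t 1-based frame (classification conventionally uses the first
#'   observation frame).
#' @param min_volume minimum component size in voxels (default 4).
#' @return list with `labels` (`(Z, Y, X)` integer array), `voxels` (list
#'   of component voxel-index matrices) and the stack calibration.
#' @export
segment_mito <- function(stack, roi, channel, t = 1L, min_volume = 4L) {
  d <- dim(stack$data)
  ch <- channel_index(stack, channel)
  foot <- roi_mask(roi, d[4], d[5])
  if (!any(foot)) stop("ROI footprint is empty")
  foot3 <- aperm(array(foot, c(d[4], d[5], d[3])), c(3, 1, 2))
  vol <- get_vol(stack, t, ch)
  thr <- otsu_threshold(vol[foot3])
  mask <- foot3 & (vol > thr)
  lab <- label_components_3d(mask)
  keep <- which(vapply(lab$voxels, nrow, 0L) >= min_volume)
  labels <- array(0L, d[c(3, 4, 5)])
  voxels <- lab$voxels[keep]
  for (k in seq_along(voxels)) labels[voxels[[k]]] <- k
  list(labels = labels, voxels = voxels,
       z_step_um = stack$z_step_um, xy_pixel_um = stack$xy_pixel_um)
}

#' Per-cell mitochondrial amount and shape features
#'
#' Volume from voxel count times physical voxel volume; per-component
#' elongation as the ratio of the largest to the middle principal-axis
#' length of the second-moment ellipsoid, computed in physical units
#' (anisotropic voxels handled by scaling coordinates before the moment
#' computation, with the voxel's own second moment added in). A component
#' is punctate when its elongation is below `elong_cutoff`;
#' `punctate_fraction` is volume-weighted. Zero components yield a zeroed
#' profile with `punctate_fraction = 1` (vacuously all-punctate).
#'
#' @param seg a [segment_mito()] result (or a list with `voxels` plus
#'   `z_step_um`, `xy_pixel_um`).
#' @param cell_id identifier stored on the profile.
#' @param elong_cutoff punctate/elongated boundary (default 2.5).
#' @return a `mito_profile`: list with `total_volume_um3`, `n_components`,
#'   `median_elongation`, `max_elongation`, `punctate_fraction`,
#'   `component_volumes_um3`, `component_elongations`; `group` and
#'   `flattened_within_4h` unset.
#' @export
mito_features <- function(seg, cell_id = NA, elong_cutoff = 2.5) {
  vox_vol <- seg$z_step_um * seg$xy_pixel_um^2
  n <- length(seg$voxels)
  if (n == 0L) {
    return(structure(list(cell_id = cell_id, total_volume_um3 = 0,
                          n_components = 0L, median_elongation = NA_real_,
                          max_elongation = NA_real_, punctate_fraction = 1,
                          component_volumes_um3 = numeric(0),
                          component_elongations = numeric(0),
                          elong_cutoff = elong_cutoff,
                          group = NA_integer_, flattened_within_4h = NA),
                     class = "mito_profile"))
  }
  vols <- vapply(seg$voxels, nrow, 0L) * vox_vol
  elong <- vapply(seg$voxels, function(v) {
    p <- cbind(v[, 1] * seg$z_step_um, v[, 2] * seg$xy_pixel_um,
               v[, 3] * seg$xy_pixel_um)
    cv <- stats::cov(p) * (nrow(p) - 1) / nrow(p)
    # add the voxel's own moments so single-voxel components are well-posed
    diag(cv) <- diag(cv) +
      c(seg$z_step_um, seg$xy_pixel_um, seg$xy_pixel_um)^2 / 12
    ax <- sqrt(pmax(sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
                         decreasing = TRUE), 1e-12))
    ax[1] / ax[2]
  }, 0)
  punct <- elong < elong_cutoff
  structure(list(cell_id = cell_id,
                 total_volume_um3 = sum(vols), n_components = n,
                 median_elongation = median(elong), max_elongation = max(elong),
                 punctate_fraction = sum(vols[punct]) / sum(vols),
                 component_volumes_um3 = vols, component_elongations = elong,
                 elong_cutoff = elong_cutoff,
                 group = NA_integer_, flattened_within_4h = NA),
            class = "mito_profile")
}

#' Assign the four-way mitochondrial morphology group
#'
#' Group 1: small amount, only punctate (volume <= `v_small` and
#' punctate fraction >= `purity`); group 2: small amount, mixed
#' punctate/elongated; group 3: moderate amount
#' (`v_small` < volume <= `v_moderate`); group 4: large amount
#' (volume > `v_moderate`). Deterministic; boundary values go to the
#' lower-numbered group.
#'
#' @param profile a [mito_features()] profile.
#' @param thresholds list with `v_small`, `v_moderate` (um^3, must be
#'   increasing) and `purity` (default `list(v_small = 12, v_moderate = 30,
#'   purity = 0.8)`; volumes are as the segmenter measures them — Otsu
#'   components include the resolution-blurred skirt of each organelle, so
#'   the cutoffs are calibrated on segmented synthetic cells, not on bare
#'   geometric volumes).
#' @return the profile with `group` set (integer 1-4).
#' @export
classify_group <- function(profile,
                           thresholds = list(v_small = 12, v_moderate = 30,
                                             purity = 0.8)) {
  th <- thresholds
  if (!(th$v_small < th$v_moderate))
    stop_config("thresholds", "v_small must be < v_moderate")
  v <- profile$total_volume_um3
  pf <- profile$punctate_fraction
  profile$group <- if (v <= th$v_small) {
    if (pf >= th$purity) 1L else 2L
  } else if (v <= th$v_moderate) 3L else 4L
  profile
}

#' Did a cell flatten within the observation horizon?
#' @param timeline an [event_timeline()] (or any list with `t_flattened`).
#' @param horizon_min horizon in minutes (default 240: four hours).
#' @export
flattening_outcome <- function(timeline, horizon_min = 240) {
  !is.na(timeline$t_flattened) && timeline$t_flattened <= horizon_min
}

#' Group-by-outcome contingency table
#'
#' 4 x 2 counts of morphology group against the flattening outcome, with
#' per-group flattened percentages (rounded to integer percent for
#' reporting; raw fractions retained) and the total cell count. Profiles
#' with unknown outcome are excluded with a message.
#'
#' @param profiles list of classified [mito_features()] profiles with
#'   `flattened_within_4h` set.
#' @return a `group_table`.
#' @export
contingency <- function(profiles) {
  known <- vapply(profiles, function(p) !is.na(p$flattened_within_4h), TRUE)
  if (any(!known))
    message(sum(!known), " profile(s) with unknown outcome excluded")
  profiles <- profiles[known]
  counts <- matrix(0L, 4L, 2L,
                   dimnames = list(paste0("group", 1:4),
                                   c("flattened", "not_flattened")))
  for (p in profiles) {
    j <- if (isTRUE(p$flattened_within_4h)) 1L else 2L
    counts[p$group, j] <- counts[p$group, j] + 1L
  }
  group_table(counts)
}

#' @rdname contingency
#' @param counts 4 x 2 matrix of counts `(group x flattened/not)`.
#' @export
group_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 2L)) || any(counts < 0))
    stop("counts must be a non-negative 4 x 2 matrix")
  dimnames(counts) <- list(paste0("group", 1:4), c("flattened", "not_flattened"))
  rows <- rowSums(counts)
  frac <- ifelse(rows > 0, counts[, 1] / rows, NA)
  structure(list(counts = counts,
                 flattened_fraction = frac,
                 flattened_percent = round(100 * frac),
                 total = sum(counts)),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat("<group_table>", x$total, "cells\n")
  for (g in 1:4)
    cat(sprintf("  group %d: %d:%d flattened:not (%s%%)\n", g,
                x$counts[g, 1], x$counts[g, 2],
                ifelse(is.na(x$flattened_percent[g]), "-",
                       x$flattened_percent[g])))
  invisible(x)
}

#' Time mitochondrial-signal disappearance in sub-ROIs
#'
#' Mean intensity per box per frame; per box, the disappearance is the
#' first frame at which the intensity falls below
#' `baseline mean - k_sd * SD` sustained `sustain` frames (baseline over
#' the first `n_baseline` frames). Boxes with (near-)zero baseline
#' variance are flagged degenerate. The cell-level `t_disappear` is the
#' median over boxes with a call; if `t_arrest` is given, the co-timing
#' `t_disappear - t_arrest` is reported.
#'
#' @param stack an [image_stack()].
#' @param roi a [cell_roi()].
#' @param channel mitochondria channel.
#' @param sub_rois list of boxes `list(x, y, z, half_px, half_z)` or
#'   explicit `list(xr =, yr =, zr =)` index ranges (1-based).
#' @param k_sd baseline-SD multiplier (default 3).
#' @param sustain consecutive frames (default 2).
#' @param n_baseline baseline frames (default 5).
#' @param t_arrest optional arrest time for the co-timing report.
#' @return list with `series` (box x frame matrix), `t_disappear_box`,
#'   `degenerate` (logical per box), `t_disappear` (cell median) and
#'   `co_timing_min`.
#' @export
mito_disappearance <- function(stack, roi, channel, sub_rois, k_sd = 3,
                               sustain = 2L, n_baseline = 5L, t_arrest = NA) {
  d <- dim(stack$data)
  ch <- channel_index(stack, channel)
  times <- frame_times(stack)
  series <- t(vapply(sub_rois, function(b) {
    if (is.null(b$xr)) {
      h <- b$half_px %||% 2L; hz <- b$half_z %||% 1L
      b <- list(xr = clamp((b$x - h):(b$x + h) + 1L, 1L, d[5]),
                yr = clamp((b$y - h):(b$y + h) + 1L, 1L, d[4]),
                zr = clamp((b$z - hz):(b$z + hz), 1L, d[3]))
    }
    vapply(seq_len(d[1]), function(t)
      mean(stack$data[t, ch, b$zr, b$yr, b$xr]), 0)
  }, numeric(d[1])))
  n_b <- nrow(series)
  t_box <- rep(NA_real_, n_b); degen <- rep(FALSE, n_b)
  for (i in seq_len(n_b)) {
    base <- series[i, seq_len(min(n_baseline, d[1]))]
    s <- sd(base)
    if (!is.finite(s) || s < 1e-9) { degen[i] <- TRUE; next }
    j <- first_sustained(series[i, ] < mean(base) - k_sd * s, sustain,
                         start = n_baseline + 1L)
    if (!is.na(j)) t_box[i] <- times[j]
  }
  t_dis <- if (any(!is.na(t_box))) median(t_box, na.rm = TRUE) else NA_real_
  list(series = series, times = times, t_disappear_box = t_box,
       degenerate = degen, t_disappear = t_dis,
       co_timing_min = t_dis - t_arrest)
}
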