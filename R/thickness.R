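#' Cell thickness at one frame from the z intensity profile
#'
#' The per-z mean intensity over the ROI footprint is thresholded at a
#' fraction `f` of its own maximum (relative threshold: robust to the
#' cytoplasmic-dye brightness dip during expansion); the longest contiguous
#' above-threshold run `[z_lo, z_hi]` gives the thickness
#' `(z_hi - z_lo + 1) * z_step_um`. A partial-volume-refined thickness
#' (`thickness_pv_um`) additionally weights the run's boundary slices by
#' their relative intensity, recovering sub-slice extent.
#'
#' A frame with no contrast in the profile (`max < contrast_min * min`,
#' i.e. no slice stands out against the emptiest slice) is reported
#' absent; this requires the crop to retain at least one cell-free slice.
#'
#' @param stack an [image_stack()].
#' @param roi a [cell_roi()].
#' @param channel the cytoplasm channel (name or index).
#' @param t 1-based frame.
#' @param f relative threshold (default 0.5).
#' @param contrast_min absent-cell contrast guard (default 1.5).
#' @param foot optional precomputed footprint mask (internal reuse).
#' @return list `(thickness_um, thickness_pv_um, z_lo, z_hi, absent)`;
#'   slice indices are 1-based.
#' @export
cell_thickness <- function(stack, roi, channel, t, f = 0.5, contrast_min = 1.5,
                           foot = NULL) {
  d <- dim(stack$data)
  ch <- channel_index(stack, channel)
  foot <- foot %||% roi_mask(roi, d[4], d[5])
  if (!any(foot)) stop("ROI footprint is empty")
  if (!is.null(stack$validity)) foot <- foot & stack$validity[t, , ]
  m <- matrix(get_vol(stack, t, ch), d[3], d[4] * d[5])
  prof <- rowMeans(m[, c(foot), drop = FALSE])
  absent <- list(thickness_um = NA_real_, thickness_pv_um = NA_real_,
                 z_lo = NA_integer_, z_hi = NA_integer_, absent = TRUE)
  if (max(prof) <= 0) return(absent)
  if (max(prof) < contrast_min * max(min(prof), 1e-12)) return(absent)
  thr <- f * max(prof)
  above <- prof >= thr
  runs <- rle(above)
  if (!any(runs$values)) return(absent)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  z_lo <- starts[best]; z_hi <- ends[best]
  run_len <- z_hi - z_lo + 1L
  # partial-volume refinement: interior level and fractional edge slices
  core <- if (run_len > 2L) mean(prof[(z_lo + 1L):(z_hi - 1L)]) else max(prof)
  pv <- run_len
  if (run_len > 2L) {
    pv <- run_len - 2L + clamp(prof[z_lo] / core, 0, 1) + clamp(prof[z_hi] / core, 0, 1)
  }
  if (z_lo > 1L) pv <- pv + clamp(prof[z_lo - 1L] / core, 0, 1)
  if (z_hi < d[3]) pv <- pv + clamp(prof[z_hi + 1L] / core, 0, 1)
  list(thickness_um = run_len * stack$z_step_um,
       thickness_pv_um = pv * stack$z_step_um,
       z_lo = z_lo, z_hi = z_hi, absent = FALSE)
}

#' Thickness time series of a cell
#'
#' @inheritParams cell_thickness
#' @return a `thickness_series`: data frame `(time_min, thickness_um,
#'   thickness_pv_um, z_lo, z_hi, absent)` with attribute `z_step_um`.
#' @export
thickness_series <- function(stack, roi, channel, f = 0.5, contrast_min = 1.5) {
  times <- frame_times(stack)
  d <- dim(stack$data)
  foot <- roi_mask(roi, d[4], d[5])
  rows <- lapply(seq_along(times), function(t)
    cell_thickness(stack, roi, channel, t, f, contrast_min, foot = foot))
  out <- data.frame(
    time_min = times,
    thickness_um = vapply(rows, `[[`, 0, "thickness_um"),
    thickness_pv_um = vapply(rows, `[[`, 0, "thickness_pv_um"),
    z_lo = vapply(rows, `[[`, 0L, "z_lo"),
    z_hi = vapply(rows, `[[`, 0L, "z_hi"),
    absent = vapply(rows, `[[`, TRUE, "absent"))
  attr(out, "z_step_um") <- stack$z_step_um
  attr(out, "frame_interval_min") <- stack$frame_interval_min
  class(out) <- c("thickness_series", "data.frame")
  out
}

#' Stage onset, maximum expansion and flattening from a thickness series
#'
#' Raw rules: onset is the first frame with thickness at least
#' `onset_factor` times the pre-event baseline (median of pre-onset
#' frames), sustained `sustain` frames; maximum expansion is the argmax of
#' thickness between onset and the first subsequent return below baseline
#' (tie plateaus are averaged); flattening is the first frame after the
#' maximum with thickness at most `flatten_um` (default two z-steps — the
#' smallest band measurable at 0.6-um axial sampling, true corneocyte
#' thickness being below it), sustained `sustain` frames. Any stage whose
#' condition never holds is absent.
#'
#' With `refine = TRUE` (default) the onset and flattening times are
#' refined to sub-frame resolution by intersecting a local linear fit of
#' the partial-volume thickness with the baseline (onset) and with the
#' post-collapse floor (flattening); unrefined rule times are also
#' returned. Refinement removes the systematic lateness of a threshold
#' crossed only part-way up the expansion ramp.
#'
#' @param series a [thickness_series()].
#' @param onset_factor relative thickness marking onset (default 1.10).
#' @param sustain consecutive frames required (default 2).
#' @param flatten_um flattened-thickness criterion (default 2 z-steps).
#' @param refine sub-frame refinement (default `TRUE`).
#' @return list `(t_onset, t_max_expansion, t_flattened, baseline_um,
#'   t_onset_raw, t_flattened_raw)`, times in minutes, `NA` when absent.
#' @importFrom stats coef lm
#' @export
stage_morphology <- function(series, onset_factor = 1.10, sustain = 2L,
                             flatten_um = NULL, refine = TRUE) {
  if (nrow(series) < 10L) stop("need at least 10 frames to stage morphology")
  dz <- attr(series, "z_step_um")
  dt <- attr(series, "frame_interval_min") %||% diff(series$time_min[1:2])
  flatten_um <- flatten_um %||% (2 * dz)
  th <- series$thickness_pv_um
  th[series$absent] <- NA
  tt <- series$time_min
  out <- list(t_onset = NA_real_, t_max_expansion = NA_real_,
              t_flattened = NA_real_, baseline_um = NA_real_,
              t_onset_raw = NA_real_, t_flattened_raw = NA_real_)

  # baseline from pre-event frames, re-estimated once the crossing is known
  base <- median(th[seq_len(min(5L, nrow(series)))], na.rm = TRUE)
  for (pass in 1:2) {
    i_on <- first_sustained(th >= base * onset_factor, sustain)
    if (!is.na(i_on) && i_on > 3L) {
      base2 <- median(th[seq_len(i_on - 1L)], na.rm = TRUE)
      if (is.finite(base2)) base <- base2
    }
    if (is.na(i_on) || pass == 2) break
  }
  if (!is.finite(base) || base <= 0) return(out)
  out$baseline_um <- base
  if (is.na(i_on)) return(out)
  out$t_onset_raw <- tt[i_on]
  out$t_onset <- if (refine)
    refine_onset(tt, th, i_on, base, dz, dt) else tt[i_on]

  # maximum expansion: argmax between onset and first return below baseline
  after <- which(seq_along(th) > i_on & th < base)
  i_end <- if (length(after)) after[1] else length(th)
  win <- i_on:i_end
  pk <- max(th[win], na.rm = TRUE)
  plateau <- win[!is.na(th[win]) & th[win] >= pk - 0.4 * dz]
  # contiguous plateau around the argmax
  i_pk <- win[which.max(th[win])]
  plateau <- plateau[cumsum(c(1, diff(plateau)) != 1) ==
                     cumsum(c(1, diff(plateau)) != 1)[match(i_pk, plateau)]]
  out$t_max_expansion <- mean(tt[plateau])
  if (refine) {
    t_tent <- refine_peak(tt, th, i_on, i_pk, i_end, base, pk, dz, dt)
    if (!is.na(t_tent)) out$t_max_expansion <- t_tent
  }

  # flattening after the maximum
  i_flat <- first_sustained(series$thickness_um <= flatten_um, sustain,
                            start = i_pk + 1L)
  if (is.na(i_flat)) return(out)
  out$t_flattened_raw <- tt[i_flat]
  out$t_flattened <- if (refine)
    refine_flatten(tt, th, i_pk, i_flat, dz, dt) else tt[i_flat]
  out
}

# intersect a linear fit of the monotone rising ramp (frames walking back
# from the crossing while above baseline and increasing) with the baseline;
# clamped to at most 3 frames before the raw crossing
refine_onset <- function(tt, th, i_on, base, dz, dt) {
  w <- i_on
  # extend forward along the still-rising ramp: more points stabilise the
  # slope without touching the plateau
  k <- i_on + 1L
  while (k <= min(length(th), i_on + 2L) && !is.na(th[k]) && th[k] > th[k - 1L]) {
    w <- c(w, k); k <- k + 1L
  }
  j <- i_on - 1L
  # walk back only through clearly rising points; the margin keeps
  # baseline quantization noise out of the ramp fit
  margin <- 0.3 * dz
  while (j >= 1L && !is.na(th[j]) && th[j] > base + margin && th[j] < th[j + 1L]) {
    w <- c(j, w); j <- j - 1L
  }
  if (length(w) >= 2L) {
    fit <- lm(th[w] ~ tt[w])
    sl <- coef(fit)[2]
    if (is.finite(sl) && sl > 0) {
      t0 <- (base - coef(fit)[1]) / sl
      return(clamp(unname(t0), tt[i_on] - 3 * dt, tt[i_on]))
    }
  }
  # single straddling frame: interpolate the baseline crossing
  if (j >= 1L && !is.na(th[j]) && th[i_on] > th[j]) {
    fr <- (base - th[j]) / (th[i_on] - th[j])
    return(tt[j] + clamp(fr, 0, 1) * dt)
  }
  tt[i_on]
}

# peak of the expansion tent: intersection of lines fitted to the rising
# and falling flanks (the thickness track is piecewise-linear, so the
# discrete argmax is biased toward the shallower flank); NA to fall back
# to the plateau midpoint
refine_peak <- function(tt, th, i_on, i_pk, i_end, base, pk, dz, dt) {
  flank <- function(idx) {
    idx <- idx[!is.na(th[idx]) & th[idx] < pk - 0.3 * dz & th[idx] > base]
    if (length(idx) < 2L) return(NULL)
    stats::coef(lm(th[idx] ~ tt[idx]))
  }
  up <- flank(max(1L, i_on - 1L):(i_pk - 1L))
  dn <- flank((i_pk + 1L):min(i_end, i_pk + 4L))
  if (is.null(up) || is.null(dn)) return(NA_real_)
  s_up <- up[2]; s_dn <- dn[2]
  if (!is.finite(s_up) || !is.finite(s_dn) || s_up <= 0 || s_dn >= 0)
    return(NA_real_)
  t_x <- unname((dn[1] - up[1]) / (s_up - s_dn))
  if (abs(t_x - tt[i_pk]) > 1.5 * dt) return(NA_real_)
  t_x
}

# intersect the collapse ramp with the post-flattening floor
refine_flatten <- function(tt, th, i_pk, i_flat, dz, dt) {
  floor_lvl <- median(th[i_flat:min(length(th), i_flat + 4L)], na.rm = TRUE)
  ramp <- which(seq_along(th) >= i_pk & seq_along(th) <= i_flat &
                th > floor_lvl + 0.5 * dz)
  ramp <- utils::tail(ramp, 3L)
  ramp <- ramp[!is.na(th[ramp])]
  if (length(ramp) < 2L) {
    # single straddling frame: interpolate between it and the first flat frame
    if (i_flat > 1L && !is.na(th[i_flat - 1L]) && th[i_flat - 1L] > floor_lvl) {
      fr <- (th[i_flat - 1L] - floor_lvl) / max(th[i_flat - 1L] - th[i_flat], 1e-9)
      return(tt[i_flat - 1L] + clamp(fr, 0, 1) * dt)
    }
    return(tt[i_flat])
  }
  fit <- lm(th[ramp] ~ tt[ramp])
  sl <- coef(fit)[2]
  if (!is.finite(sl) || sl >= 0) return(tt[i_flat])
  t0 <- (floor_lvl - coef(fit)[1]) / sl
  clamp(unname(t0), tt[i_pk], tt[i_flat] + dt)
}
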