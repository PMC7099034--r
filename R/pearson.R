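#' Pearson correlation of two images over a mask
#'
#' The colocalization coefficient of two equally-shaped intensity arrays
#' restricted to a voxel mask:
#' `r = sum((a - mean(a)) (b - mean(b))) / sqrt(sum((a - mean(a))^2) sum((b - mean(b))^2))`.
#' Applied to consecutive frames of one channel it measures motion: moving
#' structures decorrelate neighbouring frames, arrested structures drive r
#' towards 1. Invariant under positive affine rescaling of either image.
#'
#' @param img_a,img_b numeric arrays of identical shape.
#' @param mask logical array of the same shape (default: all voxels).
#' @return Pearson coefficient in `[-1, 1]`.
#' @importFrom stats cor sd
#' @export
pearson_frame_pair <- function(img_a, img_b, mask = NULL) {
  if (!identical(dim(img_a) %||% length(img_a), dim(img_b) %||% length(img_b)))
    stop("images must have identical shape")
  a <- if (is.null(mask)) as.numeric(img_a) else as.numeric(img_a[mask])
  b <- if (is.null(mask)) as.numeric(img_b) else as.numeric(img_b[mask])
  if (length(a) < 2L) stop("need at least 2 masked voxels")
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined correlation: constant masked input")
  unname(cor(a, b))
}

#' Frame-pair correlation series within a cell ROI
#'
#' For each consecutive frame pair, the Pearson coefficient of the chosen
#' channel over the ROI voxels (polygon footprint x z-range), excluding
#' voxels invalidated by drift correction in either frame. Times are the
#' midpoints of each pair. Pairs whose masked voxels are constant yield
#' `NA` with a warning.
#'
#' @param stack a drift-corrected [image_stack()].
#' @param roi a [cell_roi()].
#' @param channel channel name or index (the vesicle channel).
#' @return a `correlation_series`: data frame `(time_min, r, n_voxels)`.
#' @export
correlation_series <- function(stack, roi, channel) {
  d <- dim(stack$data)
  ch <- channel_index(stack, channel)
  foot <- roi_mask(roi, d[4], d[5])
  if (!any(foot)) stop("ROI footprint is empty or outside the field")
  zr <- roi$z_range %||% c(1L, d[3])
  if (zr[1] < 1L || zr[2] > d[3]) stop("ROI z_range outside the stack")
  zsel <- zr[1]:zr[2]
  times <- frame_times(stack)
  n_pair <- d[1] - 1L
  r <- n_vox <- numeric(n_pair)
  n_zs <- length(zsel)
  mask3 <- aperm(array(foot, c(d[4], d[5], n_zs)), c(3, 1, 2))
  foot_idx <- which(mask3)
  # (y, x) linear index of every masked voxel, to intersect with validity
  yx_of <- ((foot_idx - 1L) %/% n_zs) + 1L
  for (k in seq_len(n_pair)) {
    idx <- foot_idx
    if (!is.null(stack$validity)) {
      v2 <- stack$validity[k, , ] & stack$validity[k + 1, , ]
      idx <- foot_idx[v2[yx_of]]
    }
    if (length(idx) < 2L) stop("empty pair mask at frame ", k)
    a <- get_vol(stack, k, ch)[zsel, , , drop = FALSE][idx]
    b <- get_vol(stack, k + 1, ch)[zsel, , , drop = FALSE][idx]
    n_vox[k] <- length(idx)
    r[k] <- tryCatch(pearson_frame_pair(a, b),
                     error = function(e) { warning(conditionMessage(e)); NA_real_ })
  }
  out <- data.frame(time_min = (times[-d[1]] + times[-1]) / 2,
                    r = r, n_voxels = n_vox)
  class(out) <- c("correlation_series", "data.frame")
  out
}

#' Call the vesicle-arrest time from a correlation series
#'
#' The r series is median-filtered (window 3) to suppress single-pair
#' spikes; the arrest is the first pair at which r reaches
#' `threshold_r` and stays there for `sustain_frames` consecutive pairs,
#' provided the median r of all preceding pairs is below the threshold
#' (a low-motion baseline must exist). Absence is a valid outcome.
#'
#' By default the reported time is refined to sub-pair resolution: for
#' diffusing Gaussian puncta the frame-pair correlation of a pair that
#' spends a fraction `f` of its gap moving is `r(f) ~ rp / (1 + f * beta)`
#' (the Gaussian overlap averaged over the chi-squared step length), with
#' `rp` the arrested plateau and `beta` fixed by the moving baseline
#' `rb = rp / (1 + beta)`; inverting this on the straddling pair's raw r
#' locates the freeze within the pair. `refine = FALSE` reports the raw
#' first-qualifying-pair midpoint (systematically late by up to one
#' frame, since a straddling pair can already qualify).
#'
#' @param series a [correlation_series()].
#' @param threshold_r correlation threshold (default 0.6).
#' @param sustain_frames consecutive pairs required at/above threshold
#'   (default 3, ~6 min at 2-min sampling).
#' @param refine report the transition-boundary time (default `TRUE`).
#' @return an `arrest_call`: list with `t_arrest` (min, `NA` if absent),
#'   `t_arrest_raw`, `baseline_r`, `plateau_r` and the parameters used.
#' @export
detect_arrest <- function(series, threshold_r = 0.6, sustain_frames = 3L,
                          refine = TRUE) {
  n <- nrow(series)
  if (n < sustain_frames + 2L)
    stop("series too short: need at least sustain_frames + 2 pairs")
  rs <- median_filter_1d(series$r, 3L)
  high <- rs >= threshold_r
  high[is.na(high)] <- FALSE
  call_idx <- NA_integer_
  j <- first_sustained(high, sustain_frames)
  while (!is.na(j)) {
    if (j > 1L && median(rs[seq_len(j - 1L)], na.rm = TRUE) < threshold_r) {
      call_idx <- j; break
    }
    # baseline proviso failed at this crossing: try the next qualifying run
    nxt <- which(!high & seq_len(n) > j)
    if (!length(nxt)) break
    j <- first_sustained(high, sustain_frames, start = nxt[1])
  }
  out <- list(t_arrest = NA_real_, t_arrest_raw = NA_real_,
              baseline_r = NA_real_, plateau_r = NA_real_,
              threshold_r = threshold_r, sustain_frames = sustain_frames,
              refine = refine)
  if (!is.na(call_idx)) {
    out$t_arrest_raw <- series$time_min[call_idx]
    dt_pair <- median(diff(series$time_min))
    out$baseline_r <- median(rs[seq_len(call_idx - 1L)], na.rm = TRUE)
    out$plateau_r <- median(rs[call_idx:n], na.rm = TRUE)
    out$t_arrest <- if (refine)
      refine_arrest(series$r, series$time_min, call_idx, n, dt_pair)
    else out$t_arrest_raw
  }
  class(out) <- "arrest_call"
  out
}

# locate the freeze at sub-pair resolution. Model: a pair spending the
# fraction f of its gap moving has r(f) = rp / (1 + f * beta) (Gaussian
# punctum overlap averaged over chi-squared step lengths), so
# 1/r = (1 + beta f) / rp is linear in f. The freeze time is fitted by
# weighted least squares of 1/r over the pairs bracketing the call
# (weights r^2, the delta-method variance of 1/r), with the plateau rp
# (f = 0) and moving baseline rb (f = 1) estimated from the raw series.
refine_arrest <- function(r, times, j, n, dt_pair) {
  start_j <- times[j] - dt_pair / 2
  rp <- median(r[min(j + 1L, n):min(j + 5L, n)], na.rm = TRUE)
  rb <- median(r[seq_len(max(j - 1L, 1L))], na.rm = TRUE)
  if (!is.finite(rp) || !is.finite(rb) || rb <= 0 || rp <= rb)
    return(start_j)
  beta <- rp / rb - 1
  # only the pairs bracketing the call: the moving baseline fluctuates
  # strongly from pair to pair (finite vesicle number), and farther
  # baseline pairs would masquerade as partial freezes
  w <- max(1L, j - 1L):min(n, j + 1L)
  w <- w[!is.na(r[w]) & r[w] > 0.02]
  if (length(w) < 2L) return(start_j)
  starts <- times[w] - dt_pair / 2
  inv_r <- 1 / r[w]
  wt <- r[w]^2
  cand <- seq(start_j - dt_pair, start_j + dt_pair, by = 0.01 * dt_pair)
  sse <- vapply(cand, function(t) {
    f <- clamp((t - starts) / dt_pair, 0, 1)
    sum(wt * (inv_r - (1 + beta * f) / rp)^2)
  }, 0)
  cand[which.min(sse)]
}

#' @export
print.arrest_call <- function(x, ...) {
  if (is.na(x$t_arrest)) cat("<arrest_call> absent\n")
  else cat(sprintf("<arrest_call> t = %.2f min (baseline r %.2f, plateau r %.2f)\n",
                   x$t_arrest, x$baseline_r, x$plateau_r))
  invisible(x)
}
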