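#' Estimate rigid xy drift against a reference frame
#'
#' Per-frame translation is estimated on the max-intensity z-projection of
#' one channel by phase correlation (Hann-windowed, whitened cross-power
#' spectrum, which gives a delta-like peak for rigid shifts) with
#' parabolic sub-pixel refinement of the peak (resolution ~0.1 px). The reported
#' shift `(dy, dx)` of frame k is the displacement of frame k relative to
#' the reference, i.e. `frame_k(y, x) ~ ref(y - dy, x - dx)`;
#' [apply_drift()] undoes it.
#'
#' @param stack an [image_stack()] with `T >= 2`.
#' @param channel channel used for registration (default `"cyto"` if named,
#'   else 1): the brightest, most persistent structure.
#' @param reference_frame 1-based reference frame index.
#' @param despike apply a Hampel filter (window 5, 3 MADs with a 0.3-px
#'   floor) followed by a running local-linear smoother (window 7) to the
#'   per-frame shifts (default `TRUE`). Drift is slow and smooth by
#'   assumption, while phase correlation on low-texture projections
#'   carries per-frame jitter and occasionally an isolated 1-2 px
#'   outlier; applied as corrections, both would themselves decorrelate
#'   neighbouring frames. The local-linear fit is exact on
#'   constant-velocity drift, including at the ends of the series.
#' @return a `drift_trace`: data frame `(frame, dy, dx)` with attribute
#'   `reference_frame`.
#' @importFrom stats fft mad
#' @export
estimate_drift <- function(stack, channel = NULL, reference_frame = 1L,
                           despike = TRUE) {
  d <- dim(stack$data)
  if (d[1] < 2L) stop("drift estimation needs at least 2 frames")
  channel <- channel %||% (if ("cyto" %in% stack$channel_names) "cyto" else 1L)
  ch <- channel_index(stack, channel)
  proj <- lapply(seq_len(d[1]), function(t)
    apply(get_vol(stack, t, ch), c(2, 3), max))
  ref <- proj[[reference_frame]]
  if (max(ref) - min(ref) <= 0)
    stop("degenerate input: reference frame is constant, no correlation peak")
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  win <- outer(hann(d[4]), hann(d[5]))
  Fr <- fft((ref - mean(ref)) * win)
  shifts <- t(vapply(seq_len(d[1]), function(t) {
    if (t == reference_frame) return(c(0, 0))
    fr <- proj[[t]]
    if (max(fr) - min(fr) <= 0)
      stop("degenerate input: frame ", t, " is constant, no correlation peak")
    cp <- Fr * Conj(fft((fr - mean(fr)) * win))
    cp <- cp / pmax(Mod(cp), 1e-12)
    cc <- Re(fft(cp, inverse = TRUE))
    peak_subpixel(cc)
  }, c(0, 0)))
  dy <- -shifts[, 1]; dx <- -shifts[, 2]
  if (despike && d[1] >= 5L) {
    dy <- run_line(hampel_filter(dy))
    dx <- run_line(hampel_filter(dx))
    dy <- dy - dy[reference_frame]
    dx <- dx - dx[reference_frame]
  }
  out <- data.frame(frame = seq_len(d[1]), dy = dy, dx = dx)
  attr(out, "reference_frame") <- reference_frame
  class(out) <- c("drift_trace", "data.frame")
  out
}

# running local-linear fit (Savitzky-Golay order 1 with truncated end
# windows): exact for constant-velocity sequences, averages down jitter
run_line <- function(x, window = 7L) {
  n <- length(x)
  half <- window %/% 2L
  t <- seq_len(n)
  out <- x
  for (i in seq_len(n)) {
    w <- max(1L, i - half):min(n, i + half)
    cf <- stats::coef(lm(x[w] ~ t[w]))
    out[i] <- cf[1] + cf[2] * i
  }
  out
}

# replace isolated outliers with the local running median
hampel_filter <- function(x, window = 5L, k = 3, floor = 0.3) {
  n <- length(x)
  half <- window %/% 2L
  out <- x
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half):min(n, i + half)]
    m <- median(w)
    thr <- max(k * mad(w, center = m), floor)
    if (abs(x[i] - m) > thr) out[i] <- m
  }
  out
}

# integer argmax of a circular cross-correlation surface + parabolic
# refinement; returns the (dy, dx) lag of the peak in (-n/2, n/2]
peak_subpixel <- function(cc) {
  d <- dim(cc)
  ij <- arrayInd(which.max(cc), d)
  wrap <- function(i, n) ((i - 1 + n / 2) %% n) - n / 2  # lag of 1-based index
  sub <- function(i, n, get) {
    cm <- get(((i - 2) %% n) + 1L); c0 <- get(i); cp <- get((i %% n) + 1L)
    den <- 2 * c0 - cm - cp
    if (den <= 0) 0 else clamp(0.5 * (cp - cm) / den, -0.5, 0.5)
  }
  dy <- wrap(ij[1], d[1]) + sub(ij[1], d[1], function(i) cc[i, ij[2]])
  dx <- wrap(ij[2], d[2]) + sub(ij[2], d[2], function(j) cc[ij[1], j])
  c(dy, dx)
}

#' Undo estimated drift
#'
#' Each frame is translated by its negated shift; voxels sampled from
#' outside the field are filled with 0 and flagged invalid in the stack's
#' validity mask so downstream statistics can exclude them. Calibration is
#' unchanged.
#'
#' @param stack an [image_stack()].
#' @param trace a `drift_trace` from [estimate_drift()] (length must equal T).
#' @param interpolation `"linear"` (bilinear) or `"nearest"`.
#' @export
apply_drift <- function(stack, trace, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(stack$data)
  if (nrow(trace) != d[1])
    stop("drift trace length (", nrow(trace), ") must equal T (", d[1], ")")
  out <- stack$data
  validity <- array(TRUE, d[c(1, 4, 5)])
  n_cz <- d[2] * d[3]
  for (t in seq_len(d[1])) {
    dy <- trace$dy[t]; dx <- trace$dx[t]
    if (dy == 0 && dx == 0) next
    sm <- sample_map(d[4], d[5], dy, dx, interpolation)
    # all (c, z) slices translated at once: rows = (c, z), cols = (y, x)
    m <- matrix(stack$data[t, , , , ], n_cz)
    out[t, , , , ] <- array(resample_planes(m, sm), d[2:5])
    validity[t, , ] <- sm$valid
  }
  st <- image_stack(out, stack$frame_interval_min, stack$z_step_um,
                    stack$xy_pixel_um, stack$channel_names, validity)
  st
}

# precompute the source-sampling plan for out(y,x) = src(y + dy, x + dx):
# linear column indices into the (y, x) plane plus per-pixel weights
sample_map <- function(n_y, n_x, dy, dx, interpolation) {
  ys <- (seq_len(n_y) - 1) + dy
  xs <- (seq_len(n_x) - 1) + dx
  lin <- function(iy, ix) c(outer(iy, (ix - 1) * n_y, "+"))
  if (interpolation == "nearest") {
    iy <- clamp(round(ys) + 1, 1, n_y); ix <- clamp(round(xs) + 1, 1, n_x)
    vy <- round(ys) >= 0 & round(ys) <= n_y - 1
    vx <- round(xs) >= 0 & round(xs) <= n_x - 1
    list(mode = "nearest", i00 = lin(iy, ix), valid = c(outer(vy, vx, "&")))
  } else {
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    iy0 <- clamp(y0 + 1, 1, n_y); iy1 <- clamp(y0 + 2, 1, n_y)
    ix0 <- clamp(x0 + 1, 1, n_x); ix1 <- clamp(x0 + 2, 1, n_x)
    vy <- ys >= 0 & ys <= n_y - 1
    vx <- xs >= 0 & xs <= n_x - 1
    list(mode = "linear",
         i00 = lin(iy0, ix0), i01 = lin(iy0, ix1),
         i10 = lin(iy1, ix0), i11 = lin(iy1, ix1),
         w00 = c(outer(1 - fy, 1 - fx)), w01 = c(outer(1 - fy, fx)),
         w10 = c(outer(fy, 1 - fx)), w11 = c(outer(fy, fx)),
         valid = c(outer(vy, vx, "&")))
  }
}

# m: rows = any number of planes, cols = (y, x) linear
resample_planes <- function(m, sm) {
  n <- nrow(m)
  out <- if (sm$mode == "nearest") {
    m[, sm$i00, drop = FALSE]
  } else {
    m[, sm$i00, drop = FALSE] * rep(sm$w00, each = n) +
      m[, sm$i01, drop = FALSE] * rep(sm$w01, each = n) +
      m[, sm$i10, drop = FALSE] * rep(sm$w10, each = n) +
      m[, sm$i11, drop = FALSE] * rep(sm$w11, each = n)
  }
  out[, !sm$valid] <- 0
  out
}

#' Write / read a drift trace as CSV (frame, dy, dx)
#' @param trace a `drift_trace`.
#' @param path CSV file.
#' @importFrom utils write.csv read.csv
#' @export
write_drift <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drift
#' @param reference_frame reference frame recorded with the trace.
#' @export
read_drift <- function(path, reference_frame = 1L) {
  out <- read.csv(path)
  attr(out, "reference_frame") <- reference_frame
  class(out) <- c("drift_trace", "data.frame")
  out
}

#' Denoise a stack slice-wise
#'
#' Applies a median or Gaussian filter to every `(t, c, z)` slice; shape
#' and calibration are unchanged.
#'
#' @param stack an [image_stack()].
#' @param method `"median"` or `"gaussian"`.
#' @param radius_px median radius (integer >= 1) or Gaussian sigma (> 0).
#' @export
denoise <- function(stack, method = c("median", "gaussian"), radius_px = 1) {
  method <- match.arg(method)
  d <- dim(stack$data)
  out <- stack$data
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    scale <- max(stack$data[t, ch, , , ], 1e-12)
    for (z in seq_len(d[3])) {
      sl <- stack$data[t, ch, z, , ] / scale
      fs <- if (method == "median") {
        if (radius_px < 1) stop("median radius must be >= 1")
        EBImage::medianFilter(sl, as.integer(radius_px))
      } else {
        if (radius_px <= 0) stop("gaussian sigma must be > 0")
        EBImage::gblur(sl, sigma = radius_px)
      }
      out[t, ch, z, , ] <- as.numeric(fs) * scale
    }
  }
  image_stack(out, stack$frame_interval_min, stack$z_step_um,
              stack$xy_pixel_um, stack$channel_names, stack$validity)
}
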