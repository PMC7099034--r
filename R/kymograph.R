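#' Kymograph along a line or a z-column
#'
#' For a line request, intensity is sampled bilinearly at 1-px spacing
#' along the segment on the maximum-intensity z-projection (or one z
#' slice) of the chosen channel, per frame, and stacked into a space x
#' time map. For a z-column request (an xy point), the per-z profile over
#' a 3x3 px neighbourhood is used, giving a z x time map — the direct
#' visual counterpart of a thickness series.
#'
#' @param stack an [image_stack()].
#' @param line either `list(p0 = c(x, y), p1 = c(x, y), z = "max" or slice)`
#'   for a line, or `list(x =, y =)` for a z-column (0-based pixel coords).
#' @param channel channel name or index.
#' @return a `kymograph`: list with `map` (space x time matrix), `times`,
#'   and the line definition.
#' @export
kymograph <- function(stack, line, channel) {
  d <- dim(stack$data)
  ch <- channel_index(stack, channel)
  times <- frame_times(stack)
  if (!is.null(line$p0)) {
    p0 <- line$p0; p1 <- line$p1
    len <- sqrt(sum((p1 - p0)^2))
    if (len <= 0) stop("degenerate line: zero length")
    n_s <- max(2L, ceiling(len) + 1L)
    ss <- seq(0, 1, length.out = n_s)
    xs <- p0[1] + ss * (p1[1] - p0[1])
    ys <- p0[2] + ss * (p1[2] - p0[2])
    if (any(xs < 0 | xs > d[5] - 1 | ys < 0 | ys > d[4] - 1))
      stop("line extends outside the field")
    map <- vapply(seq_len(d[1]), function(t) {
      vol <- get_vol(stack, t, ch)
      img <- if (identical(line$z %||% "max", "max"))
        apply(vol, c(2, 3), max)
      else matrix(vol[line$z, , ], d[4], d[5])
      bilinear_sample(img, ys, xs)
    }, numeric(n_s))
  } else {
    x <- line$x; y <- line$y
    if (is.null(x) || is.null(y)) stop("line must give p0/p1 or x/y")
    yr <- clamp(round(y) + (-1:1) + 1L, 1L, d[4])
    xr <- clamp(round(x) + (-1:1) + 1L, 1L, d[5])
    map <- vapply(seq_len(d[1]), function(t) {
      vol <- get_vol(stack, t, ch)
      apply(vol[, yr, xr, drop = FALSE], 1, mean)
    }, numeric(d[3]))
  }
  structure(list(map = map, times = times, line = line, channel = ch),
            class = "kymograph")
}

bilinear_sample <- function(img, ys, xs) {
  n_y <- nrow(img); n_x <- ncol(img)
  y0 <- clamp(floor(ys), 0, n_y - 2); x0 <- clamp(floor(xs), 0, n_x - 2)
  fy <- ys - y0; fx <- xs - x0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d x %d (space x time)\n", nrow(x$map), ncol(x$map)))
  invisible(x)
}

#' Export a kymograph as CSV (rows = space, columns = frames)
#' @param kymo a [kymograph()].
#' @param path CSV file.
#' @export
write_kymograph <- function(kymo, path) {
  df <- as.data.frame(kymo$map)
  names(df) <- sprintf("t%g", kymo$times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
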