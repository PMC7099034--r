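#' Cell region of interest
#'
#' A simple (non-self-intersecting) xy polygon in 0-based pixel
#' coordinates, with optional inclusive z-slice and frame ranges.
#'
#' @param cell_id identifier.
#' @param polygon numeric matrix with columns `x`, `y` (0-based pixels),
#'   vertices in order, not closed.
#' @param z_range optional inclusive 1-based slice index range `c(z_lo, z_hi)`.
#' @param t_range optional inclusive 1-based frame range.
#' @return object of class `cell_roi`.
#' @export
cell_roi <- function(cell_id, polygon, z_range = NULL, t_range = NULL) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("polygon must be an n x 2 matrix (x, y) with n >= 3")
  colnames(polygon) <- c("x", "y")
  a <- polygon_area(polygon)
  if (a <= 0) stop("polygon must have positive area")
  if (!polygon_is_simple(polygon)) stop("polygon must be simple (non-self-intersecting)")
  if (!is.null(z_range)) {
    if (length(z_range) != 2L || z_range[1] > z_range[2])
      stop("z_range must be c(z_lo, z_hi) with z_lo <= z_hi")
  }
  structure(list(cell_id = cell_id, polygon = polygon,
                 z_range = z_range, t_range = t_range),
            class = "cell_roi")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# O(n^2) segment-intersection check; fine for hand-drawn outlines
polygon_is_simple <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  inter <- function(a, b) {
    d1 <- cross(b[3:4] - b[1:2], a[1:2] - b[1:2])
    d2 <- cross(b[3:4] - b[1:2], a[3:4] - b[1:2])
    d3 <- cross(a[3:4] - a[1:2], b[1:2] - a[1:2])
    d4 <- cross(a[3:4] - a[1:2], b[3:4] - a[1:2])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  cross <- function(u, v) u[1] * v[2] - u[2] * v[1]
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize an ROI footprint to a logical (Y, X) mask
#'
#' Pixel centers are at integer 0-based coordinates.
#'
#' @param roi a [cell_roi()].
#' @param n_y,n_x field size in pixels.
#' @export
roi_mask <- function(roi, n_y, n_x) {
  px <- rep(0:(n_x - 1), each = n_y)
  py <- rep(0:(n_y - 1), times = n_x)
  vx <- roi$polygon[, 1]; vy <- roi$polygon[, 2]
  n <- length(vx)
  jx <- c(vx[n], vx[-n]); jy <- c(vy[n], vy[-n])
  crossings <- integer(length(px))
  for (e in seq_len(n)) {  # even-odd ray casting, vectorized over pixels
    x1 <- vx[e]; y1 <- vy[e]; x2 <- jx[e]; y2 <- jy[e]
    if (y1 == y2) next
    hit <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    crossings <- crossings + hit
  }
  matrix(crossings %% 2L == 1L, n_y, n_x)
}

#' Write / read ROIs as JSON (cell_id to polygon vertices, 0-based pixels)
#' @param rois list of [cell_roi()].
#' @param path JSON file.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r) list(
    cell_id = r$cell_id,
    polygon = unname(apply(r$polygon, 1, function(v) c(v[1], v[2]), simplify = FALSE)),
    z_range = r$z_range, t_range = r$t_range))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, unlist))
    cell_roi(r$cell_id, poly,
             z_range = if (length(r$z_range)) unlist(r$z_range) else NULL,
             t_range = if (length(r$t_range)) unlist(r$t_range) else NULL)
  })
}

#' @export
print.cell_roi <- function(x, ...) {
  cat(sprintf("<cell_roi> %s: %d vertices, area %.1f px^2\n",
              format(x$cell_id), nrow(x$polygon), polygon_area(x$polygon)))
  invisible(x)
}
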