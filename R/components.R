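#' Label connected components in a 3D binary mask
#'
#' 26-connected (face, edge and corner neighbours) component labelling of a
#' `(Z, Y, X)` logical array, built on a voxel-adjacency graph.
#'
#' @param mask logical `(Z, Y, X)` array.
#' @param connectivity 26 (default) or 6 (faces only).
#' @return list with `labels` (integer array, 0 = background), `n`
#'   (component count) and `voxels` (list of `n x 3` index matrices,
#'   1-based `(z, y, x)` rows, one per component).
#' @export
label_components_3d <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3D (Z, Y, X) array")
  fg <- which(mask)
  labels <- array(0L, d)
  if (!length(fg)) return(list(labels = labels, n = 0L, voxels = list()))
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  ind <- arrayInd(fg, d)
  id_of <- integer(prod(d))
  id_of[fg] <- seq_along(fg)
  edges <- NULL
  for (o in seq_len(nrow(offs))) {
    nz <- ind[, 1] + offs$dz[o]; ny <- ind[, 2] + offs$dy[o]; nx <- ind[, 3] + offs$dx[o]
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    nl <- (nx[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nz[ok]
    nb <- id_of[nl]
    src <- which(ok)[nb > 0]
    if (length(src)) edges <- rbind(edges, cbind(src, nb[nb > 0]))
  }
  if (is.null(edges)) {
    comp <- seq_along(fg)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  labels[fg] <- as.integer(comp)
  n <- max(comp)
  voxels <- lapply(seq_len(n), function(k) ind[comp == k, , drop = FALSE])
  list(labels = labels, n = n, voxels = voxels)
}

# Otsu threshold of a numeric vector (histogram-based, 256 levels)
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  xm <- matrix((x - rng[1]) / diff(rng), nrow = 1L)
  thr <- EBImage::otsu(xm, range = c(0, 1), levels = levels)
  rng[1] + thr * diff(rng)
}
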