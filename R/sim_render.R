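#' Render a phantom into a noisy calibrated image stack
#'
#' Voxelizes the scene into a 4-channel `(nucleus, cyto, vesicle, mito)`
#' stack. Cytoplasm uses exact per-slice z-coverage (partial-volume edges),
#' the nucleus is a soft ellipsoid, vesicles and mitochondrial primitives
#' are Gaussian stamps, and the leakage halo is an annulus outside the
#' nuclear footprint. Global xy drift accumulates at the configured
#' px/frame and is applied to all object coordinates (sub-pixel). Noise is
#' Poisson shot noise at `poisson_scale` plus Gaussian read noise, clipped
#' at zero.
#'
#' @param phantom a [build_phantom()] result.
#' @param config the same [sim_config()] used to build the phantom.
#' @param channels which of `"nucleus"`, `"cyto"`, `"vesicle"`, `"mito"`
#'   to render (all four by default); analyses that need only a subset can
#'   skip the rest.
#' @return list with `stack` (an [image_stack()]), `truth` (the unmodified
#'   timelines) and `rois` (one [cell_roi()] per cell).
#' @importFrom stats rpois rnorm
#' @export
render_stack <- function(phantom, config = phantom$config,
                         channels = c("nucleus", "cyto", "vesicle", "mito")) {
  stopifnot(inherits(phantom, "phantom"))
  channels <- match.arg(channels, several.ok = TRUE)
  iN <- match("nucleus", channels); iC <- match("cyto", channels)
  iV <- match("vesicle", channels); iM <- match("mito", channels)
  n_ch <- length(channels)
  sh <- config$stack_shape
  n_t <- sh[1]; n_z <- sh[2]; n_y <- sh[3]; n_x <- sh[4]
  total <- prod(c(sh[1], n_ch, sh[2:4]))
  if (total > config$max_voxels)
    stop(sprintf("stack too large: %d voxels required, %d allowed (max_voxels)",
                 total, config$max_voxels))
  dz <- config$z_step_um
  xs <- seq_len(n_x) - 1; ys <- seq_len(n_y) - 1
  z_centers <- (seq_len(n_z) - 0.5) * dz
  z_edges_lo <- (seq_len(n_z) - 1) * dz
  gsd <- config$noise[[1]]; ps <- config$noise[[2]]
  bg <- config$amplitudes[["background"]]

  data <- array(0, c(n_t, n_ch, n_z, n_y, n_x))
  for (k in seq_len(n_t)) {
    vol <- array(0, c(n_ch, n_z, n_y, n_x))
    dyk <- phantom$drift[k, "dy"]; dxk <- phantom$drift[k, "dx"]
    for (cell in phantom$cells) {
      cy <- cell$center[["y"]] + dyk; cx <- cell$center[["x"]] + dxk
      DX <- matrix(xs - cx, n_y, n_x, byrow = TRUE)
      DY <- matrix(ys - cy, n_y, n_x)
      ct <- cos(cell$theta); st <- sin(cell$theta)
      xr <- ct * DX + st * DY; yr <- -st * DX + ct * DY
      nr2 <- (xr / cell$rx)^2 + (yr / cell$ry)^2
      foot <- as.numeric(nr2 <= 1)

      # cytoplasm: footprint x exact z-coverage of [z_lo, z_hi]
      if (!is.na(iC)) {
        z_hi <- cell$z_lo_um + cell$thickness_um[k]
        cov <- clamp((pmin(z_hi, z_edges_lo + dz) -
                      pmax(cell$z_lo_um, z_edges_lo)) / dz, 0, 1)
        vol[iC, , , ] <- vol[iC, , , ] +
          array(outer(cov, cell$cyto_amp[k] * foot), c(n_z, n_y, n_x))
      }

      # nucleus: soft ellipsoid centred mid-cell
      if (!is.na(iN)) {
        zc <- cell$z_lo_um + cell$thickness_um[k] / 2
        rz <- max(0.35 * cell$thickness_um[k], 0.5)
        az <- ((z_centers - zc) / rz)^2
        nxy <- (xr / (0.55 * cell$rx))^2 + (yr / (0.55 * cell$ry))^2
        blob <- pmax(0, 1 - outer(az, c(nxy), "+"))
        vol[iN, , , ] <- vol[iN, , , ] +
          array(cell$nuc_amp[k] * blob, c(n_z, n_y, n_x))

        # DNA-leakage halo: dye spreading radially from the nuclear boundary
        if (cell$halo_amp[k] > 0) {
          ring <- as.numeric(nxy > 0.8 & nxy < 2.5^2) * foot
          zw <- pmax(0, 1 - az)
          vol[iN, , , ] <- vol[iN, , , ] +
            array(cell$halo_amp[k] * outer(zw, ring), c(n_z, n_y, n_x))
        }
      }

      # vesicles
      if (!is.na(iV) && cell$ves_amp[k] > 0.5) {
        vv <- cell$vesicles
        for (v in seq_len(nrow(vv))) {
          vol[iV, , , ] <- stamp_gauss(
            vol[iV, , , ], n_z, n_y, n_x,
            z_px = vv[v, k, "z_um"] / dz - 0.5,
            y_px = cy + vv[v, k, "y"], x_px = cx + vv[v, k, "x"],
            sz = 0.5 / dz * 0.6, sy = 1.2, sx = 1.2, amp = cell$ves_amp[k])
        }
      }

      # mitochondria (off from onset)
      if (!is.na(iM) && cell$mito_on[k]) {
        amp_m <- config$amplitudes[["mito"]]
        for (pr in cell$mito) {
          s_xy <- pr$radius_um / config$xy_pixel_um
          s_z <- pr$radius_um / dz
          if (pr$type == "sphere") {
            vol[iM, , , ] <- stamp_gauss(vol[iM, , , ], n_z, n_y, n_x,
              pr$center[["z_um"]] / dz - 0.5,
              cy + pr$center[["y"]], cx + pr$center[["x"]],
              s_z, s_xy, s_xy, amp_m)
          } else {
            n_pts <- max(2L, ceiling(pr$length_um / 0.3))
            ss <- seq(-pr$length_um / 2, pr$length_um / 2, length.out = n_pts)
            for (s in ss) {
              vol[iM, , , ] <- stamp_gauss(vol[iM, , , ], n_z, n_y, n_x,
                (pr$center[["z_um"]] + s * pr$dir[1]) / dz - 0.5,
                cy + pr$center[["y"]] + s * pr$dir[2] / config$xy_pixel_um,
                cx + pr$center[["x"]] + s * pr$dir[3] / config$xy_pixel_um,
                s_z, s_xy, s_xy, amp_m * 0.7)
            }
          }
        }
      }
    }

    v <- c(vol) + bg
    if (ps > 0) v <- rpois(length(v), v * ps) / ps
    if (gsd > 0) v <- v + rnorm(length(v), 0, gsd)
    data[k, , , , ] <- pmax(v, 0)
  }

  stack <- image_stack(data, config$frame_interval_min, config$z_step_um,
                       config$xy_pixel_um, channels)
  rois <- lapply(phantom$cells, function(cell)
    cell_roi(cell$cell_id, cell$polygon))
  list(stack = stack, truth = phantom$timelines, rois = rois)
}

# add a separable 3D gaussian of amplitude amp at (z_px, y_px, x_px);
# coordinates 0-based, array (Z, Y, X) 1-based
stamp_gauss <- function(vol, n_z, n_y, n_x, z_px, y_px, x_px, sz, sy, sx, amp) {
  ez <- ceiling(2 * sz); ey <- ceiling(2 * sy); ex <- ceiling(2 * sx)
  zr <- max(1L, floor(z_px - ez) + 1L):min(n_z, ceiling(z_px + ez) + 1L)
  yr <- max(1L, floor(y_px - ey) + 1L):min(n_y, ceiling(y_px + ey) + 1L)
  xr <- max(1L, floor(x_px - ex) + 1L):min(n_x, ceiling(x_px + ex) + 1L)
  if (!length(zr) || !length(yr) || !length(xr)) return(vol)
  gz <- exp(-((zr - 1 - z_px)^2) / (2 * sz^2))
  gy <- exp(-((yr - 1 - y_px)^2) / (2 * sy^2))
  gx <- exp(-((xr - 1 - x_px)^2) / (2 * sx^2))
  vol[zr, yr, xr] <- vol[zr, yr, xr] +
    amp * array(outer(gz, c(outer(gy, gx))), c(length(zr), length(yr), length(xr)))
  vol
}

#' Simulate a cohort of single-cell crops with ground truth
#'
#' Convenience wrapper: draws `n` timelines, builds and renders one
#' single-cell field per timeline, and returns stacks, ROIs and truth. All
#' randomness flows from one RNG stream seeded once with `seed`.
#'
#' @param config a [sim_config()] (its `n_cells` is forced to 1 per crop).
#' @param n number of cells.
#' @param seed integer seed (defaults to `config$seed`).
#' @param force_cornify generate only cornifying cells (see
#'   [sample_timeline()]).
#' @param keep_stacks if `FALSE`, stacks are dropped after the caller's
#'   `per_cell` function has seen them (memory-friendly for large cohorts).
#' @param per_cell optional `function(stack, roi, truth)` applied to each
#'   rendered cell; its results are collected in `$results`.
#' @param channels channels to render (see [render_stack()]).
#' @return list with `truth` (list of timelines), `results` (if `per_cell`
#'   given), and `cells` (list of `list(stack, roi)` if `keep_stacks`).
#' @export
simulate_cohort <- function(config, n, seed = config$seed,
                            force_cornify = FALSE, keep_stacks = TRUE,
                            per_cell = NULL,
                            channels = c("nucleus", "cyto", "vesicle", "mito")) {
  set.seed(seed)
  cfg1 <- config
  cfg1$n_cells <- 1L
  truth <- vector("list", n)
  results <- if (!is.null(per_cell)) vector("list", n) else NULL
  cells <- if (keep_stacks) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tl <- sample_timeline(cfg1, i, force_cornify)
    ph <- build_phantom(cfg1, list(tl))
    r <- render_stack(ph, cfg1, channels = channels)
    truth[[i]] <- tl
    if (!is.null(per_cell)) results[[i]] <- per_cell(r$stack, r$rois[[1]], tl)
    if (keep_stacks) cells[[i]] <- list(stack = r$stack, roi = r$rois[[1]])
  }
  list(truth = truth, results = results, cells = cells, config = cfg1)
}
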