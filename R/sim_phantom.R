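#' Build a renderable scene from ground-truth timelines
#'
#' Turns per-cell event timelines into explicit geometry and brightness
#' scripts: an elliptical cell footprint, a z-extent track (baseline, then a
#' linear expansion to `expansion_factor` times baseline between onset and
#' maximum expansion, then a linear collapse to the flattened thickness), a
#' nuclear ellipsoid riding mid-cell, acidic-vesicle random walks frozen at
#' arrest, mitochondrial primitives per morphology group switched off at
#' onset (potential-dye behaviour), a perinuclear halo from DNA leakage
#' onward, and post-flattening brightness scripts (cytoplasm dip then rise,
#' vesicle and nuclear fade).
#'
#' @param config a [sim_config()].
#' @param timelines list of [sample_timeline()] results, one per cell.
#' @param strict if `TRUE`, a timeline whose flattening falls outside the
#'   simulated duration is an error; the default warns and renders the
#'   events that fit (right-censoring, as in a real acquisition).
#' @return object of class `phantom`.
#' @importFrom stats rnorm rbinom
#' @export
build_phantom <- function(config, timelines, strict = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (length(timelines) != config$n_cells)
    stop("need exactly one timeline per cell (n_cells = ", config$n_cells, ")")
  sh <- config$stack_shape
  n_t <- sh[1]; n_z <- sh[2]; n_y <- sh[3]; n_x <- sh[4]
  dt <- config$frame_interval_min
  duration <- (n_t - 1) * dt
  times <- (seq_len(n_t) - 1) * dt
  dz <- config$z_step_um

  over <- vapply(timelines, function(tl)
    !is.na(tl$t_flattened) && tl$t_flattened > duration, TRUE)
  if (any(over)) {
    msg <- sprintf("%d timeline(s) extend beyond the simulated duration (%g min)",
                   sum(over), duration)
    if (strict) stop(msg) else warning(msg, "; events are right-censored")
  }

  # cell centers: single cell centered, several cells on a jittered grid
  n_cells <- config$n_cells
  grid_n <- ceiling(sqrt(n_cells))
  centers <- cbind(
    y = (rep(seq_len(grid_n), each = grid_n)[seq_len(n_cells)] - 0.5) / grid_n * n_y,
    x = (rep(seq_len(grid_n), times = grid_n)[seq_len(n_cells)] - 0.5) / grid_n * n_x)
  if (n_cells > 1)
    centers <- centers + matrix(rnorm(2 * n_cells, 0, 1), ncol = 2)

  r_px <- config$cell_radius_um / config$xy_pixel_um
  z_lo <- 2 * dz  # resting base of the cell above the crop floor
  h0 <- config$baseline_thickness_um
  ef <- config$expansion_factor
  h_flat <- config$flattened_thickness_um

  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    tl <- timelines[[i]]
    ry <- r_px * runif(1, 0.9, 1.05)
    rx <- r_px * runif(1, 0.9, 1.05)
    theta <- runif(1, 0, pi)

    thick <- rep(h0, n_t)
    if (!is.na(tl$t_onset)) {
      up <- times >= tl$t_onset & times < tl$t_max_expansion
      thick[up] <- h0 * (1 + (ef - 1) *
        (times[up] - tl$t_onset) / (tl$t_max_expansion - tl$t_onset))
      dn <- times >= tl$t_max_expansion & times < tl$t_flattened
      thick[dn] <- ef * h0 + (h_flat - ef * h0) *
        (times[dn] - tl$t_max_expansion) / (tl$t_flattened - tl$t_max_expansion)
      thick[times >= tl$t_flattened] <- h_flat
    }

    amp <- config$amplitudes
    cyto_amp <- rep(amp[["cyto"]], n_t)
    nuc_amp <- rep(amp[["nucleus"]], n_t)
    ves_amp <- rep(amp[["vesicle"]], n_t)
    halo_amp <- rep(0, n_t)
    mito_on <- rep(TRUE, n_t)
    if (!is.na(tl$t_onset)) {
      mid <- times >= tl$t_onset & times < tl$t_flattened
      cyto_amp[mid] <- amp[["cyto"]] * 0.75        # CTG dip during the change
      post <- times >= tl$t_flattened
      cyto_amp[post] <- amp[["cyto"]] * 1.2        # CTG rise after flattening
      nuc_amp[post] <- amp[["nucleus"]] *
        pmax(0.3, exp(-(times[post] - tl$t_flattened) / 30))
      ves_amp[post] <- amp[["vesicle"]] *
        exp(-(times[post] - tl$t_flattened) / 12)
      mito_on <- times < tl$t_onset                # abrupt depolarization
    }
    if (!is.na(tl$t_leakage))
      halo_amp[times >= tl$t_leakage] <- amp[["halo"]]

    ves <- simulate_vesicles(config, tl, times, ry, rx, theta,
                             z_lo, thick)
    mito <- sample_mito_primitives(tl$group, config, ry, rx, theta,
                                   z_lo, h0)

    ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
    poly <- cbind(
      x = centers[i, "x"] + 1.12 * (rx * cos(ang) * cos(theta) - ry * sin(ang) * sin(theta)),
      y = centers[i, "y"] + 1.12 * (rx * cos(ang) * sin(theta) + ry * sin(ang) * cos(theta)))

    cells[[i]] <- list(
      cell_id = tl$cell_id, center = centers[i, ], ry = ry, rx = rx,
      theta = theta, polygon = poly, z_lo_um = z_lo, thickness_um = thick,
      cyto_amp = cyto_amp, nuc_amp = nuc_amp, ves_amp = ves_amp,
      halo_amp = halo_amp, mito_on = mito_on,
      vesicles = ves, mito = mito)
  }

  structure(list(config = config, timelines = timelines, cells = cells,
                 times = times,
                 drift = cbind(dy = (times / dt) * config$drift_per_frame_px[[1]],
                               dx = (times / dt) * config$drift_per_frame_px[[2]])),
            class = "phantom")
}

# vesicle random walks in cell-local coordinates; frozen from t_arrest on.
# A pair of frames straddling the arrest gets the diffusion-scaled partial
# step sqrt(f), f = fraction of the inter-frame gap spent moving.
simulate_vesicles <- function(config, tl, times, ry, rx, theta, z_lo, thick) {
  n_v <- config$n_vesicles
  n_t <- length(times)
  dt <- config$frame_interval_min
  pos <- array(NA_real_, c(n_v, n_t, 3L),
               dimnames = list(NULL, NULL, c("z_um", "y", "x")))
  rr <- 0.8 * sqrt(runif(n_v)); aa <- runif(n_v, 0, 2 * pi)
  ey <- rr * sin(aa) * ry; ex <- rr * cos(aa) * rx
  pos[, 1, "y"] <- ex * sin(theta) + ey * cos(theta)
  pos[, 1, "x"] <- ex * cos(theta) - ey * sin(theta)
  pos[, 1, "z_um"] <- z_lo + runif(n_v, 0.3, max(thick[1] - 0.3, 0.4))
  step <- config$vesicle_step_px
  if (n_t < 2L) return(pos)
  for (k in 2:n_t) {
    f <- if (is.na(tl$t_arrest)) 1 else
      clamp((tl$t_arrest - times[k - 1]) / dt, 0, 1)
    if (f == 0) { pos[, k, ] <- pos[, k - 1, ]; next }
    s <- step * sqrt(f)
    ny <- pos[, k - 1, "y"] + rnorm(n_v, 0, s)
    nx <- pos[, k - 1, "x"] + rnorm(n_v, 0, s)
    nz <- pos[, k - 1, "z_um"] + rnorm(n_v, 0, 0.25 * sqrt(f))
    # reflect back inside the footprint (normalized radius 0.85)
    xr <- nx * cos(theta) + ny * sin(theta)
    yr <- -nx * sin(theta) + ny * cos(theta)
    nr <- sqrt((xr / rx)^2 + (yr / ry)^2)
    shrink <- ifelse(nr > 0.85, 0.85 / nr, 1)
    pos[, k, "y"] <- ny * shrink
    pos[, k, "x"] <- nx * shrink
    pos[, k, "z_um"] <- clamp(nz, z_lo + 0.3, z_lo + max(thick[k] - 0.3, 0.4))
  }
  pos
}

# mitochondrial primitives by morphology group:
# 1 few spheres; 2 few spheres + clearly elongated rods; 3 moderate short
# rods; 4 many long rods. Primitive centers keep a minimum separation so
# that puncta do not fuse into pseudo-elongated components.
sample_mito_primitives <- function(group, config, ry, rx, theta, z_lo, h0) {
  placed <- NULL
  px <- config$xy_pixel_um
  place <- function() {
    for (try in 1:25) {
      rr <- 0.7 * sqrt(runif(1)); aa <- runif(1, 0, 2 * pi)
      ey <- rr * sin(aa) * ry; ex <- rr * cos(aa) * rx
      p <- c(z_um = z_lo + runif(1, 0.8, h0 - 0.8),
             y = ex * sin(theta) + ey * cos(theta),
             x = ex * cos(theta) - ey * sin(theta))
      if (is.null(placed)) break
      d2 <- (placed[, 1] - p[1])^2 + ((placed[, 2] - p[2]) * px)^2 +
        ((placed[, 3] - p[3]) * px)^2
      if (min(d2) > 1.4^2) break
    }
    placed <<- rbind(placed, p)
    p
  }
  mk <- function(type, n, len_mu, len_sd, radius) {
    if (n <= 0) return(list())
    lapply(seq_len(n), function(j) {
      az <- runif(1, 0, 2 * pi); dz <- runif(1, -0.2, 0.2)
      d <- c(dz, sin(az), cos(az)); d <- d / sqrt(sum(d^2))
      list(type = type, center = place(), dir = d,
           length_um = if (type == "rod") max(0.8, rnorm(1, len_mu, len_sd)) else 0,
           radius_um = radius)
    })
  }
  switch(group,
    c(mk("sphere", 3L + rbinom(1, 3, 0.5), 0, 0, 0.45)),
    c(mk("sphere", 2L + rbinom(1, 2, 0.5), 0, 0, 0.45),
      mk("rod", 1L + rbinom(1, 1, 0.5), 3.5, 0.3, 0.27)),
    c(mk("rod", 10L + sample(-2:2, 1), 2.1, 0.2, 0.33)),
    c(mk("rod", 21L + sample(-3:3, 1), 4.0, 0.5, 0.35)))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d cell(s), %d frames, %s\n", length(x$cells),
              length(x$times), x$config$condition))
  invisible(x)
}
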