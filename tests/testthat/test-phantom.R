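test_that("event-free cells keep constant geometry and mobile vesicles", {
  cfg <- tiny_config(flatten_prob_by_group = rep(0, 4))
  set.seed(2)
  tl <- sample_timeline(cfg, 1L)
  ph <- build_phantom(cfg, list(tl))
  cell <- ph$cells[[1]]
  expect_true(all(cell$thickness_um == cfg$baseline_thickness_um))
  disp <- abs(diff(t(cell$vesicles[, , "y"])))
  expect_gt(mean(disp > 0), 0.99)
})

test_that("vesicles are frozen exactly from the arrest frame on", {
  cfg <- tiny_config()
  set.seed(3)
  tl <- scripted_timeline(arrest = 20, onset = 24, max_exp = 32, flat = 40,
                          leak = NA)  # arrest exactly at frame 11 (t = 20)
  ph <- build_phantom(cfg, list(tl))
  v <- ph$cells[[1]]$vesicles
  frames_after <- which(ph$times >= 20)
  for (k in frames_after[-1]) {
    expect_identical(v[, k, ], v[, k - 1, ])
  }
  pre <- which(ph$times < 18)
  expect_gt(max(abs(v[, pre[2], "y"] - v[, pre[1], "y"])), 0)
})

test_that("group 4 cells carry more, longer mitochondria than group 1", {
  cfg <- tiny_config()
  set.seed(4)
  prim_vol <- function(p) {
    if (p$type == "sphere") 4 / 3 * pi * p$radius_um^3
    else pi * p$radius_um^2 * p$length_um
  }
  prim_elong <- function(p) {
    if (p$type == "sphere") 1 else p$length_um / (2 * p$radius_um)
  }
  m1 <- cornitrack:::sample_mito_primitives(1L, cfg, 16, 16, 0, 1.2, 6)
  m4 <- cornitrack:::sample_mito_primitives(4L, cfg, 16, 16, 0, 1.2, 6)
  expect_gt(sum(vapply(m4, prim_vol, 0)), sum(vapply(m1, prim_vol, 0)))
  expect_gt(max(vapply(m4, prim_elong, 0)), max(vapply(m1, prim_elong, 0)))
})

test_that("rendering is deterministic given the seed", {
  cfg <- tiny_config()
  render_once <- function() {
    set.seed(21)
    tl <- sample_timeline(cfg, 1L, force_cornify = TRUE)
    ph <- build_phantom(cfg, list(tl))
    render_stack(ph, cfg, channels = c("cyto", "vesicle"))$stack$data
  }
  expect_identical(render_once(), render_once())
})

test_that("injected drift shows up as the cross-correlation lag", {
  cfg <- tiny_config(drift_per_frame_px = c(dy = 1, dx = 0),
                     noise = c(gaussian_sd = 0, poisson_scale = 0),
                     flatten_prob_by_group = rep(0, 4))
  set.seed(6)
  tl <- sample_timeline(cfg, 1L)
  ph <- build_phantom(cfg, list(tl))
  st <- render_stack(ph, cfg, channels = "cyto")$stack
  proj0 <- apply(st$data[1, 1, , , ], c(2, 3), max)
  # brute-force integer-lag correlation oracle
  best <- c(NA, NA); best_v <- -Inf
  for (k in c(4L, 7L)) {
    projk <- apply(st$data[k, 1, , , ], c(2, 3), max)
    for (dy in -8:8) for (dx in -3:3) {
      ys <- (1 + max(0, dy)):(nrow(proj0) + min(0, dy))
      xs <- (1 + max(0, dx)):(ncol(proj0) + min(0, dx))
      a <- proj0[ys - dy, xs - dx]; b <- projk[ys, xs]
      v <- sum(a * b)
      if (v > best_v) { best_v <- v; best <- c(dy, dx) }
    }
    expect_equal(best, c(k - 1, 0))
    best_v <- -Inf
  }
})

test_that("a default cohort shows visible z-expansion for cornifying cells", {
  cfg <- tiny_config()
  res <- simulate_cohort(cfg, 3, seed = 31, force_cornify = TRUE,
                         channels = "cyto")
  found <- FALSE
  for (cell in res$cells) {
    ts <- thickness_series(cell$stack, cell$roi, "cyto")
    base <- median(ts$thickness_pv_um[1:4], na.rm = TRUE)
    if (!is.na(base) && max(ts$thickness_pv_um, na.rm = TRUE) > 1.2 * base)
      found <- TRUE
  }
  expect_true(found)
})

test_that("oversized stacks are refused with the voxel budget", {
  cfg <- tiny_config(max_voxels = 1000)
  set.seed(9)
  tl <- sample_timeline(cfg, 1L)
  ph <- build_phantom(cfg, list(tl))
  expect_error(render_stack(ph, cfg), "voxels")
})

test_that("timelines beyond the simulated duration are caught", {
  cfg <- tiny_config()
  tl <- scripted_timeline(arrest = 10, onset = 12, max_exp = 20, flat = 500,
                          leak = NA)
  expect_warning(build_phantom(cfg, list(tl)), "duration")
  expect_error(build_phantom(cfg, list(tl), strict = TRUE), "duration")
})
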