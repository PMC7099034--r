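test_that("a slab spanning slices 11-21 measures 6.6 um at 0.6-um steps", {
  st <- slab_stack(z_on = 11L, z_off = 21L)
  res <- cell_thickness(st, square_roi(), "cyto", 1)
  expect_equal(res$thickness_um, 11 * 0.6)
  expect_equal(res$z_lo, 11L)
  expect_equal(res$z_hi, 21L)
})

test_that("zero-intensity and contrast-free ROIs report an absent cell", {
  dark <- image_stack(array(0, c(1, 1, 10, 12, 12)), 2, 0.6, 0.25, "cyto")
  expect_true(cell_thickness(dark, square_roi(x1 = 10, y1 = 10), 1, 1)$absent)
  flat <- image_stack(array(7, c(1, 1, 10, 12, 12)), 2, 0.6, 0.25, "cyto")
  expect_true(cell_thickness(flat, square_roi(x1 = 10, y1 = 10), 1, 1)$absent)
})

test_that("thickness is invariant to positive intensity rescaling", {
  st <- slab_stack(z_on = 8L, z_off = 15L)
  st5 <- st; st5$data <- st$data * 5
  r1 <- cell_thickness(st, square_roi(), 1, 1)
  r5 <- cell_thickness(st5, square_roi(), 1, 1)
  expect_equal(r1$thickness_um, r5$thickness_um)
  expect_equal(r1$z_lo, r5$z_lo)
})

# hand-traceable trapezoid: baseline 6 um, 5-frame ramp to 8.4 um,
# 5-frame collapse to 1.2 um, then flat
trapezoid_series <- function() {
  th <- c(rep(6, 8), seq(6.48, 8.4, length.out = 5),
          seq(6.96, 1.2, length.out = 5), rep(1.2, 12))
  out <- data.frame(time_min = (seq_along(th) - 1) * 2, thickness_um = th,
                    thickness_pv_um = th,
                    z_lo = 3L, z_hi = 3L + round(th / 0.6) - 1L,
                    absent = FALSE)
  attr(out, "z_step_um") <- 0.6
  attr(out, "frame_interval_min") <- 2
  class(out) <- c("thickness_series", "data.frame")
  out
}

test_that("staging rules hand-trace on a noiseless trapezoid", {
  ts <- trapezoid_series()
  st <- stage_morphology(ts, refine = FALSE)
  expect_equal(st$baseline_um, 6)
  # first frame >= 6.6 sustained 2: the 6.96-um frame at index 10 (t = 18)
  expect_equal(st$t_onset, ts$time_min[which(ts$thickness_um >= 6.6)[1]])
  # peak of the trapezoid
  expect_equal(st$t_max_expansion, ts$time_min[which.max(ts$thickness_um)])
  # first frame <= 1.2 um after the peak, sustained 2
  i_flat <- which(ts$time_min > st$t_max_expansion & ts$thickness_um <= 1.2)[1]
  expect_equal(st$t_flattened, ts$time_min[i_flat])
})

test_that("staging honours onset <= max <= flattened whenever present", {
  set.seed(44)
  for (i in 1:30) {
    th <- pmax(0.6, 6 + cumsum(rnorm(30, 0, 0.8)))
    out <- data.frame(time_min = (0:29) * 2, thickness_um = th,
                      thickness_pv_um = th, z_lo = 1L, z_hi = 10L,
                      absent = FALSE)
    attr(out, "z_step_um") <- 0.6
    attr(out, "frame_interval_min") <- 2
    st <- stage_morphology(out)
    ts <- c(st$t_onset, st$t_max_expansion, st$t_flattened)
    ts <- ts[!is.na(ts)]
    if (length(ts) > 1) expect_true(all(diff(ts) >= 0))
  }
})

test_that("a constant series stages nothing", {
  out <- data.frame(time_min = (0:19) * 2, thickness_um = rep(6, 20),
                    thickness_pv_um = rep(6, 20), z_lo = 3L, z_hi = 12L,
                    absent = FALSE)
  attr(out, "z_step_um") <- 0.6
  attr(out, "frame_interval_min") <- 2
  st <- stage_morphology(out)
  expect_true(is.na(st$t_onset))
  expect_true(is.na(st$t_max_expansion))
  expect_true(is.na(st$t_flattened))
})

test_that("too-short series are rejected", {
  out <- data.frame(time_min = (0:5) * 2, thickness_um = rep(6, 6),
                    thickness_pv_um = rep(6, 6), z_lo = 1L, z_hi = 10L,
                    absent = FALSE)
  attr(out, "z_step_um") <- 0.6
  expect_error(stage_morphology(out), "10 frames")
})
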