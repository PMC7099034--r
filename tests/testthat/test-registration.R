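smooth_test_image <- function(n_y = 48, n_x = 48, seed = 15) {
  set.seed(seed)
  ys <- seq_len(n_y); xs <- seq_len(n_x)
  img <- outer(ys, xs, function(y, x)
    50 + 40 * sin(y / 5) * cos(x / 7) + 25 * sin((x + y) / 9))
  img + matrix(runif(n_y * n_x, 0, 2), n_y, n_x)
}

shifted_stack <- function(img, shifts) {
  n_t <- nrow(shifts)
  data <- array(0, c(n_t, 1, 1, nrow(img), ncol(img)))
  for (t in seq_len(n_t)) {
    dy <- shifts[t, 1]; dx <- shifts[t, 2]
    src_y <- seq_len(nrow(img)) - dy
    src_x <- seq_len(ncol(img)) - dx
    oky <- src_y >= 1 & src_y <= nrow(img)
    okx <- src_x >= 1 & src_x <= ncol(img)
    fr <- matrix(0, nrow(img), ncol(img))
    fr[oky, okx] <- img[src_y[oky], src_x[okx]]
    data[t, 1, 1, , ] <- fr
  }
  image_stack(data, 2, 0.6, 0.25, "cyto")
}

test_that("known integer translations are recovered to 0.1 px", {
  img <- smooth_test_image()
  st <- shifted_stack(img, rbind(c(0, 0), c(3, -2)))
  tr <- estimate_drift(st, "cyto")
  expect_equal(tr$dy[1], 0); expect_equal(tr$dx[1], 0)
  expect_equal(tr$dy[2], 3, tolerance = 0.1)
  expect_equal(tr$dx[2], -2, tolerance = 0.1)
})

test_that("identical frames give zero drift; constant frames error", {
  img <- smooth_test_image(seed = 16)
  st <- shifted_stack(img, rbind(c(0, 0), c(0, 0), c(0, 0)))
  tr <- estimate_drift(st, "cyto")
  expect_true(all(abs(tr$dy) < 0.05 & abs(tr$dx) < 0.05))
  flat <- image_stack(array(1, c(2, 1, 1, 8, 8)), 2, 0.6, 0.25)
  expect_error(estimate_drift(flat, 1), "degenerate")
})

test_that("apply_drift with a zero trace is the identity", {
  img <- smooth_test_image(seed = 17)
  st <- shifted_stack(img, rbind(c(0, 0), c(0, 0)))
  tr <- data.frame(frame = 1:2, dy = c(0, 0), dx = c(0, 0))
  out <- apply_drift(st, tr)
  expect_identical(out$data, st$data)
})

test_that("correction is a contraction on synthetic integer drifts", {
  img <- smooth_test_image(seed = 18)
  n_t <- 6
  st <- shifted_stack(img, cbind((0:(n_t - 1)) * 1, 0))  # 1 px/frame in y
  tr <- estimate_drift(st, "cyto")
  slope <- coef(lm(tr$dy ~ tr$frame))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
  corr <- apply_drift(st, tr, "nearest")
  tr2 <- estimate_drift(corr, "cyto")
  expect_true(all(abs(tr2$dy) <= 0.1 + 1e-9))
  expect_true(all(abs(tr2$dx) <= 0.1 + 1e-9))
})

test_that("interior intensity is conserved under integer shifts", {
  img <- smooth_test_image(seed = 19)
  st <- shifted_stack(img, rbind(c(0, 0), c(2, 1)))
  tr <- data.frame(frame = 1:2, dy = c(0, 2), dx = c(0, 1))
  out <- apply_drift(st, tr, "nearest")
  inner <- 10:38
  expect_equal(out$data[2, 1, 1, inner, inner], st$data[1, 1, 1, inner, inner])
  expect_false(all(out$validity[2, , ]))
})

test_that("trace length mismatches are rejected", {
  st <- shifted_stack(smooth_test_image(seed = 20), rbind(c(0, 0), c(1, 0)))
  expect_error(apply_drift(st, data.frame(frame = 1, dy = 0, dx = 0)), "length")
})

test_that("drift trace CSV round trip", {
  tr <- data.frame(frame = 1:3, dy = c(0, 0.5, 1), dx = c(0, -0.2, -0.4))
  f <- tempfile(fileext = ".csv")
  write_drift(tr, f)
  back <- read_drift(f)
  expect_equal(back$dy, tr$dy)
  unlink(f)
})

test_that("denoising behaves like the named filters", {
  set.seed(22)
  base <- array(10, c(1, 1, 2, 16, 16))
  st_const <- image_stack(base, 2, 0.6, 0.25)
  out <- denoise(st_const, "median", 1)
  expect_equal(out$data, st_const$data, tolerance = 1e-6)

  hot <- base
  hot[1, 1, 1, 8, 8] <- 1000
  st_hot <- image_stack(hot, 2, 0.6, 0.25)
  out <- denoise(st_hot, "median", 1)
  # the median filter quantizes internally; the hot pixel must collapse
  # to the neighbourhood level
  expect_equal(out$data[1, 1, 1, 8, 8], 10, tolerance = 0.01)

  noisy <- array(50 + rnorm(2 * 1 * 2 * 24 * 24, 0, 8), c(2, 1, 2, 24, 24))
  st_noisy <- image_stack(noisy, 2, 0.6, 0.25)
  sm <- denoise(st_noisy, "gaussian", 1.5)
  expect_identical(dim(sm$data), dim(st_noisy$data))
  expect_equal(sm$z_step_um, 0.6)
  for (t in 1:2) for (z in 1:2)
    expect_lt(var(c(sm$data[t, 1, z, , ])), var(c(st_noisy$data[t, 1, z, , ])))
  expect_error(denoise(st_noisy, "boxcar"), "arg")
})
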