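# hand-built mito test stack: bright shapes on a dim noisy background
shape_stack <- function(fill, n_z = 12L, n_y = 32L, n_x = 32L, noise_sd = 1) {
  set.seed(61)
  data <- array(2 + abs(rnorm(n_z * n_y * n_x, 0, noise_sd)),
                c(1, 1, n_z, n_y, n_x))
  data[1, 1, , , ] <- fill(data[1, 1, , , ])
  image_stack(data, 2, 0.6, 0.25, "mito")
}

add_ball <- function(vol, zc, yc, xc, r_vox_z, r_vox_xy, level = 120) {
  d <- dim(vol)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (((z - zc) / r_vox_z)^2 + ((y - yc) / r_vox_xy)^2 +
        ((x - xc) / r_vox_xy)^2 <= 1)
      vol[z, y, x] <- level
  }
  vol
}

full_roi <- function(n = 32) cell_roi(1, cbind(x = c(0, n - 1, n - 1, 0),
                                               y = c(0, 0, n - 1, n - 1)))

test_that("disjoint spheres segment into one component each", {
  st <- shape_stack(function(v) {
    centers <- list(c(4, 6, 6), c(4, 6, 24), c(8, 16, 16), c(4, 26, 8),
                    c(8, 26, 26))
    for (ctr in centers) v <- add_ball(v, ctr[1], ctr[2], ctr[3], 1.6, 2.2)
    v
  })
  seg <- segment_mito(st, full_roi(), "mito", 1)
  expect_equal(length(seg$voxels), 5)
})

test_that("an empty ROI yields zero components and a zeroed profile", {
  st <- shape_stack(function(v) v)
  seg <- segment_mito(st, full_roi(), "mito", 1)
  # Otsu on pure noise splits it, but min_volume and the flat histogram
  # leave nothing resembling organelles above 4 voxels is not guaranteed;
  # use a strictly zero image for the contract
  dark <- image_stack(array(0, c(1, 1, 6, 16, 16)), 2, 0.6, 0.25, "mito")
  seg0 <- segment_mito(dark, cell_roi(1, cbind(x = c(0, 15, 15, 0),
                                               y = c(0, 0, 15, 15))), "mito", 1)
  expect_equal(length(seg0$voxels), 0)
  prof <- mito_features(seg0)
  expect_equal(prof$total_volume_um3, 0)
  expect_equal(prof$n_components, 0L)
  expect_equal(prof$punctate_fraction, 1)
})

test_that("spheres are punctate and long rods are elongated", {
  # physically isotropic ball: radius 1.2 um = 2 z-slices = 4.8 xy px
  st_ball <- shape_stack(function(v) add_ball(v, 6, 16, 16, 2, 4.8))
  seg <- segment_mito(st_ball, full_roi(), "mito", 1)
  prof <- mito_features(seg)
  expect_equal(prof$n_components, 1L)
  expect_lt(prof$max_elongation, 1.3)  # digitized ball stays near-isotropic
  expect_equal(prof$punctate_fraction, 1)

  st_rod <- shape_stack(function(v) {
    v[6, 15:16, 3:30] <- 120  # ~7 um x 0.5 um rod along x, one slice thick
    v
  })
  seg <- segment_mito(st_rod, full_roi(), "mito", 1)
  prof <- mito_features(seg)
  expect_equal(prof$n_components, 1L)
  expect_gt(prof$max_elongation, 5)
  expect_equal(prof$punctate_fraction, 0)
})

test_that("segmentation counts are invariant to intensity rescaling", {
  st <- shape_stack(function(v) {
    v <- add_ball(v, 4, 8, 8, 1.6, 2.2)
    add_ball(v, 8, 22, 22, 1.6, 2.2)
  })
  st2 <- st; st2$data <- st$data * 2
  n1 <- length(segment_mito(st, full_roi(), "mito", 1)$voxels)
  n2 <- length(segment_mito(st2, full_roi(), "mito", 1)$voxels)
  expect_equal(n1, n2)
})

test_that("group classification follows the volume/purity rules", {
  th <- list(v_small = 5, v_moderate = 16, purity = 0.8)  # explicit, not the defaults
  mk <- function(vol, pf) {
    structure(list(total_volume_um3 = vol, punctate_fraction = pf,
                   n_components = 1L, flattened_within_4h = NA),
              class = "mito_profile")
  }
  expect_equal(classify_group(mk(0, 1), th)$group, 1L)
  expect_equal(classify_group(mk(3, 0.9), th)$group, 1L)
  expect_equal(classify_group(mk(3, 0.5), th)$group, 2L)
  expect_equal(classify_group(mk(10, 0.1), th)$group, 3L)
  expect_equal(classify_group(mk(40, 0.0), th)$group, 4L)
  # boundary values go to the lower-numbered group
  expect_equal(classify_group(mk(5, 0.8), th)$group, 1L)
  expect_equal(classify_group(mk(16, 0), th)$group, 3L)
  expect_error(classify_group(mk(3, 1), list(v_small = 9, v_moderate = 2,
                                             purity = 0.8)), "v_small")
})

test_that("flattening outcome honours the strict 4-h horizon", {
  expect_true(flattening_outcome(list(t_flattened = 120)))
  expect_true(flattening_outcome(list(t_flattened = 240)))
  expect_false(flattening_outcome(list(t_flattened = 241)))
  expect_false(flattening_outcome(list(t_flattened = NA)))
})

test_that("contingency reproduces printed-style counts and is order-invariant", {
  profs <- list()
  counts <- rbind(c(62, 22), c(23, 59), c(6, 120), c(0, 191))
  id <- 1
  for (g in 1:4) for (fl in c(TRUE, FALSE)) {
    k <- counts[g, if (fl) 1 else 2]
    for (i in seq_len(k)) {
      profs[[id]] <- structure(list(group = g, flattened_within_4h = fl),
                               class = "mito_profile")
      id <- id + 1
    }
  }
  tab <- contingency(profs)
  expect_equal(tab$total, 483)
  expect_equal(unname(tab$flattened_percent[1]), 74)
  expect_equal(unname(tab$counts[2, ]), c(23, 59), ignore_attr = TRUE)
  set.seed(62)
  tab2 <- contingency(sample(profs))
  expect_identical(tab$counts, tab2$counts)
  one <- contingency(list(structure(list(group = 2L, flattened_within_4h = TRUE),
                                    class = "mito_profile")))
  expect_equal(one$total, 1)
  expect_equal(unname(one$counts[2, 1]), 1L)
})

test_that("mito disappearance triggers on a sustained step-down", {
  n_t <- 14L
  data <- array(2, c(n_t, 1, 6, 20, 20))
  data[, 1, 3:4, 9:12, 9:12] <- 100
  data[8:n_t, 1, 3:4, 9:12, 9:12] <- 5  # extinction at frame 8 (t = 14)
  data <- data + array(abs(rnorm(length(data), 0, 0.5)), dim(data))
  st <- image_stack(data, 2, 0.6, 0.25, "mito")
  roi <- cell_roi(1, cbind(x = c(0, 19, 19, 0), y = c(0, 0, 19, 19)))
  box <- list(xr = 10:12, yr = 10:12, zr = 3:4)
  res <- mito_disappearance(st, roi, "mito", list(box), t_arrest = 10)
  expect_equal(res$t_disappear, 14)
  expect_equal(res$co_timing_min, 4)
  # constant series: no call; zero-variance baseline: degenerate flag
  quiet <- list(xr = 16:18, yr = 16:18, zr = 5:6)
  res2 <- mito_disappearance(st, roi, "mito", list(quiet))
  expect_true(is.na(res2$t_disappear))
  flat_st <- image_stack(array(7, c(10, 1, 4, 12, 12)), 2, 0.6, 0.25, "mito")
  res3 <- mito_disappearance(flat_st, cell_roi(1, cbind(x = c(0, 11, 11, 0),
                                                        y = c(0, 0, 11, 11))),
                             "mito", list(list(xr = 4:6, yr = 4:6, zr = 2:3)))
  expect_true(res3$degenerate[1])
})
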