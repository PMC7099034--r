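test_that("truncated-normal moment matching hits attainable targets", {
  for (p in list(c(9.2, 3.3), c(9.0, 3.0), c(6, 2))) {
    f <- tnorm_match(p[1], p[2])
    expect_equal(f$mean_realized, p[1], tolerance = 1e-4)
    expect_equal(f$sd_realized, p[2], tolerance = 1e-3)
  }
  # cv > 1 is unattainable for a zero-truncated normal: the mean must
  # still be matched closely
  f <- tnorm_match(2.3, 3.1)
  expect_equal(f$mean_realized, 2.3, tolerance = 0.05)
})

test_that("sampled interval means agree with a Monte-Carlo oracle", {
  set.seed(42)
  cfg <- sim_config()
  p <- cfg$interval_parents$onset_to_max
  draws <- rtnorm0(1e4, p$mu, p$sigma)
  se <- sd(draws) / sqrt(length(draws))
  expect_true(all(draws >= 0))
  expect_lt(abs(mean(draws) - cfg$interval_params$onset_to_max[["mean"]]),
            3 * se + abs(p$mean_realized - 9.2))
  expect_equal(mean(draws), p$mean_realized, tolerance = 4 * se)
})

test_that("zero-SD intervals reproduce the configured means exactly", {
  cfg <- sim_config(interval_params = list(
    arrest_to_onset = c(mean = 2.3, sd = 0), onset_to_max = c(mean = 9.2, sd = 0),
    max_to_flat = c(mean = 9.0, sd = 0), flat_to_leak = c(mean = 3.9, sd = 0)),
    leak_probability = 1)
  set.seed(1)
  tl <- sample_timeline(cfg, 1L, force_cornify = TRUE)
  expect_equal(tl$t_onset - tl$t_arrest, 2.3)
  expect_equal(tl$t_max_expansion - tl$t_onset, 9.2)
  expect_equal(tl$t_flattened - tl$t_max_expansion, 9.0)
  expect_equal(tl$t_leakage - tl$t_flattened, 3.9)
})

test_that("timeline ordering and leakage structure hold across seeds", {
  cfg <- sim_config()
  for (seed in c(3, 17, 99)) {
    set.seed(seed)
    tls <- sample_timelines(cfg, 150, force_cornify = (seed == 17))
    for (tl in tls) {
      ts <- c(tl$t_arrest, tl$t_onset, tl$t_max_expansion,
              tl$t_flattened, tl$t_leakage)
      ts <- ts[!is.na(ts)]
      expect_true(all(diff(ts) >= 0))
      if (!is.na(tl$t_leakage)) expect_false(is.na(tl$t_flattened))
      expect_true(tl$group %in% 1:4)
    }
  }
})

test_that("zero flattening probability yields event-free timelines", {
  cfg <- sim_config(flatten_prob_by_group = rep(0, 4))
  set.seed(5)
  tls <- sample_timelines(cfg, 50)
  expect_true(all(vapply(tls, function(t) is.na(t$t_arrest), TRUE)))
  expect_true(all(vapply(tls, function(t) !t$flattened_within_4h, TRUE)))
})

test_that("group-conditional flattening matches configured probabilities", {
  cfg <- sim_config()
  set.seed(8)
  tls <- sample_timelines(cfg, 1e4)
  df <- timelines_df(tls)
  for (g in 1:3) {  # group 4 never flattens by configuration
    sel <- df$group == g
    p_hat <- mean(df$flattened_within_4h[sel])
    p <- cfg$flatten_prob_by_group[g]
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(p_hat - p), 3 * se + 1e-6)
  }
  expect_equal(sum(df$flattened_within_4h[df$group == 4]), 0)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(frame_interval_min = 0), "frame_interval_min")
  expect_error(sim_config(group_probs = c(0.5, 0.5, 0.2, 0.2)), "group_probs")
  expect_error(sim_config(leak_probability = 1.4), "leak_probability")
  expect_error(sim_config(interval_params = list(arrest_to_onset = c(-1, 1))),
               "interval_params")
  expect_error(sim_config(stack_shape = c(10, 10)), "stack_shape")
})

test_that("flg_kd preset lengthens flattening and lowers onset rate", {
  ctrl <- sim_config()
  kd <- sim_config(condition = "flg_kd")
  expect_equal(kd$interval_params$max_to_flat[["mean"]],
               4 * ctrl$interval_params$max_to_flat[["mean"]])
  expect_equal(kd$flatten_prob_by_group, 0.4 * ctrl$flatten_prob_by_group)
})
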