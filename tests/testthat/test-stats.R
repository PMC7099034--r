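tl_with <- function(...) {
  iv <- list(...)
  structure(list(intervals = c(arrest_to_onset = iv$a %||% NA,
                               onset_to_max = iv$o %||% NA,
                               max_to_flat = iv$m %||% NA,
                               flat_to_leak = iv$f %||% NA)),
            class = "event_timeline")
}

test_that("duration summaries use the sample SD and flag degenerate n", {
  s <- summarize_durations(list(tl_with(o = 2), tl_with(o = 4)), "onset_to_max")
  expect_equal(s$mean_min, 3)
  expect_equal(s$sd_min, sqrt(2))
  expect_equal(s$n, 2)
  one <- summarize_durations(list(tl_with(m = 5)), "max_to_flat")
  expect_equal(one$mean_min, 5)
  expect_equal(one$sd_min, 0)
  expect_true(one$n1_flag)
})

test_that("summaries are permutation-invariant and clamp small negatives", {
  tls <- lapply(c(3, 7, 1, 9, 4), function(v) tl_with(a = v))
  s1 <- summarize_durations(tls, "arrest_to_onset")
  s2 <- summarize_durations(rev(tls), "arrest_to_onset")
  expect_equal(s1$mean_min, s2$mean_min)
  expect_equal(s1$sd_min, s2$sd_min)
  expect_message(
    s <- summarize_durations(list(tl_with(a = -0.4), tl_with(a = 2)),
                             "arrest_to_onset"),
    "clamped")
  expect_equal(s$values, c(0, 2))
  expect_equal(s$n_clamped, 1)
})

test_that("missing intervals are excluded per-interval, empty errors", {
  tls <- list(tl_with(a = 1), tl_with(o = 5))
  expect_equal(summarize_durations(tls, "arrest_to_onset")$n, 1)
  expect_error(summarize_durations(tls, "flat_to_leak"), "no timeline")
})

test_that("exact rank-sum p-values match hand-enumerated cases", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(w$two_sided_p, 0.1)   # 2/20 arrangements as extreme
  expect_equal(w$U, 0)
  expect_equal(w$mode_used, "exact")
  same <- wilcoxon_rank_sum(c(2, 4, 1, 3), c(3, 1, 4, 2), mode = "auto")
  expect_equal(same$two_sided_p, 1.0)
  expect_equal(same$mode_used, "normal_approx")  # ties force the approximation
})

test_that("exact mode refuses ties and oversized samples; empty errors", {
  expect_error(wilcoxon_rank_sum(c(1, 2), c(2, 3), mode = "exact"), "ties")
  expect_error(wilcoxon_rank_sum(1:20, 21:40, mode = "exact"), "25")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact p agrees with the enumeration oracle for all n + m <= 8", {
  set.seed(71)
  for (n in 1:4) for (m in n:(8 - n)) {
    for (rep in 1:3) {
      x <- sample(seq(1, 100), n)
      y <- sample(setdiff(seq(1, 100), x), m)
      w <- wilcoxon_rank_sum(x, y, mode = "exact")
      expect_equal(w$two_sided_p, wilcoxon_oracle(x, y), tolerance = 1e-12)
    }
  }
})

test_that("the normal approximation tracks the exact test at n = m = 12", {
  set.seed(72)
  for (rep in 1:5) {
    x <- rnorm(12); y <- rnorm(12, 0.5)
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$two_sided_p
    pn <- wilcoxon_rank_sum(x, y, mode = "normal_approx")$two_sided_p
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("a 3-SD shift is detected essentially always at n = m = 30", {
  set.seed(73)
  rejections <- vapply(1:100, function(i) {
    x <- rnorm(30); y <- rnorm(30, 3)
    wilcoxon_rank_sum(x, y, mode = "normal_approx")$two_sided_p < 0.001
  }, TRUE)
  expect_gte(sum(rejections), 99)
})

test_that("events per hour is a simple rate with guarded inputs", {
  expect_equal(events_per_hour(6, 180), 2.0)
  expect_equal(events_per_hour(0, 120), 0.0)
  expect_error(events_per_hour(3, 0), "> 0")
})

test_that("significance stars follow the 0.05/0.01/0.001 legend", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
               c("", "*", "**", "***", ""))
})

test_that("knockdown-like onset-rate cohorts separate by rank sum", {
  set.seed(74)
  reject <- vapply(1:40, function(i) {
    ctrl <- vapply(1:8, function(j) events_per_hour(rpois(1, 12), 240), 0)
    kd <- vapply(1:8, function(j) events_per_hour(rpois(1, 12 * 0.4), 240), 0)
    wilcoxon_rank_sum(ctrl, kd)$two_sided_p < 0.05
  }, TRUE)
  expect_gte(mean(reject), 0.8)
})
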