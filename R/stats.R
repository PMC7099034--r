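#' Summarize an event interval over a cohort
#'
#' Mean and sample SD (n-1 denominator) of one recovered interval over the
#' cells where both endpoints are present. Slightly negative intervals —
#' within one frame interval, i.e. quantization slack — are clamped to 0
#' with a message; intervals with one endpoint missing are excluded
#' per-interval, not per-cell.
#'
#' @param timelines list of [event_timeline()] (or compatible) objects.
#' @param interval one of `"arrest_to_onset"`, `"onset_to_max"`,
#'   `"max_to_flat"`, `"flat_to_leak"`.
#' @return a `duration_summary`: list `(interval, n, mean_min, sd_min,
#'   values, n_clamped)`.
#' @export
summarize_durations <- function(timelines,
                                interval = c("arrest_to_onset", "onset_to_max",
                                             "max_to_flat", "flat_to_leak")) {
  interval <- match.arg(interval)
  vals <- vapply(timelines, function(tl) {
    if (!is.null(tl$intervals)) return(tl$intervals[[interval]])
    ends <- switch(interval,
      arrest_to_onset = c("t_arrest", "t_onset"),
      onset_to_max = c("t_onset", "t_max_expansion"),
      max_to_flat = c("t_max_expansion", "t_flattened"),
      flat_to_leak = c("t_flattened", "t_leakage"))
    (tl[[ends[2]]] %||% NA_real_) - (tl[[ends[1]]] %||% NA_real_)
  }, 0)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no timeline defines the interval '", interval, "'")
  neg <- vals < 0
  if (any(neg)) {
    message(sum(neg), " negative '", interval, "' interval(s) clamped to 0")
    vals[neg] <- 0
  }
  structure(list(interval = interval, n = length(vals),
                 mean_min = mean(vals),
                 sd_min = if (length(vals) > 1) sd(vals) else 0,
                 values = vals, n_clamped = sum(neg),
                 n1_flag = length(vals) == 1L),
            class = "duration_summary")
}

#' @export
print.duration_summary <- function(x, ...) {
  cat(sprintf("<duration_summary> %s: %.1f +/- %.1f min (n = %d%s)\n",
              x$interval, x$mean_min, x$sd_min, x$n,
              if (x$n1_flag) ", single value" else ""))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample rank-sum test. `mode = "exact"` enumerates the
#' null distribution of the U statistic (legal only without ties and for
#' `n + m <= 25`); `"normal_approx"` uses the normal approximation with
#' midranks, tie correction and continuity correction; `"auto"` picks
#' exact when legal.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list `(U, two_sided_p, mode_used, n, m)`; `U` is the
#'   Mann-Whitney statistic of `x`.
#' @importFrom stats wilcox.test
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  n <- length(x); m <- length(y)
  if (mode == "exact") {
    if (ties) stop("exact mode is not defined with ties; use normal_approx or auto")
    if (n + m > 25) stop("exact mode requires n + m <= 25")
  }
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = !ties && (n + m) <= 25)
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE, conf.int = FALSE))
  list(U = unname(wt$statistic), two_sided_p = min(wt$p.value, 1),
       mode_used = if (use_exact) "exact" else "normal_approx", n = n, m = m)
}

#' Significance stars (* < 0.05, ** < 0.01, *** < 0.001)
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, "")
}

#' Morphological-change onsets per observed hour
#' @param onset_count number of cells beginning the morphological change.
#' @param observed_minutes observation span in minutes (> 0).
#' @export
events_per_hour <- function(onset_count, observed_minutes) {
  if (!is.numeric(observed_minutes) || observed_minutes <= 0)
    stop("observed_minutes must be > 0")
  if (onset_count < 0) stop("onset_count must be >= 0")
  60 * onset_count / observed_minutes
}
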