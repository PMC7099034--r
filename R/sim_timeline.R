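#' Sample a ground-truth event timeline for one synthetic cell
#'
#' Draws the mitochondrial group, the 4-h flattening outcome conditional on
#' the group, and — for cornifying cells — the continuous event times
#' (vesicle arrest, morphological-change onset, maximum z-expansion,
#' flattening, DNA leakage) in minutes from acquisition start. Intervals are
#' zero-truncated normals moment-matched to the configured mean/SD.
#'
#' Draw order per cell (documented stream order): group, flattening
#' Bernoulli, arrest time, the four intervals, leakage Bernoulli.
#'
#' @param config a [sim_config()].
#' @param cell_index integer id stored on the timeline.
#' @param force_cornify if `TRUE`, the cell flattens regardless of its
#'   group's flattening probability (used to generate cohorts of cornifying
#'   cells, mirroring duration statistics that are conditional on
#'   flattening).
#' @return object of class `true_timeline` with fields `cell_id`, `group`,
#'   `flattened_within_4h`, and times `t_arrest`, `t_onset`,
#'   `t_max_expansion`, `t_flattened`, `t_leakage` (`NA` when absent).
#' @importFrom stats runif
#' @export
sample_timeline <- function(config, cell_index = 1L, force_cornify = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  group <- sample.int(4L, 1L, prob = config$group_probs)
  flattens <- if (force_cornify) TRUE else
    runif(1) < config$flatten_prob_by_group[group]
  tl <- list(cell_id = as.integer(cell_index), group = group,
             flattened_within_4h = FALSE,
             t_arrest = NA_real_, t_onset = NA_real_,
             t_max_expansion = NA_real_, t_flattened = NA_real_,
             t_leakage = NA_real_)
  if (flattens) {
    w <- config$arrest_window_min
    tl$t_arrest <- runif(1, w[1], w[2])
    draw <- function(nm) {
      p <- config$interval_parents[[nm]]
      rtnorm0(1L, p$mu, p$sigma)
    }
    tl$t_onset <- tl$t_arrest + draw("arrest_to_onset")
    tl$t_max_expansion <- tl$t_onset + draw("onset_to_max")
    tl$t_flattened <- tl$t_max_expansion + draw("max_to_flat")
    tl$flattened_within_4h <- tl$t_flattened <= 240
    if (runif(1) < config$leak_probability)
      tl$t_leakage <- tl$t_flattened + draw("flat_to_leak")
  }
  structure(tl, class = "true_timeline")
}

#' Sample many timelines
#' @inheritParams sample_timeline
#' @param n number of cells.
#' @export
sample_timelines <- function(config, n, force_cornify = FALSE) {
  lapply(seq_len(n), function(i) sample_timeline(config, i, force_cornify))
}

#' Convert a list of timelines (true or recovered) to a data frame
#' @param timelines list of `true_timeline` or `event_timeline` objects.
#' @export
timelines_df <- function(timelines) {
  grab <- function(f) vapply(timelines, function(t) t[[f]] %||% NA_real_, 0)
  df <- data.frame(
    cell_id = vapply(timelines, function(t) as.integer(t$cell_id %||% NA), 0L),
    t_arrest = grab("t_arrest"), t_onset = grab("t_onset"),
    t_max_expansion = grab("t_max_expansion"),
    t_flattened = grab("t_flattened"), t_leakage = grab("t_leakage"))
  if (!is.null(timelines[[1]]$group)) {
    df$group <- vapply(timelines, function(t) as.integer(t$group), 0L)
    df$flattened_within_4h <-
      vapply(timelines, function(t) isTRUE(t$flattened_within_4h), TRUE)
  }
  df
}

#' @export
print.true_timeline <- function(x, ...) {
  cat(sprintf("<true_timeline> cell %d group %d%s\n", x$cell_id, x$group,
              if (isTRUE(x$flattened_within_4h)) " (cornifies)" else ""))
  for (f in c("t_arrest", "t_onset", "t_max_expansion", "t_flattened", "t_leakage"))
    if (!is.na(x[[f]])) cat(sprintf("  %-16s %7.2f min\n", f, x[[f]]))
  invisible(x)
}

#' Write / read ground-truth timelines as JSON
#' @param timelines list of timelines.
#' @param path output file.
#' @export
write_truth <- function(timelines, path) {
  jsonlite::write_json(timelines_df(timelines), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
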