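#' Full per-cell analysis: registration, arrest, staging, leakage
#'
#' The preprocessing-plus-detection path applied to one cell crop:
#' estimate xy drift on the cytoplasm channel, undo it (bilinear), then
#' stage all events with [stage_cell()].
#'
#' @param stack an [image_stack()] (uncorrected).
#' @param roi a [cell_roi()].
#' @param channel_map role-to-channel map (see [stage_cell()]).
#' @param params detector parameter overrides (see [stage_cell()]).
#' @param register estimate and undo drift first (default `TRUE`).
#' @return an [event_timeline()].
#' @export
analyze_cell <- function(stack, roi,
                         channel_map = c(nucleus = "nucleus", cyto = "cyto",
                                         vesicle = "vesicle"),
                         params = list(), register = TRUE) {
  if (register) {
    trace <- estimate_drift(stack, channel_map[["cyto"]])
    stack <- apply_drift(stack, trace, "linear")
  }
  stage_cell(stack, roi, channel_map, params = params)
}

#' Simulate and analyze a cohort of cornifying cells
#'
#' Generates `n` single-cell crops with [simulate_cohort()] and runs
#' [analyze_cell()] on each, returning ground truth and recovered
#' timelines side by side. This is the package's parameter-recovery
#' harness: the generator scripts the events, the pipeline must find them.
#'
#' @param config a [sim_config()].
#' @param n number of cells.
#' @param seed integer seed.
#' @param force_cornify only cornifying cells (default `TRUE`: duration
#'   statistics are conditional on flattening).
#' @param params detector overrides.
#' @return list with `truth` and `recovered` (lists of timelines), plus
#'   data-frame views `truth_df`, `recovered_df`.
#' @export
run_recovery_cohort <- function(config, n, seed = config$seed,
                                force_cornify = TRUE, params = list()) {
  res <- simulate_cohort(config, n, seed = seed,
                         force_cornify = force_cornify, keep_stacks = FALSE,
                         per_cell = function(stack, roi, truth)
                           suppressWarnings(
                             analyze_cell(stack, roi, params = params)),
                         channels = c("nucleus", "cyto", "vesicle"))
  list(truth = res$truth, recovered = res$results,
       truth_df = timelines_df(res$truth),
       recovered_df = timelines_df(res$results))
}
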