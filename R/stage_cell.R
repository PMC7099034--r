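#' Recovered per-cell event timeline
#'
#' @param cell_id identifier.
#' @param t_arrest,t_onset,t_max_expansion,t_flattened,t_leakage event
#'   times in minutes (`NA` when absent).
#' @param frame_interval_min used to flag ordering violations beyond the
#'   one-frame quantization slack.
#' @return object of class `event_timeline` with the five times, the four
#'   derived intervals (`arrest_to_onset`, `onset_to_max`, `max_to_flat`,
#'   `flat_to_leak`) and `flags` naming any interval more negative than
#'   one frame interval (flagged, never silently reordered).
#' @export
event_timeline <- function(cell_id, t_arrest = NA, t_onset = NA,
                           t_max_expansion = NA, t_flattened = NA,
                           t_leakage = NA, frame_interval_min = 2) {
  iv <- c(arrest_to_onset = t_onset - t_arrest,
          onset_to_max = t_max_expansion - t_onset,
          max_to_flat = t_flattened - t_max_expansion,
          flat_to_leak = t_leakage - t_flattened)
  flags <- names(iv)[!is.na(iv) & iv < -frame_interval_min]
  structure(list(cell_id = cell_id, t_arrest = t_arrest, t_onset = t_onset,
                 t_max_expansion = t_max_expansion, t_flattened = t_flattened,
                 t_leakage = t_leakage, intervals = iv, flags = flags,
                 frame_interval_min = frame_interval_min),
            class = "event_timeline")
}

#' @export
print.event_timeline <- function(x, ...) {
  cat(sprintf("<event_timeline> cell %s\n", format(x$cell_id)))
  for (f in c("t_arrest", "t_onset", "t_max_expansion", "t_flattened", "t_leakage"))
    cat(sprintf("  %-16s %s\n", f,
                if (is.na(x[[f]])) "absent" else sprintf("%7.2f min", x[[f]])))
  if (length(x$flags))
    cat("  ordering flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Stage all cornification events of one cell
#'
#' Merges the vesicle-arrest call, the thickness-based morphology stages
#' and the DNA-leakage call into one recovered [event_timeline()]:
#' computes the correlation series on the vesicle channel, stages
#' onset/maximum/flattening on the cytoplasm channel, and detects leakage
#' on the nucleus channel. Ordering violations are flagged on the
#' timeline, never silently reordered.
#'
#' @param stack a drift-corrected [image_stack()].
#' @param roi a [cell_roi()].
#' @param channel_map named vector mapping roles to channels, with at
#'   least `nucleus`, `cyto` and `vesicle` (names or indices).
#' @param arrest optional precomputed [detect_arrest()] call.
#' @param params optional list overriding detector defaults:
#'   `threshold_r`, `sustain_pairs`, `onset_factor`, `sustain`,
#'   `flatten_um`, `k_sd`, `refine`.
#' @return an [event_timeline()].
#' @export
stage_cell <- function(stack, roi, channel_map = c(nucleus = "nucleus",
                                                   cyto = "cyto",
                                                   vesicle = "vesicle"),
                       arrest = NULL, params = list()) {
  for (role in c("nucleus", "cyto", "vesicle"))
    if (!role %in% names(channel_map))
      stop("channel_map is missing the required role '", role, "'")
  p <- utils::modifyList(list(threshold_r = 0.6, sustain_pairs = 3L,
                              onset_factor = 1.10, sustain = 2L,
                              flatten_um = NULL, k_sd = 3, refine = TRUE),
                         params)
  if (is.null(arrest)) {
    cs <- correlation_series(stack, roi, channel_map[["vesicle"]])
    arrest <- detect_arrest(cs, p$threshold_r, p$sustain_pairs, p$refine)
  }
  ts <- thickness_series(stack, roi, channel_map[["cyto"]])
  st <- stage_morphology(ts, p$onset_factor, p$sustain, p$flatten_um, p$refine)
  t_leak <- NA_real_
  if (!is.na(st$t_flattened)) {
    # ring baseline needs a few pre-flattening frames; no need for earlier ones
    i_flat <- findInterval(st$t_flattened, frame_times(stack))
    ns <- nuclear_series(stack, roi, channel_map[["nucleus"]],
                         t_range = c(max(1L, i_flat - 6L), dim(stack$data)[1]))
    if (!is.null(ns))
      t_leak <- tryCatch(
        detect_leakage(ns, st$t_flattened, k_sd = p$k_sd, refine = p$refine),
        error = function(e) NA_real_)
  }
  event_timeline(roi$cell_id, arrest$t_arrest, st$t_onset,
                 st$t_max_expansion, st$t_flattened, t_leak,
                 stack$frame_interval_min)
}
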