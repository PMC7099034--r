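#' Assemble the tabular and graphical result surface
#'
#' Writes, deterministically for given inputs: `intervals.csv` (per-cohort
#' interval summaries, minutes to 1 decimal retained as raw values),
#' `comparison.csv` (per-interval control-vs-condition rank-sum tests with
#' significance stars) when a condition cohort is given, `contingency.csv`
#' when a [group_table()] is given, `report.json` with every number, and
#' PNG box/bar plots.
#'
#' @param timelines_control list of [event_timeline()] objects.
#' @param timelines_condition optional second cohort (e.g. knockdown).
#' @param group_table optional [group_table()].
#' @param out_dir output directory (created if needed).
#' @param condition_labels labels for the two cohorts.
#' @return invisibly, the named list of files written.
#' @importFrom grDevices png dev.off
#' @export
build_report <- function(timelines_control, timelines_condition = NULL,
                         group_table = NULL, out_dir,
                         condition_labels = c("control", "condition")) {
  if (is.null(timelines_control) || !length(timelines_control))
    stop("at least one cohort (timelines_control) is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- list()
  intervals <- c("arrest_to_onset", "onset_to_max", "max_to_flat", "flat_to_leak")

  summarize_cohort <- function(tls, label) {
    do.call(rbind, lapply(intervals, function(iv) {
      s <- tryCatch(suppressMessages(summarize_durations(tls, iv)),
                    error = function(e) NULL)
      if (is.null(s)) return(NULL)
      data.frame(cohort = label, interval = iv, n = s$n,
                 mean_min = s$mean_min, sd_min = s$sd_min)
    }))
  }
  tab <- summarize_cohort(timelines_control, condition_labels[1])
  if (!is.null(timelines_condition))
    tab <- rbind(tab, summarize_cohort(timelines_condition, condition_labels[2]))
  f <- file.path(out_dir, "intervals.csv")
  write.csv(tab, f, row.names = FALSE)
  files$intervals <- f

  comp <- NULL
  if (!is.null(timelines_condition)) {
    comp <- do.call(rbind, lapply(intervals, function(iv) {
      vx <- tryCatch(suppressMessages(summarize_durations(timelines_control, iv))$values,
                     error = function(e) NULL)
      vy <- tryCatch(suppressMessages(summarize_durations(timelines_condition, iv))$values,
                     error = function(e) NULL)
      if (is.null(vx) || is.null(vy)) return(NULL)
      w <- wilcoxon_rank_sum(vx, vy)
      data.frame(interval = iv, U = w$U, p = w$two_sided_p,
                 stars = significance_stars(w$two_sided_p),
                 n_control = w$n, n_condition = w$m)
    }))
    f <- file.path(out_dir, "comparison.csv")
    write.csv(comp, f, row.names = FALSE)
    files$comparison <- f
  }

  if (!is.null(group_table)) {
    ct <- data.frame(group = 1:4,
                     flattened = group_table$counts[, 1],
                     not_flattened = group_table$counts[, 2],
                     flattened_percent = group_table$flattened_percent)
    f <- file.path(out_dir, "contingency.csv")
    write.csv(ct, f, row.names = FALSE)
    files$contingency <- f
  }

  rep <- list(intervals = tab, comparison = comp,
              contingency = if (!is.null(group_table))
                list(counts = group_table$counts,
                     flattened_percent = group_table$flattened_percent,
                     total = group_table$total))
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor", na = "null")
  files$json <- f

  # plots
  df_iv <- do.call(rbind, lapply(
    list(list(timelines_control, condition_labels[1]),
         if (!is.null(timelines_condition))
           list(timelines_condition, condition_labels[2])),
    function(pair) {
      if (is.null(pair)) return(NULL)
      do.call(rbind, lapply(intervals, function(iv) {
        v <- tryCatch(suppressMessages(summarize_durations(pair[[1]], iv))$values,
                      error = function(e) NULL)
        if (is.null(v)) return(NULL)
        data.frame(cohort = pair[[2]], interval = iv, minutes = v)
      }))
    }))
  if (!is.null(df_iv)) {
    df_iv$interval <- factor(df_iv$interval, levels = intervals)
    p1 <- ggplot2::ggplot(df_iv, ggplot2::aes(x = interval, y = minutes,
                                              fill = cohort)) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(x = NULL, y = "interval (min)") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "intervals.png")
    png(f, width = 900, height = 500, res = 120)
    print(p1); dev.off()
    files$intervals_plot <- f
  }
  if (!is.null(group_table)) {
    dfc <- data.frame(group = factor(rep(1:4, 2)),
                      outcome = rep(c("flattened", "not flattened"),
                                    each = 4),
                      count = c(group_table$counts[, 1], group_table$counts[, 2]))
    p2 <- ggplot2::ggplot(dfc, ggplot2::aes(x = group, y = count, fill = outcome)) +
      ggplot2::geom_col(position = "fill") +
      ggplot2::labs(y = "proportion of cells") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "contingency.png")
    png(f, width = 600, height = 450, res = 120)
    print(p2); dev.off()
    files$contingency_plot <- f
  }
  invisible(files)
}
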