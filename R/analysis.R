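#' Summarize reaching performance per condition
#'
#' Descriptive statistics of the reaching times, grouped by cohort x method x
#' DOF condition. Discarded (practice) trials and failed (timeout) trials are
#' dropped from the reaching-time statistics; timeouts are reported as a
#' separate failure rate. When several subjects contributed to a condition
#' and `subject_average = TRUE` (the default, mirroring how multi-subject
#' cohorts are usually pooled), reaching times are first averaged per
#' target x trial index across subjects and the averages pooled; otherwise
#' all trials are pooled directly.
#'
#' @param results trial data.frame from [run_session()] (or several row-bound
#'   sessions).
#' @param subject_average average across subjects per target x trial index
#'   before pooling, default TRUE.
#' @param bin_width histogram bin width in seconds, default 1; edges are
#'   anchored at 0.
#' @param sd_type `"sample"` (n-1 divisor, default) or `"population"`.
#' @return data.frame of class `condition_summary`, one row per condition:
#'   n_events, mean_s, sd_s, min_s, max_s, n_failed, failure_rate, with the
#'   per-condition histograms (`list(bin_edges, counts)`) in the `histograms`
#'   attribute.
#' @export
summarize_trials <- function(results, subject_average = TRUE,
                             bin_width = 1, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("cohort", "method", "dof", "target_id", "trial_index",
                  "discarded", "success", "reaching_time_s") %in% names(results)))
  keys <- unique(results[, c("cohort", "method", "dof")])
  keys <- keys[order(keys$cohort, keys$method, keys$dof), , drop = FALSE]
  hists <- list()
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    g <- results[results$cohort == k$cohort & results$method == k$method &
                   results$dof == k$dof & !results$discarded, , drop = FALSE]
    ok <- g[g$success, , drop = FALSE]
    times <- if (subject_average && "subject" %in% names(g) &&
                 length(unique(g$subject)) > 1) {
      as.numeric(tapply(ok$reaching_time_s,
                        interaction(ok$target_id, ok$trial_index, drop = TRUE),
                        mean))
    } else ok$reaching_time_s
    n <- length(times)
    s <- if (n >= 2) stats::sd(times) else NA_real_
    if (sd_type == "population" && n >= 2) s <- s * sqrt((n - 1) / n)
    edges <- if (n > 0) seq(0, bin_width * ceiling(max(times) / bin_width + 1e-12),
                            by = bin_width) else numeric(0)
    if (n > 0 && length(edges) < 2) edges <- c(0, bin_width)
    counts <- if (n > 0)
      graphics::hist(times, breaks = edges, plot = FALSE, right = FALSE)$counts
    else integer(0)
    hists[[i]] <<- list(bin_edges = edges, counts = counts)
    data.frame(cohort = k$cohort, method = k$method, dof = k$dof,
               n_events = n,
               mean_s = if (n > 0) mean(times) else NA_real_,
               sd_s = s,
               min_s = if (n > 0) min(times) else NA_real_,
               max_s = if (n > 0) max(times) else NA_real_,
               n_failed = sum(!g$success),
               failure_rate = if (nrow(g) > 0) mean(!g$success) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- hists
  class(out) <- c("condition_summary", class(out))
  out
}

#' Write a summary report
#'
#' Writes the per-condition summary table as CSV and, optionally, one
#' reaching-time histogram image per condition. Output is deterministic for
#' a fixed input.
#'
#' @param summaries a [summarize_trials()] result.
#' @param dir output directory (created if missing).
#' @param plots also write histogram PNGs, default TRUE.
#' @return invisibly, the paths written.
#' @export
report <- function(summaries, dir, plots = TRUE) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- file.path(dir, "summary.csv")
  df <- as.data.frame(summaries)
  utils::write.csv(df, paths, row.names = FALSE)
  if (plots) {
    hists <- attr(summaries, "histograms")
    for (i in seq_len(nrow(df))) {
      h <- hists[[i]]
      if (length(h$counts) == 0) next
      f <- file.path(dir, sprintf("hist_%s_%s_%ddof.png",
                                  df$cohort[i], df$method[i], df$dof[i]))
      grDevices::png(f, width = 640, height = 480)
      mids <- h$bin_edges[-length(h$bin_edges)] + diff(h$bin_edges) / 2
      graphics::barplot(h$counts, names.arg = sprintf("%g", mids),
                        xlab = "reaching time (s)", ylab = "trials",
                        main = sprintf("%s / %s / %d-DOF", df$cohort[i],
                                       df$method[i], df$dof[i]))
      graphics::abline(v = NULL)
      grDevices::dev.off()
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Write / read a trial log as CSV
#' @param results trial data.frame from [run_session()].
#' @param path CSV path.
#' @export
write_trials <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) utils::read.csv(path)
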