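# Span scoring and session summaries.
#
# The task's performance measure is the span: the number of consecutive
# correct responses from the start of a trial, up to the ceiling. Summaries
# aggregate spans and response latencies per (condition x valence x
# stimulus-category) cell, mirroring the published group tables.

.cell_key <- function(category, condition, valence) {
  paste(category, condition, valence, sep = "|")
}

cell_order <- function(df) {
  order(match(df$category, .sdrst_categories),
        match(df$condition, .sdrst_conditions),
        match(df$valence, .sdrst_valences))
}

#' Span of one trial
#'
#' Counts the leading correct responses: the index of the first mistake
#' minus one, or the number of responses when there is no mistake. Step 1
#' is a forced touch (only one stimulus is on screen), so spans of
#' completed trials lie in `[1, max_items]`.
#'
#' @param correct logical vector of response correctness in order, or a
#'   list/data frame with a `correct` element.
#' @return integer span.
#' @examples
#' trial_span(c(TRUE, TRUE, TRUE, FALSE))  # 3
#' trial_span(rep(TRUE, 8))                # 8 (ceiling)
#' @export
trial_span <- function(correct) {
  if (is.list(correct)) correct <- correct$correct
  correct <- as.logical(correct)
  if (length(correct) == 0L || anyNA(correct)) {
    stop("trial has no responses", call. = FALSE)
  }
  wrong <- which(!correct)
  if (length(wrong) == 0L) length(correct) else wrong[1L] - 1L
}

#' Summarize a completed session
#'
#' Per (stimulus category x condition x valence) cell: number of trials,
#' mean and sample SD (n - 1 denominator) of trial spans, and mean response
#' latency (response timestamp minus the matching display onset, pooled
#' over the cell's responses). Cells with no trials are absent. The overall
#' mean span equals the trial-count-weighted mean of the cell means.
#'
#' @param log an `sdrst_log` from a session that reached `session_ended`.
#' @return an `sdrst_summary`: `overall` (`n_trials`, `mean_span`,
#'   `sd_span`, `mean_rt_ms`) and `cells` (one row per non-empty cell).
#' @examples
#' log <- run_with_agent(sdrst_preset("study_b"), agent_perfect(), 1)
#' summarize_session(log)$cells
#' @export
summarize_session <- function(log) {
  stopifnot(inherits(log, "sdrst_log"))
  if (!isTRUE(log$header$complete) &&
      !(nrow(log$events) > 0L && any(log$events$type == "session_end"))) {
    stop("truncated log: missing session_end event", call. = FALSE)
  }
  trials <- log$trials
  if (nrow(trials) == 0L) stop("log contains no completed trials",
                               call. = FALSE)

  rt <- rep(NA_real_, nrow(trials))
  ev <- log$events
  if (nrow(ev) > 0L) {
    disp <- ev[ev$type == "display", c("trial", "step", "timestamp_ms")]
    resp <- ev[ev$type == "response", c("trial", "step", "timestamp_ms")]
    key_d <- paste(disp$trial, disp$step)
    key_r <- paste(resp$trial, resp$step)
    lat <- resp$timestamp_ms - disp$timestamp_ms[match(key_r, key_d)]
    per_trial <- tapply(lat, resp$trial, mean)
    rt <- as.numeric(per_trial[as.character(trials$trial)])
  }

  key <- .cell_key(trials$category, trials$condition, trials$valence)
  cells <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key),
                                 function(i) {
    data.frame(category = trials$category[i[1L]],
               condition = trials$condition[i[1L]],
               valence = trials$valence[i[1L]],
               n_trials = length(i),
               mean_span = mean(trials$span[i]),
               sd_span = stats::sd(trials$span[i]),
               mean_rt_ms = if (all(is.na(rt[i]))) NA_real_ else
                 mean(rt[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  cells <- cells[cell_order(cells), , drop = FALSE]
  rownames(cells) <- NULL

  structure(
    list(overall = list(
           n_trials = nrow(trials),
           mean_span = mean(trials$span),
           sd_span = stats::sd(trials$span),
           mean_rt_ms = if (all(is.na(rt))) NA_real_ else
             mean(rt, na.rm = TRUE)),
         cells = cells,
         max_items = log$header$config$max_items),
    class = "sdrst_summary")
}

#' @export
print.sdrst_summary <- function(x, ...) {
  cat(sprintf("<sdrst_summary> %d trials, mean span %.3f (SD %.3f)\n",
              x$overall$n_trials, x$overall$mean_span, x$overall$sd_span))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Export a session summary as CSV
#'
#' One row per non-empty cell, RFC 4180 comma-separated, numbers to six
#' decimals; byte-deterministic for a fixed summary.
#'
#' @param summary an `sdrst_summary`.
#' @param group_label label written in the first column.
#' @param path optional output file.
#' @return the CSV text (invisibly when `path` is given).
#' @export
export_summary <- function(summary, group_label = "group", path = NULL) {
  stopifnot(inherits(summary, "sdrst_summary"))
  c_ <- summary$cells
  lines <- c(
    "group,category,condition,valence,n_trials,mean_span,sd_span,mean_rt_ms",
    sprintf("%s,%s,%s,%s,%d,%s,%s,%s",
            group_label, c_$category, c_$condition, c_$valence, c_$n_trials,
            fmt_num(c_$mean_span), fmt_num(c_$sd_span),
            fmt_num(c_$mean_rt_ms)))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
    return(invisible(text))
  }
  text
}
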