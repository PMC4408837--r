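# Session logs: in-memory representation and JSON-Lines persistence.
#
# A log is a header (canonical config, agent provenance) plus a data frame
# of timestamped events (display, response, feedback, invalid_response,
# trial_end, session_end) and a per-trial table derived from the engine's
# counters. Logs contain no wall-clock times, so identical seeds give
# byte-identical files.

.ev_fields <- c("type", "trial", "step", "location", "correct",
                "timestamp_ms", "feedback", "span", "ended_by",
                "condition", "valence", "category")

#' Extract the log from a finished (or running) session
#'
#' @param state an `sdrst_session`.
#' @param agent optional agent whose name/parameters are echoed into the
#'   log header for provenance.
#' @return an `sdrst_log`: `header` (format tag, canonical config, agent),
#'   `events` (data frame, empty when the session recorded spans only) and
#'   `trials` (one row per completed trial: `trial`, `condition`,
#'   `valence`, `category`, `span`, `ended_by`).
#' @export
session_log <- function(state, agent = NULL) {
  stopifnot(inherits(state, "sdrst_session"))
  n <- if (state$record) state$n_ev else 0L
  idx <- seq_len(n)
  events <- data.frame(
    type = state$ev_type[idx],
    trial = state$ev_trial[idx],
    step = state$ev_step[idx],
    location = state$ev_location[idx],
    correct = state$ev_correct[idx],
    timestamp_ms = state$ev_ts[idx],
    feedback = state$ev_feedback[idx],
    span = state$ev_span[idx],
    ended_by = state$ev_ended_by[idx],
    condition = state$ev_condition[idx],
    valence = state$ev_valence[idx],
    category = state$ev_category[idx],
    stringsAsFactors = FALSE)
  done <- which(nzchar(state$ended_by))
  trials <- data.frame(
    trial = done,
    condition = vapply(state$plans[done], `[[`, "", "condition"),
    valence = vapply(state$plans[done], `[[`, "", "valence"),
    category = vapply(state$plans[done], `[[`, "", "category"),
    span = state$spans[done],
    ended_by = state$ended_by[done],
    stringsAsFactors = FALSE)
  structure(
    list(header = list(
           format = "sdrst-log/1",
           n_trials = state$n_trials,
           complete = state$phase == "session_ended",
           agent = if (is.null(agent)) NULL else
             list(name = agent$name, params = agent$params),
           config = config_to_list(state$config)),
         events = events,
         trials = trials),
    class = "sdrst_log")
}

#' @export
print.sdrst_log <- function(x, ...) {
  cat(sprintf("<sdrst_log> %d/%d trials, %d events%s\n",
              nrow(x$trials), x$header$n_trials, nrow(x$events),
              if (isTRUE(x$header$complete)) "" else " (incomplete)"))
  invisible(x)
}

#' Write a session log as JSON-Lines
#'
#' One JSON object per line: a header line (`"type": "header"`) followed by
#' the events in order, each carrying only the fields defined for its type.
#' Timestamps are monotone within the file. Output is byte-deterministic
#' for a given log.
#'
#' @param log an `sdrst_log` with recorded events.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "sdrst_log"))
  header <- c(list(type = "header"), log$header)
  lines <- character(nrow(log$events) + 1L)
  lines[1L] <- as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                             digits = I(17), null = "null"))
  ev <- log$events
  for (i in seq_len(nrow(ev))) {
    row <- as.list(ev[i, .ev_fields])
    row <- row[!vapply(row, function(v) is.na(v), NA)]
    lines[i + 1L] <- as.character(jsonlite::toJSON(row, auto_unbox = TRUE,
                                                   digits = I(17)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-Lines session log
#'
#' Reconstructs the `sdrst_log` written by [write_session_log()]; the
#' per-trial table is rebuilt from the `trial_end` events, so re-scoring a
#' stored log reproduces the original summaries.
#'
#' @param path path to a `.jsonl` log file.
#' @return an `sdrst_log`.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty log file", call. = FALSE)
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  if (!identical(objs[[1L]]$type, "header")) {
    stop("log file missing header line", call. = FALSE)
  }
  header <- objs[[1L]]
  header$type <- NULL
  ev <- objs[-1L]
  get_col <- function(field, template) {
    cast <- switch(typeof(template),
                   integer = as.integer, double = as.numeric,
                   character = as.character, logical = as.logical)
    vapply(ev, function(e) {
      v <- e[[field]]
      if (is.null(v)) template else cast(v)
    }, template)
  }
  events <- data.frame(
    type = get_col("type", NA_character_),
    trial = get_col("trial", NA_integer_),
    step = get_col("step", NA_integer_),
    location = get_col("location", NA_integer_),
    correct = get_col("correct", NA),
    timestamp_ms = get_col("timestamp_ms", NA_real_),
    feedback = get_col("feedback", NA_character_),
    span = get_col("span", NA_integer_),
    ended_by = get_col("ended_by", NA_character_),
    condition = get_col("condition", NA_character_),
    valence = get_col("valence", NA_character_),
    category = get_col("category", NA_character_),
    stringsAsFactors = FALSE)
  te <- events[events$type == "trial_end", , drop = FALSE]
  trials <- data.frame(
    trial = te$trial, condition = te$condition, valence = te$valence,
    category = te$category, span = te$span, ended_by = te$ended_by,
    stringsAsFactors = FALSE)
  structure(list(header = header, events = events, trials = trials),
            class = "sdrst_log")
}
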