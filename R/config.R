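# Task configuration: the full examiner-selectable parameter surface of the
# SDRST (stimulus set, condition, counts, grid, timings, feedback), with
# validation, JSON (de)serialization, and the three published study presets.

.sdrst_categories <- c("geometric", "iaps_scene", "face")
.sdrst_valences   <- c("negative", "positive", "neutral", "none")
.sdrst_conditions <- c("unique", "varied")
.sdrst_choices    <- c("random", "defined")
.sdrst_feedback   <- c("none", "auditory", "auditory_plus_reward")

check_enum <- function(value, choices, field) {
  if (!(is.character(value) && length(value) == 1L && value %in% choices)) {
    stop(sprintf("%s: must be one of %s (got %s)",
                 field, paste(sQuote(choices), collapse = ", "),
                 deparse(value)), call. = FALSE)
  }
  value
}

check_count <- function(value, field, min = 1L) {
  v <- suppressWarnings(as.integer(value))
  if (length(v) != 1L || is.na(v) || v < min) {
    stop(sprintf("%s: must be a single integer >= %d (got %s)",
                 field, min, deparse(value)), call. = FALSE)
  }
  v
}

#' Describe one stimulus
#'
#' Stimuli are abstract identifiers plus metadata; no image assets are
#' managed. The display size in cm is descriptive only (the engine is
#' headless and never renders).
#'
#' @param stimulus_id non-empty string, unique within a stimulus set.
#' @param category one of `"geometric"`, `"iaps_scene"`, `"face"`.
#' @param valence emotional valence: `"negative"`, `"positive"`, `"neutral"`,
#'   or `"none"`. `"none"` is only permitted for geometric stimuli.
#' @param width_cm,height_cm physical display size metadata (default 4 cm
#'   square, the size used in the published studies).
#' @return an object of class `sdrst_stimulus`.
#' @examples
#' stimulus_spec("geometric_01", "geometric", "none")
#' stimulus_spec("face_negative_01", "face", "negative")
#' @export
stimulus_spec <- function(stimulus_id, category = "geometric",
                          valence = "none", width_cm = 4, height_cm = 4) {
  if (!is.character(stimulus_id) || length(stimulus_id) != 1L ||
      !nzchar(stimulus_id)) {
    stop("stimulus_id: must be a non-empty string", call. = FALSE)
  }
  category <- check_enum(category, .sdrst_categories, "category")
  valence <- check_enum(valence, .sdrst_valences, "valence")
  if (valence == "none" && category != "geometric") {
    stop(sprintf(
      "valence: 'none' is only permitted for geometric stimuli (stimulus %s has category %s)",
      sQuote(stimulus_id), sQuote(category)), call. = FALSE)
  }
  if (!is.numeric(width_cm) || width_cm <= 0 || !is.numeric(height_cm) ||
      height_cm <= 0) {
    stop("display_size_cm: width_cm and height_cm must be positive",
         call. = FALSE)
  }
  structure(
    list(stimulus_id = stimulus_id, category = category, valence = valence,
         display_size_cm = c(as.numeric(width_cm), as.numeric(height_cm))),
    class = "sdrst_stimulus")
}

#' Define the grid of candidate stimulus locations
#'
#' The default is the 4 x 4 evenly spaced grid on the unit square, giving
#' the task's 16 candidate locations. Positions are abstract 2-D
#' coordinates; hit testing is by location index, not geometry.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param positions optional `n_rows * n_cols` x 2 numeric matrix of
#'   pairwise-distinct coordinates; defaults to evenly spaced cell centres.
#' @return an object of class `sdrst_grid` with `n_rows`, `n_cols` and a
#'   `positions` matrix (one row per location index).
#' @examples
#' g <- grid_spec()           # the standard 16-location grid
#' nrow(g$positions)          # 16
#' @export
grid_spec <- function(n_rows = 4L, n_cols = 4L, positions = NULL) {
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  n_loc <- n_rows * n_cols
  if (is.null(positions)) {
    positions <- cbind(
      rep((seq_len(n_cols) - 0.5) / n_cols, times = n_rows),
      rep((seq_len(n_rows) - 0.5) / n_rows, each = n_cols))
  }
  positions <- matrix(as.numeric(positions), ncol = 2L,
                      dimnames = NULL)
  if (nrow(positions) != n_loc) {
    stop(sprintf("positions: need %d rows (n_rows * n_cols), got %d",
                 n_loc, nrow(positions)), call. = FALSE)
  }
  if (anyDuplicated(positions) > 0L) {
    stop("positions: cell positions must be pairwise distinct", call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, positions = positions),
            class = "sdrst_grid")
}

n_locations <- function(grid) nrow(grid$positions)

#' Build a full task configuration
#'
#' Collects every examiner-selectable parameter of the task: the stimulus
#' set, the unique/varied condition, stimulus choice policy, trial counts
#' (optionally per valence), the location grid, the exposure/delay/interval
#' timings, feedback mode, and the session RNG seed. Invalid combinations
#' are rejected with an error naming the offending field.
#'
#' Timing semantics: `interval_time_ms` paces successive stimulus onsets and
#' is the only behaviourally meaningful timing for the headless engine;
#' `exposure_time_ms` and `delay_time_ms` are stored and logged verbatim.
#'
#' @param stimulus_set list of [stimulus_spec()] objects (unique ids).
#' @param condition `"unique"` (all stimuli in a trial identical) or
#'   `"varied"` (all distinct). Varied requires at least `max_items`
#'   stimuli in the set.
#' @param stimulus_choice `"random"` (uniform draw from the valence-matching
#'   stimuli) or `"defined"` (listed order).
#' @param n_trials total number of trials; may be omitted when
#'   `trials_per_valence` is given (then it is the sum of the counts).
#' @param max_items span ceiling: the number of stimuli a trial grows to.
#'   Cannot exceed the number of grid locations.
#' @param grid a [grid_spec()]; defaults to the 16-location 4 x 4 grid.
#' @param exposure_time_ms,delay_time_ms,interval_time_ms non-negative
#'   integer millisecond timings.
#' @param background_color opaque string metadata.
#' @param feedback_mode `"none"`, `"auditory"` (correct -> acute tone,
#'   wrong -> bass tone) or `"auditory_plus_reward"` (correct additionally
#'   dispenses a food reward, as used with non-human primates).
#' @param trials_per_valence optional named integer vector (names from
#'   negative/positive/neutral/none) whose counts sum to `n_trials`. When
#'   omitted, trials are distributed as evenly as possible across the
#'   valences present in the stimulus set.
#' @param rng_seed integer seed determining trial order and every trial plan.
#' @return a validated object of class `sdrst_config`.
#' @examples
#' cfg <- task_config(
#'   stimulus_set = list(stimulus_spec("geometric_01")),
#'   condition = "unique", n_trials = 16, max_items = 8)
#' cfg$interval_time_ms
#' @export
task_config <- function(stimulus_set,
                        condition = "unique",
                        stimulus_choice = "random",
                        n_trials = NULL,
                        max_items = 8L,
                        grid = grid_spec(),
                        exposure_time_ms = 1000L,
                        delay_time_ms = 0L,
                        interval_time_ms = 1000L,
                        background_color = "white",
                        feedback_mode = "none",
                        trials_per_valence = NULL,
                        rng_seed = 1L) {
  if (!is.list(stimulus_set) || length(stimulus_set) == 0L) {
    stop("stimulus_set: must be a non-empty list of stimulus_spec objects",
         call. = FALSE)
  }
  stimulus_set <- lapply(stimulus_set, function(s) {
    if (!inherits(s, "sdrst_stimulus")) {
      s <- do.call(stimulus_spec, as_stimulus_args(s))
    }
    s
  })
  ids <- vapply(stimulus_set, `[[`, "", "stimulus_id")
  if (anyDuplicated(ids) > 0L) {
    stop("stimulus_set: stimulus_id values must be unique within the set",
         call. = FALSE)
  }
  condition <- check_enum(condition, .sdrst_conditions, "condition")
  stimulus_choice <- check_enum(stimulus_choice, .sdrst_choices,
                                "stimulus_choice")
  if (!inherits(grid, "sdrst_grid")) {
    stop("grid: must be a grid_spec object", call. = FALSE)
  }
  max_items <- check_count(max_items, "max_items")
  if (max_items > n_locations(grid)) {
    stop(sprintf(
      "max_items: cannot exceed the number of grid locations (%d > %d)",
      max_items, n_locations(grid)), call. = FALSE)
  }
  if (condition == "varied" && length(stimulus_set) < max_items) {
    stop(sprintf(
      "condition: 'varied' requires at least max_items = %d stimuli in stimulus_set (got %d)",
      max_items, length(stimulus_set)), call. = FALSE)
  }

  valences_present <- unique(vapply(stimulus_set, `[[`, "", "valence"))
  if (is.null(trials_per_valence)) {
    if (is.null(n_trials)) {
      stop("n_trials: supply n_trials or trials_per_valence", call. = FALSE)
    }
    n_trials <- check_count(n_trials, "n_trials")
    vals <- .sdrst_valences[.sdrst_valences %in% valences_present]
    base <- n_trials %/% length(vals)
    extra <- n_trials %% length(vals)
    counts <- rep(base, length(vals)) + (seq_along(vals) <= extra)
    trials_per_valence <- stats::setNames(as.integer(counts), vals)
    trials_per_valence <- trials_per_valence[trials_per_valence > 0L]
  } else {
    tv <- trials_per_valence
    if (is.list(tv)) tv <- unlist(tv)
    if (is.null(names(tv)) || any(!nzchar(names(tv)))) {
      stop("trials_per_valence: must be a named vector of counts",
           call. = FALSE)
    }
    bad <- setdiff(names(tv), .sdrst_valences)
    if (length(bad) > 0L) {
      stop(sprintf("trials_per_valence: unknown valence %s",
                   paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    }
    storage.mode(tv) <- "integer"
    if (anyNA(tv) || any(tv < 0L)) {
      stop("trials_per_valence: counts must be non-negative integers",
           call. = FALSE)
    }
    if (is.null(n_trials)) {
      n_trials <- sum(tv)
    } else {
      n_trials <- check_count(n_trials, "n_trials")
      if (sum(tv) != n_trials) {
        stop(sprintf(
          "trials_per_valence: counts sum to %d but n_trials = %d",
          sum(tv), n_trials), call. = FALSE)
      }
    }
    missing_val <- setdiff(names(tv)[tv > 0L], valences_present)
    if (length(missing_val) > 0L) {
      stop(sprintf(
        "trials_per_valence: no stimuli in stimulus_set with valence %s",
        paste(sQuote(missing_val), collapse = ", ")), call. = FALSE)
    }
    trials_per_valence <- tv
  }
  n_trials <- check_count(n_trials, "n_trials")

  structure(
    list(
      stimulus_set = stimulus_set,
      condition = condition,
      stimulus_choice = stimulus_choice,
      n_trials = n_trials,
      max_items = max_items,
      grid = grid,
      exposure_time_ms = check_count(exposure_time_ms, "exposure_time_ms", 0L),
      delay_time_ms = check_count(delay_time_ms, "delay_time_ms", 0L),
      interval_time_ms = check_count(interval_time_ms, "interval_time_ms", 0L),
      background_color = as.character(background_color)[1L],
      feedback_mode = check_enum(feedback_mode, .sdrst_feedback,
                                 "feedback_mode"),
      trials_per_valence = trials_per_valence,
      rng_seed = check_count(rng_seed, "rng_seed", 0L)),
    class = "sdrst_config")
}

# Accept a plain list (e.g. parsed JSON) describing one stimulus.
as_stimulus_args <- function(s) {
  list(stimulus_id = s$stimulus_id,
       category = s$category %||% "geometric",
       valence = s$valence %||% "none",
       width_cm = if (!is.null(s$display_size_cm)) s$display_size_cm[[1]] else 4,
       height_cm = if (!is.null(s$display_size_cm)) s$display_size_cm[[2]] else 4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sdrst_config <- function(x, ...) {
  cat(sprintf(
    "<sdrst_config> %d trials, %s condition, %d stimuli, %d locations, span ceiling %d\n",
    x$n_trials, x$condition, length(x$stimulus_set),
    n_locations(x$grid), x$max_items))
  cat(sprintf("  timings (ms): exposure %d, delay %d, interval %d; feedback: %s\n",
              x$exposure_time_ms, x$delay_time_ms, x$interval_time_ms,
              x$feedback_mode))
  cat("  trials per valence:",
      paste(sprintf("%s=%d", names(x$trials_per_valence),
                    x$trials_per_valence), collapse = ", "), "\n")
  invisible(x)
}

# canonical serializable list with fixed key order
config_to_list <- function(config) {
  list(
    condition = config$condition,
    stimulus_choice = config$stimulus_choice,
    n_trials = config$n_trials,
    max_items = config$max_items,
    exposure_time_ms = config$exposure_time_ms,
    delay_time_ms = config$delay_time_ms,
    interval_time_ms = config$interval_time_ms,
    background_color = config$background_color,
    feedback_mode = config$feedback_mode,
    rng_seed = config$rng_seed,
    trials_per_valence = as.list(config$trials_per_valence),
    grid = list(n_rows = config$grid$n_rows,
                n_cols = config$grid$n_cols,
                positions = lapply(seq_len(nrow(config$grid$positions)),
                                   function(i) config$grid$positions[i, ])),
    stimulus_set = lapply(config$stimulus_set, function(s) {
      list(stimulus_id = s$stimulus_id, category = s$category,
           valence = s$valence, display_size_cm = s$display_size_cm)
    }))
}

#' Serialize a task configuration to canonical JSON
#'
#' Keys are written in a fixed canonical order so that serialization is
#' byte-deterministic; [load_config()] of the output reproduces the
#' configuration exactly.
#'
#' @param config a valid `sdrst_config`.
#' @param path optional file path; when given the JSON is also written there.
#' @return the JSON text (invisibly when `path` is given).
#' @export
save_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "sdrst_config"))
  json <- as.character(jsonlite::toJSON(config_to_list(config),
                                        auto_unbox = TRUE, digits = I(17),
                                        pretty = TRUE))
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' Load a task configuration from JSON
#'
#' Accepts either a file path or JSON text. Defaults are filled and all
#' configuration invariants are re-validated; a violated invariant raises an
#' error naming the field.
#'
#' @param x path to a JSON file, or a length-1 character string of JSON.
#' @return a validated `sdrst_config`.
#' @export
load_config <- function(x) {
  if (length(x) == 1L && !grepl("^\\s*\\{", x)) {
    if (!file.exists(x)) stop(sprintf("config file not found: %s", x),
                              call. = FALSE)
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    x <- paste(x, collapse = "\n")
  }
  parsed <- tryCatch(jsonlite::fromJSON(x, simplifyVector = FALSE),
                     error = function(e) {
                       stop(sprintf("malformed JSON config: %s",
                                    conditionMessage(e)), call. = FALSE)
                     })
  grid <- if (is.null(parsed$grid)) grid_spec() else {
    pos <- parsed$grid$positions
    grid_spec(parsed$grid$n_rows %||% 4L, parsed$grid$n_cols %||% 4L,
              positions = if (is.null(pos)) NULL else
                do.call(rbind, lapply(pos, function(p) as.numeric(unlist(p)))))
  }
  tv <- parsed$trials_per_valence
  task_config(
    stimulus_set = lapply(parsed$stimulus_set, as_stimulus_args),
    condition = parsed$condition %||% "unique",
    stimulus_choice = parsed$stimulus_choice %||% "random",
    n_trials = parsed$n_trials,
    max_items = parsed$max_items %||% 8L,
    grid = grid,
    exposure_time_ms = parsed$exposure_time_ms %||% 1000L,
    delay_time_ms = parsed$delay_time_ms %||% 0L,
    interval_time_ms = parsed$interval_time_ms %||% 1000L,
    background_color = parsed$background_color %||% "white",
    feedback_mode = parsed$feedback_mode %||% "none",
    trials_per_valence = if (is.null(tv)) NULL else
      stats::setNames(as.integer(unlist(tv)), names(tv)),
    rng_seed = parsed$rng_seed %||% 1L)
}

make_stimuli <- function(prefix, category, valences, n_each = 8L) {
  out <- list()
  for (v in valences) {
    tag <- if (v == "none") prefix else paste(prefix, v, sep = "_")
    out <- c(out, lapply(seq_len(n_each), function(i) {
      stimulus_spec(sprintf("%s_%02d", tag, i), category, v)
    }))
  }
  out
}

#' Study presets
#'
#' The parameterizations of the three published studies:
#' \describe{
#'   \item{`study_a`}{IAPS scenes + geometric images, 16 trials per valence,
#'     5 s inter-stimulus interval, no feedback.}
#'   \item{`study_b`}{Facial expressions + geometric images, 10 trials per
#'     valence (40 trials in total), 3 s interval, auditory feedback
#'     (acute tone for correct, bass tone for wrong).}
#'   \item{`study_c`}{As study_a but with a 1 s interval.}
#' }
#' All use the 16-location grid with a span ceiling of 8 items. Each preset
#' is a single-condition configuration; the published studies administered
#' both conditions, so build one config per condition via the `condition`
#' argument.
#'
#' @param name `"study_a"`, `"study_b"` or `"study_c"`.
#' @param condition task condition for this configuration.
#' @param rng_seed session seed.
#' @return an `sdrst_config`.
#' @examples
#' sdrst_preset("study_b")$interval_time_ms   # 3000
#' sdrst_preset("study_b")$n_trials           # 40
#' @export
sdrst_preset <- function(name = c("study_a", "study_b", "study_c"),
                         condition = "unique", rng_seed = 1L) {
  name <- match.arg(name)
  geoms <- make_stimuli("geometric", "geometric", "none")
  emotional <- c("negative", "positive", "neutral")
  switch(
    name,
    study_a = task_config(
      stimulus_set = c(geoms, make_stimuli("iaps", "iaps_scene", emotional)),
      condition = condition,
      interval_time_ms = 5000L,
      trials_per_valence = c(negative = 16L, positive = 16L,
                             neutral = 16L, none = 16L),
      rng_seed = rng_seed),
    study_b = task_config(
      stimulus_set = c(geoms, make_stimuli("face", "face", emotional)),
      condition = condition,
      interval_time_ms = 3000L,
      feedback_mode = "auditory",
      trials_per_valence = c(negative = 10L, positive = 10L,
                             neutral = 10L, none = 10L),
      rng_seed = rng_seed),
    study_c = task_config(
      stimulus_set = c(geoms, make_stimuli("iaps", "iaps_scene", emotional)),
      condition = condition,
      interval_time_ms = 1000L,
      trials_per_valence = c(negative = 16L, positive = 16L,
                             neutral = 16L, none = 16L),
      rng_seed = rng_seed))
}
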