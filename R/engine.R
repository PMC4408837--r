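# Event-driven session state machine.
#
# A session pre-draws one constrained-random trial plan per trial from the
# config seed, then steps through an awaiting_response / trial_ended /
# session_ended state machine. At step k the first k items of the plan are
# on screen at their original locations; the k-th is the novel-location
# target. A correct touch advances to step k+1 (up to the span ceiling), a
# wrong touch ends the trial.
#
# The session state is an environment; event buffers are columnar and are
# mutated in place by evaluating pre-quoted expressions inside that
# environment (a plain `state$buf[i] <- v` would copy the buffer on every
# event, making long simulated sessions quadratic).

# Core plan draw, with the valence-matching stimulus pool precomputed by
# the caller. Assumes the RNG is already seeded for this trial.
plan_core <- function(config, trial_index, valence, pool, category) {
  m <- config$max_items
  locs <- sample.int(config$.n_locations, m)
  ids <- if (config$condition == "unique") {
    one <- if (config$stimulus_choice == "random") {
      pool[sample.int(length(pool), 1L)]
    } else pool[1L]
    rep(one, m)
  } else {
    if (length(pool) < m) {
      stop(sprintf(
        "varied condition needs %d distinct stimuli with valence %s, only %d available",
        m, sQuote(valence), length(pool)), call. = FALSE)
    }
    if (config$stimulus_choice == "random") {
      pool[sample.int(length(pool), m)]
    } else pool[seq_len(m)]
  }
  list(trial_index = as.integer(trial_index), stimulus_id = ids,
       location = locs, condition = config$condition, valence = valence,
       category = category)
}

stimulus_pool <- function(config, valence) {
  vals <- vapply(config$stimulus_set, `[[`, "", "valence")
  idx <- which(vals == valence)
  if (length(idx) == 0L) {
    stop(sprintf("no stimuli with valence %s in stimulus_set",
                 sQuote(valence)), call. = FALSE)
  }
  list(ids = vapply(config$stimulus_set[idx], `[[`, "", "stimulus_id"),
       category = config$stimulus_set[[idx[1L]]]$category)
}

#' Generate the constrained-random plan for one trial
#'
#' Locations are drawn uniformly without replacement from the grid, so all
#' `max_items` locations are pairwise distinct. Stimulus identities follow
#' the condition (`unique`: one identity repeated; `varied`: all distinct)
#' and the choice policy (`random`: uniform from the valence-matching
#' subset; `defined`: listed order). The plan for trial `i` depends only on
#' `(config$rng_seed, i)`, never on how many trials precede it.
#'
#' @param config a valid [task_config()].
#' @param trial_index 1-based trial index.
#' @param valence valence of this trial's stimuli; defaults to the first
#'   valence with a positive count in `config$trials_per_valence`.
#' @return an `sdrst_trial_plan`: ordered `stimulus_id` and `location`
#'   vectors of length `max_items`, plus `condition`, `valence`, `category`.
#' @export
generate_trial_plan <- function(config, trial_index, valence = NULL) {
  stopifnot(inherits(config, "sdrst_config"))
  if (is.null(valence)) {
    valence <- names(config$trials_per_valence)[config$trials_per_valence > 0L][1L]
  }
  pool <- stimulus_pool(config, valence)
  config$.n_locations <- n_locations(config$grid)
  plan <- with_rng_seed(derive_seed(config$rng_seed, 2L, trial_index),
                        plan_core(config, trial_index, valence, pool$ids,
                                  pool$category))
  class(plan) <- "sdrst_trial_plan"
  plan
}

# --- event buffers ---------------------------------------------------------

ev_init <- function(state) {
  cap <- 1024L
  state$ev_cap <- cap
  state$n_ev <- 0L
  state$ev_type <- character(cap)
  state$ev_trial <- rep(NA_integer_, cap)
  state$ev_step <- rep(NA_integer_, cap)
  state$ev_location <- rep(NA_integer_, cap)
  state$ev_correct <- rep(NA, cap)
  state$ev_ts <- rep(NA_real_, cap)
  state$ev_feedback <- rep(NA_character_, cap)
  state$ev_span <- rep(NA_integer_, cap)
  state$ev_ended_by <- rep(NA_character_, cap)
  state$ev_condition <- rep(NA_character_, cap)
  state$ev_valence <- rep(NA_character_, cap)
  state$ev_category <- rep(NA_character_, cap)
}

# Evaluated inside the session environment: appends one event row in place.
.ev_push_expr <- quote({
  .i <- n_ev + 1L
  if (.i > ev_cap) {
    ev_type <- c(ev_type, character(ev_cap))
    ev_trial <- c(ev_trial, rep(NA_integer_, ev_cap))
    ev_step <- c(ev_step, rep(NA_integer_, ev_cap))
    ev_location <- c(ev_location, rep(NA_integer_, ev_cap))
    ev_correct <- c(ev_correct, rep(NA, ev_cap))
    ev_ts <- c(ev_ts, rep(NA_real_, ev_cap))
    ev_feedback <- c(ev_feedback, rep(NA_character_, ev_cap))
    ev_span <- c(ev_span, rep(NA_integer_, ev_cap))
    ev_ended_by <- c(ev_ended_by, rep(NA_character_, ev_cap))
    ev_condition <- c(ev_condition, rep(NA_character_, ev_cap))
    ev_valence <- c(ev_valence, rep(NA_character_, ev_cap))
    ev_category <- c(ev_category, rep(NA_character_, ev_cap))
    ev_cap <- ev_cap * 2L
  }
  ev_type[.i] <- .a_type
  ev_trial[.i] <- .a_trial
  ev_step[.i] <- .a_step
  ev_location[.i] <- .a_location
  ev_correct[.i] <- .a_correct
  ev_ts[.i] <- .a_ts
  ev_feedback[.i] <- .a_feedback
  ev_span[.i] <- .a_span
  ev_ended_by[.i] <- .a_ended_by
  ev_condition[.i] <- .a_condition
  ev_valence[.i] <- .a_valence
  ev_category[.i] <- .a_category
  n_ev <- .i
})

ev_push <- function(state, type, trial = NA_integer_, step = NA_integer_,
                    location = NA_integer_, correct = NA, ts = NA_real_,
                    feedback = NA_character_, span = NA_integer_,
                    ended_by = NA_character_, condition = NA_character_,
                    valence = NA_character_, category = NA_character_) {
  state$.a_type <- type
  state$.a_trial <- trial
  state$.a_step <- step
  state$.a_location <- location
  state$.a_correct <- correct
  state$.a_ts <- ts
  state$.a_feedback <- feedback
  state$.a_span <- span
  state$.a_ended_by <- ended_by
  state$.a_condition <- condition
  state$.a_valence <- valence
  state$.a_category <- category
  eval(.ev_push_expr, state)
  invisible(state)
}

.span_set_expr <- quote({
  spans[.a_t] <- .a_sp
  ended_by[.a_t] <- .a_end
})

# --- state machine ---------------------------------------------------------

present_step <- function(state) {
  onset <- state$clock_ms + state$config$interval_time_ms
  state$clock_ms <- onset
  state$display_onset <- onset
  if (state$record) {
    ev_push(state, "display", trial = state$current_trial,
            step = state$current_step,
            location = state$plans[[state$current_trial]]$location[state$current_step],
            ts = onset)
  }
  invisible(state)
}

#' Start a task session
#'
#' Pre-draws every trial plan from `config$rng_seed`, shuffles the valence
#' sequence deterministically from the same seed, and enters
#' `awaiting_response` at trial 1, step 1. The returned session is an
#' environment updated in place by [apply_response()] and [advance_trial()].
#'
#' @param config a valid [task_config()].
#' @param record `"events"` (default) keeps the full timestamped event log;
#'   `"spans"` records only per-trial spans, for large simulations.
#' @return an `sdrst_session` environment with fields `phase`,
#'   `current_trial`, `current_step`, `plans`, `spans`.
#' @examples
#' s <- start_session(sdrst_preset("study_b"))
#' s$phase
#' length(s$plans)   # 40 planned trials
#' @export
start_session <- function(config, record = c("events", "spans")) {
  stopifnot(inherits(config, "sdrst_config"))
  record <- match.arg(record)
  state <- new.env(parent = baseenv())
  state$config <- config
  tv <- config$trials_per_valence
  valseq <- rep(names(tv), times = tv)
  state$valence_seq <- with_rng_seed(derive_seed(config$rng_seed, 1L, 0L),
                                     sample(valseq))
  n <- config$n_trials
  state$n_trials <- n

  vals_used <- unique(state$valence_seq)
  pools <- lapply(vals_used, function(v) stimulus_pool(config, v))
  names(pools) <- vals_used
  config$.n_locations <- n_locations(config$grid)
  state$plans <- with_rng_seed(0L, lapply(seq_len(n), function(i) {
    v <- state$valence_seq[i]
    set.seed(derive_seed(config$rng_seed, 2L, i))
    plan_core(config, i, v, pools[[v]]$ids, pools[[v]]$category)
  }))

  state$current_trial <- 1L
  state$current_step <- 1L
  state$phase <- "awaiting_response"
  state$clock_ms <- 0
  state$spans <- integer(n)
  state$ended_by <- character(n)
  state$record <- record == "events"
  if (state$record) ev_init(state)
  class(state) <- "sdrst_session"
  present_step(state)
  state
}

#' @export
print.sdrst_session <- function(x, ...) {
  cat(sprintf("<sdrst_session> trial %d/%d, step %d, phase: %s\n",
              x$current_trial, x$n_trials, x$current_step, x$phase))
  invisible(x)
}

#' What is currently on screen
#'
#' At step k the display holds the first k planned items at their original
#' locations; the target is the k-th (newest) item's location. Pure:
#' repeated calls without an intervening response return the same display.
#'
#' @param state an `sdrst_session` in phase `awaiting_response`.
#' @return an `sdrst_display`: `step`, `stimulus_id`, `location` (both
#'   length `step`), `target_location`, `onset_ms`.
#' @export
current_display <- function(state) {
  if (state$phase != "awaiting_response") {
    stop(sprintf("current_display: session phase is '%s', not 'awaiting_response'",
                 state$phase), call. = FALSE)
  }
  plan <- state$plans[[state$current_trial]]
  k <- state$current_step
  idx <- seq_len(k)
  structure(
    list(step = k,
         stimulus_id = plan$stimulus_id[idx],
         location = plan$location[idx],
         target_location = plan$location[k],
         onset_ms = state$display_onset),
    class = "sdrst_display")
}

#' Construct a response event
#'
#' @param chosen_location touched location index.
#' @param timestamp_ms event time in ms; defaults to the current display
#'   onset (zero latency).
#' @return a list usable with [apply_response()].
#' @export
response_event <- function(chosen_location, timestamp_ms = NULL) {
  list(chosen_location = as.integer(chosen_location),
       timestamp_ms = timestamp_ms)
}

feedback_kind <- function(mode, correct) {
  switch(mode,
         none = "none",
         auditory = if (correct) "correct_tone" else "wrong_tone",
         auditory_plus_reward = if (correct) "reward" else "wrong_tone")
}

#' Apply a touch response to the session
#'
#' A touch on the target (novel) location is correct and advances the trial
#' to the next step, or ends it at the ceiling once all `max_items` steps
#' are answered. A touch on any other visible location is a mistake and
#' ends the trial immediately. A touch on a location that is not on screen
#' is an invalid response: it is logged, the state is unchanged, and an
#' error of class `sdrst_invalid_response` is raised.
#'
#' @param state an `sdrst_session` in phase `awaiting_response`.
#' @param response a [response_event()] or a bare location index.
#' @return (invisibly) `list(state, correct, feedback)`; `feedback` is one
#'   of `"none"`, `"correct_tone"`, `"wrong_tone"`, `"reward"` per the
#'   config's feedback mode.
#' @export
apply_response <- function(state, response) {
  if (state$phase != "awaiting_response") {
    stop(sprintf("apply_response: session phase is '%s', not 'awaiting_response'",
                 state$phase), call. = FALSE)
  }
  if (!is.list(response)) response <- response_event(response)
  loc <- as.integer(response$chosen_location)
  plan <- state$plans[[state$current_trial]]
  k <- state$current_step
  ts <- response$timestamp_ms
  ts <- if (is.null(ts)) state$clock_ms else max(as.numeric(ts), state$clock_ms)
  if (!any(plan$location[seq_len(k)] == loc)) {
    if (state$record) {
      ev_push(state, "invalid_response", trial = state$current_trial,
              step = k, location = loc, ts = ts)
    }
    stop(structure(
      class = c("sdrst_invalid_response", "error", "condition"),
      list(message = sprintf(
        "invalid response: location %d is not on screen (trial %d, step %d)",
        loc, state$current_trial, k),
        call = sys.call())))
  }
  state$clock_ms <- ts
  correct <- loc == plan$location[k]
  fb <- feedback_kind(state$config$feedback_mode, correct)
  if (state$record) {
    ev_push(state, "response", trial = state$current_trial, step = k,
            location = loc, correct = correct, ts = ts)
    if (fb != "none") {
      ev_push(state, "feedback", trial = state$current_trial, step = k,
              feedback = fb, ts = ts)
    }
  }
  if (correct && k < state$config$max_items) {
    state$current_step <- k + 1L
    present_step(state)
  } else {
    span <- if (correct) k else k - 1L
    end_trial(state, span, if (correct) "ceiling" else "mistake")
  }
  invisible(list(state = state, correct = correct, feedback = fb))
}

end_trial <- function(state, span, ended_by) {
  t <- state$current_trial
  state$.a_t <- t
  state$.a_sp <- span
  state$.a_end <- ended_by
  eval(.span_set_expr, state)
  state$phase <- "trial_ended"
  if (state$record) {
    plan <- state$plans[[t]]
    ev_push(state, "trial_end", trial = t, ts = state$clock_ms,
            span = span, ended_by = ended_by, condition = plan$condition,
            valence = plan$valence, category = plan$category)
  }
  invisible(state)
}

#' Move on to the next trial
#'
#' @param state an `sdrst_session` in phase `trial_ended`.
#' @return (invisibly) the session, now at the next trial's step 1 in
#'   `awaiting_response`, or in `session_ended` after the last trial.
#' @export
advance_trial <- function(state) {
  if (state$phase != "trial_ended") {
    stop(sprintf("advance_trial: session phase is '%s', not 'trial_ended'",
                 state$phase), call. = FALSE)
  }
  if (state$current_trial >= state$n_trials) {
    state$phase <- "session_ended"
    if (state$record) ev_push(state, "session_end", ts = state$clock_ms)
  } else {
    state$current_trial <- state$current_trial + 1L
    state$current_step <- 1L
    state$phase <- "awaiting_response"
    present_step(state)
  }
  invisible(state)
}

#' Run a full session with a simulated participant
#'
#' Feeds the agent each display, applies its chosen location with a
#' synthetic response latency, and advances trials until the session ends.
#' The pair `(config$rng_seed, agent_seed)` fully determines the resulting
#' log.
#'
#' @param config a valid [task_config()].
#' @param agent an agent from [agent_random()], [agent_capacity()] or
#'   [agent_perfect()].
#' @param agent_seed integer seed for the agent's choices and latencies.
#' @param record see [start_session()].
#' @return an `sdrst_log` (see [session_log()]).
#' @examples
#' log <- run_with_agent(sdrst_preset("study_b"), agent_perfect(), 1)
#' summarize_session(log)$overall$mean_span   # 8: perfect responder
#' @export
run_with_agent <- function(config, agent, agent_seed = 1L,
                           record = c("events", "spans")) {
  stopifnot(inherits(agent, "sdrst_agent"))
  state <- start_session(config, record = match.arg(record))
  choose <- agent$choose
  latency <- agent$latency
  with_rng_seed(as.integer(agent_seed), {
    mem <- agent$init(config)
    while (state$phase != "session_ended") {
      if (state$phase == "trial_ended") {
        mem <- agent$reset(mem)
        advance_trial(state)
        next
      }
      d <- current_display(state)
      ch <- choose(d, mem)
      mem <- ch$state
      apply_response(state, list(chosen_location = ch$location,
                                 timestamp_ms = d$onset_ms + latency()))
    }
  })
  session_log(state, agent = agent)
}
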