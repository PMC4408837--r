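# Simulated participants.
#
# Two models make the task testable end-to-end: a uniform-random chance
# agent, whose mean span has the closed form sum_{k=1}^{K} 1/k!, and a
# capacity-limited agent that remembers the m most recent old locations and
# lapses (responds uniformly at random) with probability epsilon. The
# capacity agent is a parametric stand-in for working-memory load, not a
# fitted model of any participant group.

# Lognormal latency generator moment-matched to a target mean/sd, floored
# at 1 ms so latencies are strictly positive.
make_latency <- function(mean_ms, sd_ms) {
  if (mean_ms < 0 || sd_ms < 0) {
    stop("rt_model: rt_mean_ms and rt_sd_ms must be non-negative",
         call. = FALSE)
  }
  if (mean_ms <= 0 || sd_ms == 0) {
    fixed <- max(1, round(mean_ms))
    return(function() fixed)
  }
  sigma2 <- log(1 + (sd_ms / mean_ms)^2)
  mu <- log(mean_ms) - sigma2 / 2
  sdlog <- sqrt(sigma2)
  function() max(1, round(stats::rlnorm(1L, mu, sdlog)))
}

new_agent <- function(name, params, init, choose, reset, latency) {
  structure(list(name = name, params = params, init = init, choose = choose,
                 reset = reset, latency = latency),
            class = "sdrst_agent")
}

#' @export
print.sdrst_agent <- function(x, ...) {
  p <- paste(sprintf("%s=%s", names(x$params), unlist(x$params)),
             collapse = ", ")
  cat(sprintf("<sdrst_agent> %s(%s)\n", x$name, p))
  invisible(x)
}

#' Chance-level agent
#'
#' Touches one of the currently visible stimuli uniformly at random. Its
#' mean span is the task's chance level, [expected_random_span()].
#'
#' @param rt_mean_ms,rt_sd_ms mean and sd of the synthetic lognormal
#'   response latency (ms).
#' @return an `sdrst_agent`.
#' @export
agent_random <- function(rt_mean_ms = 1000, rt_sd_ms = 300) {
  new_agent(
    "random",
    list(rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms),
    init = function(config) NULL,
    choose = function(display, state) {
      list(location = display$location[sample.int(display$step, 1L)],
           state = state)
    },
    reset = function(state) state,
    latency = make_latency(rt_mean_ms, rt_sd_ms))
}

#' Perfect agent
#'
#' Always touches the novel-location target; reaches the span ceiling on
#' every trial.
#'
#' @inheritParams agent_random
#' @return an `sdrst_agent`.
#' @export
agent_perfect <- function(rt_mean_ms = 1000, rt_sd_ms = 300) {
  new_agent(
    "perfect", list(rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms),
    init = function(config) NULL,
    choose = function(display, state) {
      list(location = display$target_location, state = state)
    },
    reset = function(state) state,
    latency = make_latency(rt_mean_ms, rt_sd_ms))
}

#' Capacity-limited working-memory agent
#'
#' Remembers at most `m` old locations (FIFO: oldest forgotten first),
#' updated with the TRUE target location after every step — the task's
#' corrective structure reveals the answer, so memory tracks the truth
#' regardless of the agent's own choice. With probability `epsilon` the
#' agent lapses and touches uniformly at random over everything visible;
#' otherwise it touches uniformly at random among the visible locations it
#' does NOT remember (the target always being among them).
#'
#' Limits: `m = 0, epsilon = 0` reproduces [agent_random()] exactly;
#' `m >= max_items - 1, epsilon = 0` reproduces [agent_perfect()]'s span.
#'
#' @param m non-negative integer memory capacity (old locations retained).
#' @param epsilon lapse probability in `[0, 1]`.
#' @inheritParams agent_random
#' @return an `sdrst_agent`.
#' @export
agent_capacity <- function(m, epsilon = 0, rt_mean_ms = 1000,
                           rt_sd_ms = 300) {
  m <- as.integer(m)
  if (is.na(m) || m < 0L) stop("m: capacity must be a non-negative integer",
                               call. = FALSE)
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon: lapse rate must lie in [0, 1]", call. = FALSE)
  }
  new_agent(
    "capacity",
    list(m = m, epsilon = epsilon, rt_mean_ms = rt_mean_ms,
         rt_sd_ms = rt_sd_ms),
    init = function(config) integer(0),
    choose = function(display, mem) {
      vis <- display$location
      loc <- if (epsilon > 0 && stats::runif(1L) < epsilon) {
        vis[sample.int(length(vis), 1L)]
      } else {
        cand <- vis[!(vis %in% mem)]
        cand[sample.int(length(cand), 1L)]
      }
      mem <- c(mem, display$target_location)
      extra <- length(mem) - m
      if (extra > 0L) mem <- mem[-seq_len(extra)]
      list(location = loc, state = mem)
    },
    reset = function(mem) integer(0),
    latency = make_latency(rt_mean_ms, rt_sd_ms))
}

#' Chance level of the span measure
#'
#' Expected span of a responder touching uniformly among the visible
#' stimuli. At step k there are k stimuli on screen and one target, so the
#' probability of surviving steps 1..k is 1/k!, and
#' `E[span] = sum_{k=1}^{max_items} 1/k!` — approximately `e - 1` (1.71828)
#' already at a ceiling of 8 items.
#'
#' @param max_items span ceiling (>= 1).
#' @return the expected chance span.
#' @examples
#' expected_random_span(2)   # 1.5
#' expected_random_span(8)   # 1.718279
#' @export
expected_random_span <- function(max_items) {
  max_items <- as.integer(max_items)
  if (is.na(max_items) || max_items < 1L) {
    stop("max_items: must be an integer >= 1", call. = FALSE)
  }
  sum(1 / factorial(seq_len(max_items)))
}

#' Exact expected span of the capacity agent
#'
#' Closed-form enumeration over step outcomes. Along the all-correct path
#' the agent's memory at step k holds the `min(m, k - 1)` most recent old
#' locations (all true old targets), so the per-step probability of a
#' correct touch is
#' `p_k = epsilon / k + (1 - epsilon) / (k - min(m, k - 1))`
#' and `E[span] = sum_k prod_{j<=k} p_j`.
#'
#' @inheritParams expected_random_span
#' @param m memory capacity.
#' @param epsilon lapse probability.
#' @return the exact expected span.
#' @examples
#' expected_capacity_span(8, m = 0)   # chance level, 1.718279
#' expected_capacity_span(8, m = 7)   # 8: perfect memory
#' @export
expected_capacity_span <- function(max_items, m, epsilon = 0) {
  max_items <- as.integer(max_items)
  if (is.na(max_items) || max_items < 1L) {
    stop("max_items: must be an integer >= 1", call. = FALSE)
  }
  if (m < 0) stop("m: capacity must be non-negative", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) {
    stop("epsilon: lapse rate must lie in [0, 1]", call. = FALSE)
  }
  k <- seq_len(max_items)
  p <- epsilon / k + (1 - epsilon) / (k - pmin(m, k - 1))
  sum(cumprod(p))
}
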