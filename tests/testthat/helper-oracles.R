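# Independent oracles used to cross-check the implementation. These are
# deliberately written without touching the engine or the closed-form
# functions they validate.

# Exact expected span of the capacity-limited responder: recursive
# enumeration of correct/incorrect branches, tracking the explicit set of
# remembered step indices (FIFO eviction), with exact probabilities.
enum_capacity_span <- function(max_items, m, eps) {
  rec <- function(k, mem) {
    if (k > max_items) return(0)
    n_vis <- k
    n_cand <- n_vis - length(mem)  # the novel target is never remembered
    p <- eps / n_vis + (1 - eps) / n_cand
    mem2 <- c(mem, k)
    if (length(mem2) > m) mem2 <- mem2[-seq_len(length(mem2) - m)]
    p * (1 + rec(k + 1, mem2))
  }
  rec(1, integer(0))
}

# Engine-free Monte-Carlo simulation of the abstract task process: draws
# concrete location sequences and plays the memory model forward.
mc_capacity_span <- function(n_trials, max_items, m, eps,
                             n_locations = 16L) {
  spans <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    locs <- sample.int(n_locations, max_items)
    mem <- integer(0)
    span <- 0L
    for (k in seq_len(max_items)) {
      visible <- locs[seq_len(k)]
      target <- locs[k]
      pick <- if (eps > 0 && runif(1) < eps) {
        visible[sample.int(k, 1L)]
      } else {
        cand <- setdiff(visible, mem)
        cand[sample.int(length(cand), 1L)]
      }
      mem <- c(mem, target)
      if (length(mem) > m) mem <- mem[-1L]
      if (pick != target) break
      span <- span + 1L
    }
    spans[i] <- span
  }
  spans
}

# Brute-force span: scan for the first wrong response.
bf_span <- function(correct) {
  s <- 0L
  for (ok in correct) {
    if (!ok) break
    s <- s + 1L
  }
  s
}

# A randomized valid configuration (assumes the caller seeded the RNG).
random_config <- function() {
  n_rows <- sample(2:5, 1L)
  n_cols <- sample(2:5, 1L)
  n_loc <- n_rows * n_cols
  max_items <- sample(2:min(8L, n_loc), 1L)
  n_none <- max_items + sample(0:3, 1L)
  n_neg <- max_items + sample(0:3, 1L)
  stim <- c(
    lapply(seq_len(n_none), function(i) {
      stimulus_spec(sprintf("geo_%02d", i), "geometric", "none")
    }),
    lapply(seq_len(n_neg), function(i) {
      stimulus_spec(sprintf("scene_neg_%02d", i), "iaps_scene", "negative")
    }))
  task_config(
    stimulus_set = stim,
    condition = sample(c("unique", "varied"), 1L),
    stimulus_choice = sample(c("random", "defined"), 1L),
    max_items = max_items,
    grid = grid_spec(n_rows, n_cols),
    interval_time_ms = sample(c(0L, 500L, 1000L, 3000L), 1L),
    feedback_mode = sample(c("none", "auditory", "auditory_plus_reward"), 1L),
    trials_per_valence = c(none = sample(1:4, 1L),
                           negative = sample(1:4, 1L)),
    rng_seed = sample.int(.Machine$integer.max, 1L))
}

# Play a scripted sequence of span outcomes through a session: for each
# trial, answer correctly `span` times, then (if below the ceiling) touch
# the oldest on-screen location to force a mistake.
play_spans <- function(state, spans) {
  for (sp in spans) {
    plan <- state$plans[[state$current_trial]]
    max_items <- state$config$max_items
    for (k in seq_len(sp)) apply_response(state, plan$location[k])
    if (sp < max_items) apply_response(state, plan$location[1L])
    advance_trial(state)
  }
  state
}
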