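# Trial generation and the session state machine.

geo_set <- function(n = 8L, prefix = "geo") {
  lapply(seq_len(n), function(i) {
    stimulus_spec(sprintf("%s_%02d", prefix, i))
  })
}

simple_config <- function(n_trials = 4L, max_items = 8L, seed = 1L, ...) {
  task_config(stimulus_set = geo_set(), n_trials = n_trials,
              max_items = max_items, rng_seed = seed, ...)
}

test_that("trial plans satisfy the location and identity constraints", {
  set.seed(99)
  for (i in 1:200) {
    cfg <- random_config()
    plan <- generate_trial_plan(cfg, sample.int(50, 1L),
                                sample(names(cfg$trials_per_valence), 1L))
    expect_length(plan$location, cfg$max_items)
    expect_equal(anyDuplicated(plan$location), 0L)
    expect_true(all(plan$location >= 1L &
                      plan$location <= nrow(cfg$grid$positions)))
    if (cfg$condition == "unique") {
      expect_length(unique(plan$stimulus_id), 1L)
    } else {
      expect_equal(anyDuplicated(plan$stimulus_id), 0L)
    }
    valences <- vapply(cfg$stimulus_set, `[[`, "", "valence")
    ids <- vapply(cfg$stimulus_set, `[[`, "", "stimulus_id")
    expect_true(all(plan$stimulus_id %in% ids[valences == plan$valence]))
  }
})

test_that("plan generation is deterministic and per-trial independent", {
  cfg <- simple_config(seed = 7L)
  p1 <- generate_trial_plan(cfg, 3L, "none")
  p2 <- generate_trial_plan(cfg, 3L, "none")
  expect_identical(p1, p2)
  # plan for trial i does not depend on surrounding trials
  s_small <- start_session(simple_config(n_trials = 3L, seed = 7L))
  s_large <- start_session(simple_config(n_trials = 10L, seed = 7L))
  expect_identical(s_small$plans[[2]]$location, s_large$plans[[2]]$location)
  expect_error(generate_trial_plan(cfg, 1L, "positive"), "positive")
})

test_that("sessions plan the configured number of trials per valence", {
  s <- start_session(sdrst_preset("study_b"))
  expect_length(s$plans, 40L)
  expect_equal(table(s$valence_seq)[c("negative", "positive", "neutral",
                                      "none")],
               table(factor(rep(c("negative", "positive", "neutral", "none"),
                                each = 10L)))[c("negative", "positive",
                                                "neutral", "none")])
  # a single-valence restriction of study a plans 16 trials
  a <- sdrst_preset("study_a")
  a16 <- task_config(stimulus_set = a$stimulus_set,
                     trials_per_valence = c(negative = 16L),
                     interval_time_ms = a$interval_time_ms)
  expect_length(start_session(a16)$plans, 16L)
  # identical configs give identical session plans
  s2 <- start_session(sdrst_preset("study_b"))
  expect_identical(s$plans, s2$plans)
  expect_identical(s$valence_seq, s2$valence_seq)
})

test_that("the display shows the first k items and targets the newest", {
  s <- start_session(simple_config())
  d1 <- current_display(s)
  expect_equal(d1$step, 1L)
  expect_length(d1$location, 1L)
  expect_equal(d1$target_location, d1$location)
  expect_identical(current_display(s), d1)  # pure

  plan <- s$plans[[1]]
  apply_response(s, plan$location[1])
  apply_response(s, plan$location[2])
  d3 <- current_display(s)
  expect_equal(d3$step, 3L)
  expect_identical(d3$location[1:2], plan$location[1:2])
  expect_identical(d3$stimulus_id[1:2], plan$stimulus_id[1:2])
  expect_equal(d3$target_location, plan$location[3])
})

test_that("earlier items persist at their original locations at every step", {
  set.seed(11)
  for (rep in 1:20) {
    cfg <- random_config()
    s <- start_session(cfg)
    prev <- NULL
    while (s$phase == "awaiting_response") {
      d <- current_display(s)
      if (!is.null(prev)) {
        expect_identical(d$location[seq_len(prev$step)], prev$location)
        expect_identical(d$stimulus_id[seq_len(prev$step)], prev$stimulus_id)
      }
      prev <- d
      apply_response(s, d$target_location)
    }
    expect_equal(s$spans[1], cfg$max_items)
  }
})

test_that("a wrong touch ends the trial; the ceiling ends it as 'ceiling'", {
  s <- start_session(simple_config())
  plan <- s$plans[[1]]
  r <- apply_response(s, plan$location[1])   # forced first touch
  expect_true(r$correct)
  apply_response(s, plan$location[2])
  r <- apply_response(s, plan$location[1])   # old location: mistake
  expect_false(r$correct)
  expect_equal(s$phase, "trial_ended")
  expect_equal(s$spans[1], 2L)
  expect_equal(s$ended_by[1], "mistake")

  advance_trial(s)
  plan2 <- s$plans[[2]]
  for (k in 1:8) apply_response(s, plan2$location[k])
  expect_equal(s$phase, "trial_ended")
  expect_equal(s$spans[2], 8L)
  expect_equal(s$ended_by[2], "ceiling")
})

test_that("invalid touches are logged and leave the state unchanged", {
  cfg <- simple_config(max_items = 4L)
  s <- start_session(cfg)
  visible <- current_display(s)$location
  outside <- setdiff(seq_len(16L), visible)[1]
  before <- list(s$current_trial, s$current_step, s$phase)
  expect_error(apply_response(s, outside),
               class = "sdrst_invalid_response")
  expect_identical(list(s$current_trial, s$current_step, s$phase), before)
  log <- session_log(s)
  expect_true("invalid_response" %in% log$events$type)
})

test_that("phase preconditions are enforced", {
  s <- start_session(simple_config(n_trials = 1L, max_items = 2L))
  expect_error(advance_trial(s), "phase")
  plan <- s$plans[[1]]
  apply_response(s, plan$location[1])
  apply_response(s, plan$location[2])
  expect_error(current_display(s), "phase")
  expect_error(apply_response(s, plan$location[1]), "phase")
  advance_trial(s)
  expect_equal(s$phase, "session_ended")
  expect_error(advance_trial(s), "phase")
})

test_that("advance_trial moves to the next trial at step 1", {
  s <- start_session(sdrst_preset("study_b"))
  plan <- s$plans[[1]]
  apply_response(s, plan$location[1])
  apply_response(s, plan$location[1])  # wrong at step 2
  advance_trial(s)
  expect_equal(s$current_trial, 2L)
  expect_equal(s$current_step, 1L)
  expect_equal(s$phase, "awaiting_response")
})

test_that("feedback events follow the feedback mode", {
  run_two <- function(mode) {
    s <- start_session(simple_config(n_trials = 1L, feedback_mode = mode))
    plan <- s$plans[[1]]
    apply_response(s, plan$location[1])
    r <- apply_response(s, plan$location[1])  # mistake at step 2
    list(state = s, last = r$feedback)
  }
  none <- run_two("none")
  expect_equal(none$last, "none")
  expect_false("feedback" %in% session_log(none$state)$events$type)

  aud <- run_two("auditory")
  fb <- session_log(aud$state)$events
  fb <- fb$feedback[fb$type == "feedback"]
  expect_equal(fb, c("correct_tone", "wrong_tone"))

  rew <- run_two("auditory_plus_reward")
  fb <- session_log(rew$state)$events
  fb <- fb$feedback[fb$type == "feedback"]
  expect_equal(fb, c("reward", "wrong_tone"))
})

test_that("a perfect responder reaches the ceiling on every trial", {
  log <- run_with_agent(sdrst_preset("study_b"), agent_perfect(), 5L)
  expect_equal(nrow(log$trials), 40L)
  expect_true(all(log$trials$span == 8L))
  expect_true(all(log$trials$ended_by == "ceiling"))
})

test_that("timestamps are monotone and paced by the interval time", {
  cfg <- simple_config(n_trials = 3L, interval_time_ms = 3000L)
  log <- run_with_agent(cfg, agent_random(), 2L)
  ts <- log$events$timestamp_ms
  expect_true(all(diff(ts) >= 0))
  disp <- log$events[log$events$type == "display", ]
  first <- disp$timestamp_ms[disp$trial == 1 & disp$step == 1]
  expect_equal(first, 3000)
})

test_that("identical seeds reproduce the session log exactly", {
  cfg <- sdrst_preset("study_b", rng_seed = 42L)
  l1 <- run_with_agent(cfg, agent_capacity(3, 0.1), 77L)
  l2 <- run_with_agent(cfg, agent_capacity(3, 0.1), 77L)
  expect_identical(l1$events, l2$events)
  expect_identical(l1$trials, l2$trials)
  l3 <- run_with_agent(cfg, agent_capacity(3, 0.1), 78L)
  expect_false(identical(l1$events, l3$events))
})

test_that("every session terminates under any agent", {
  set.seed(4)
  for (i in 1:10) {
    cfg <- random_config()
    agent <- list(agent_random(), agent_perfect(),
                  agent_capacity(2, 0.2))[[sample.int(3, 1)]]
    log <- run_with_agent(cfg, agent, i)
    expect_true(isTRUE(log$header$complete))
    expect_equal(nrow(log$trials), cfg$n_trials)
  }
})
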