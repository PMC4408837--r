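# Cohort simulation, group tables, bootstrap contrasts.

cohort_config <- function(n_trials = 8L, condition = "unique",
                          seed = 1L) {
  stim <- c(lapply(1:8, function(i) {
    stimulus_spec(sprintf("geo_%02d", i))
  }),
  lapply(1:8, function(i) {
    stimulus_spec(sprintf("scene_neg_%02d", i), "iaps_scene", "negative")
  }))
  task_config(stimulus_set = stim, condition = condition,
              n_trials = n_trials, rng_seed = seed,
              trials_per_valence = c(none = n_trials / 2,
                                     negative = n_trials / 2))
}

test_that("a perfect-memory cohort scores the ceiling in every cell", {
  spec <- cohort_spec("ceiling", n_subjects = 5L, config = cohort_config(),
                      m_mean = 10, m_sd = 0, seed = 2L)
  res <- simulate_cohort(spec)
  expect_true(all(res$cells$mean_span == 8))
  expect_true(all(res$subjects$mean_span == 8))
})

test_that("a single-subject cohort equals that subject's summary", {
  spec <- cohort_spec("solo", n_subjects = 1L, config = cohort_config(),
                      m_mean = 2, epsilon_mean = 0.1, seed = 3L)
  res <- simulate_cohort(spec)
  expect_equal(mean(res$subjects$mean_span),
               res$summaries[[1]]$overall$mean_span)
  expect_equal(res$cells$mean_span, res$summaries[[1]]$cells$mean_span)
})

test_that("cohorts are deterministic given their seed", {
  spec <- cohort_spec("rep", n_subjects = 3L, config = cohort_config(),
                      m_mean = 3, m_sd = 1, epsilon_mean = 0.1,
                      epsilon_sd = 0.05, seed = 11L)
  r1 <- simulate_cohort(spec)
  r2 <- simulate_cohort(spec)
  expect_identical(r1$subjects, r2$subjects)
  expect_identical(r1$cells, r2$cells)
})

test_that("higher-capacity cohorts outscore lower-capacity ones", {
  for (seed in 1:3) {
    hi <- simulate_cohort(cohort_spec(
      "hi", 5L, cohort_config(seed = seed), m_mean = 5, m_sd = 1,
      epsilon_mean = 0.05, seed = seed))
    lo <- simulate_cohort(cohort_spec(
      "lo", 5L, cohort_config(seed = seed), m_mean = 2, m_sd = 1,
      epsilon_mean = 0.05, seed = seed + 50L))
    expect_gt(mean(hi$subjects$mean_span), mean(lo$subjects$mean_span))
  }
})

test_that("simulated cohorts recover their generative mean span", {
  spec <- cohort_spec("recov", n_subjects = 6L,
                      config = cohort_config(n_trials = 16L),
                      m_mean = 2, m_sd = 0, seed = 21L)
  res <- simulate_cohort(spec)
  expected <- expected_capacity_span(8, 2, 0)
  all_trials <- unlist(lapply(seq_len(6), function(i) {
    res$summaries[[i]]$overall$mean_span
  }))
  se <- sd(all_trials) / sqrt(length(all_trials))
  expect_lt(abs(mean(all_trials) - expected), 3 * se)
})

test_that("the group table has the published M (SD) layout", {
  uni <- simulate_cohort(cohort_spec(
    "ceiling", 3L, cohort_config(condition = "unique"),
    m_mean = 10, seed = 4L))
  var <- simulate_cohort(cohort_spec(
    "varied_only", 3L, cohort_config(condition = "varied"),
    m_mean = 10, seed = 5L))
  tab <- cohort_table(list(uni, var))
  expect_equal(tab$group, c("ceiling", "varied_only"))
  expect_true(any(grepl("unique", names(tab))))
  expect_true(any(grepl("varied", names(tab))))
  # cells a cohort did not run render as "-"
  expect_true(all(tab[1, grepl("varied", names(tab))] == "-"))
  expect_true(all(tab[2, grepl("unique", names(tab))] == "-"))
  # ceiling cohort shows 8.00 (0.00) in its cells
  expect_true(all(tab[1, grepl("unique", names(tab))] == "8.00 (0.00)"))
})

test_that("bootstrap contrasts are exact for identical cohorts and cover the estimate", {
  spec <- cohort_spec("same", 6L, cohort_config(), m_mean = 3, m_sd = 1,
                      seed = 9L)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  d <- bootstrap_group_diff(a, b, "geometric", "unique", "none",
                            n_boot = 500L, seed = 1L)
  expect_equal(d$estimate, 0)
  expect_true(d$ci[1] <= d$estimate && d$estimate <= d$ci[2])
  d2 <- bootstrap_group_diff(a, b, "geometric", "unique", "none",
                             n_boot = 500L, seed = 1L)
  expect_identical(d$ci, d2$ci)  # deterministic given seed
  expect_error(
    bootstrap_group_diff(a, b, "face", "unique", "neutral", seed = 1L),
    "missing")
  expect_error(
    bootstrap_group_diff(a, b, "geometric", "unique", "none",
                         n_boot = 10L, seed = 1L),
    "n_boot")
})

test_that("perfect vs chance cohorts differ by the analytic gap", {
  cfg <- cohort_config(n_trials = 40L)
  perfect <- simulate_cohort(cohort_spec("perfect", 6L, cfg, m_mean = 10,
                                         seed = 31L))
  chance <- simulate_cohort(cohort_spec("chance", 6L, cfg, m_mean = 0,
                                        seed = 32L))
  d <- bootstrap_group_diff(perfect, chance, "geometric", "unique", "none",
                            n_boot = 1000L, seed = 2L)
  gap <- 8 - expected_random_span(8)
  expect_lt(abs(d$estimate - gap), 0.35)  # MC error at 6 x 20 trials
  expect_true(d$ci[1] <= d$estimate && d$estimate <= d$ci[2])
})
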