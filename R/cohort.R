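# Cohort simulation: groups of simulated participants with subject-level
# variation in working-memory capacity and lapse rate, group tables shaped
# like the published performance table, and bootstrap group contrasts.

#' Specify a simulated cohort
#'
#' Each subject's agent parameters are drawn once per subject: capacity
#' `m ~ round(Normal(m_mean, m_sd))` clamped to `>= 0`, lapse
#' `epsilon ~ Normal(epsilon_mean, epsilon_sd)` clamped to `[0, 1]`, so
#' every draw is a valid parameterization. `varied_m_bonus` optionally adds
#' a fixed integer to each subject's capacity when the config runs the
#' varied condition — an illustrative device for the direction of the
#' published condition effect, not a mechanistic claim.
#'
#' @param group_label name of the group (e.g. `"young_adults"`).
#' @param n_subjects number of simulated participants (>= 1).
#' @param config the [task_config()] every subject performs.
#' @param m_mean,m_sd mean and sd of the capacity draw.
#' @param epsilon_mean,epsilon_sd mean and sd of the lapse-rate draw.
#' @param varied_m_bonus integer capacity bonus applied when
#'   `config$condition == "varied"` (default 0).
#' @param rt_mean_ms,rt_sd_ms response-latency model shared by subjects.
#' @param seed integer seed; fully determines the cohort.
#' @return an `sdrst_cohort_spec`.
#' @export
cohort_spec <- function(group_label, n_subjects, config,
                        m_mean, m_sd = 0, epsilon_mean = 0, epsilon_sd = 0,
                        varied_m_bonus = 0L,
                        rt_mean_ms = 1000, rt_sd_ms = 300, seed = 1L) {
  stopifnot(inherits(config, "sdrst_config"))
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (m_mean < 0 || m_sd < 0) {
    stop("m_mean/m_sd: capacity distribution must be non-negative",
         call. = FALSE)
  }
  if (epsilon_mean < 0 || epsilon_mean > 1 || epsilon_sd < 0) {
    stop("epsilon_mean/epsilon_sd: lapse distribution must lie in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(group_label = as.character(group_label)[1L],
         n_subjects = n_subjects, config = config,
         m_mean = m_mean, m_sd = m_sd,
         epsilon_mean = epsilon_mean, epsilon_sd = epsilon_sd,
         varied_m_bonus = as.integer(varied_m_bonus),
         rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
         seed = as.integer(seed)),
    class = "sdrst_cohort_spec")
}

#' Simulate a cohort through the task
#'
#' Runs `n_subjects` independent sessions, each with subject-specific
#' capacity/lapse parameters drawn from the cohort distribution and a
#' subject-specific session seed derived from `spec$seed`. Group-level cell
#' means weight subjects equally (mean of subject cell means), the standard
#' convention for group summaries.
#'
#' @param spec an [cohort_spec()].
#' @return an `sdrst_cohort`: `spec`, `subjects` (per-subject parameters
#'   and overall mean span), `subject_cells` (per-subject per-cell means)
#'   and `cells` (group-level mean/SD per cell).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sdrst_cohort_spec"))
  n <- spec$n_subjects
  pars <- with_rng_seed(derive_seed(spec$seed, 3L, 0L), {
    m <- pmax(0L, as.integer(round(stats::rnorm(n, spec$m_mean, spec$m_sd))))
    eps <- pmin(1, pmax(0, stats::rnorm(n, spec$epsilon_mean,
                                        spec$epsilon_sd)))
    list(m = m, eps = eps)
  })
  if (spec$config$condition == "varied" && spec$varied_m_bonus != 0L) {
    pars$m <- pmax(0L, pars$m + spec$varied_m_bonus)
  }

  subject_cells <- vector("list", n)
  overall <- numeric(n)
  summaries <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- spec$config
    cfg$rng_seed <- derive_seed(spec$seed, 4L, i)
    agent <- agent_capacity(pars$m[i], pars$eps[i],
                            rt_mean_ms = spec$rt_mean_ms,
                            rt_sd_ms = spec$rt_sd_ms)
    log <- run_with_agent(cfg, agent, agent_seed = derive_seed(spec$seed, 5L, i))
    s <- summarize_session(log)
    summaries[[i]] <- s
    overall[i] <- s$overall$mean_span
    sc <- s$cells
    sc$subject <- i
    subject_cells[[i]] <- sc
  }
  subject_cells <- do.call(rbind, subject_cells)

  key <- .cell_key(subject_cells$category, subject_cells$condition,
                   subject_cells$valence)
  cells <- do.call(rbind, lapply(split(seq_len(nrow(subject_cells)), key),
                                 function(i) {
    data.frame(category = subject_cells$category[i[1L]],
               condition = subject_cells$condition[i[1L]],
               valence = subject_cells$valence[i[1L]],
               n_subjects = length(i),
               mean_span = mean(subject_cells$mean_span[i]),
               sd_span = stats::sd(subject_cells$mean_span[i]),
               stringsAsFactors = FALSE)
  }))
  cells <- cells[cell_order(cells), , drop = FALSE]
  rownames(cells) <- NULL

  structure(
    list(spec = spec,
         subjects = data.frame(subject = seq_len(n), m = pars$m,
                               epsilon = pars$eps, mean_span = overall),
         summaries = summaries,
         subject_cells = subject_cells,
         cells = cells),
    class = "sdrst_cohort")
}

#' @export
print.sdrst_cohort <- function(x, ...) {
  cat(sprintf("<sdrst_cohort> %s: %d subjects, mean span %.3f\n",
              x$spec$group_label, x$spec$n_subjects,
              mean(x$subjects$mean_span)))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Group x cell performance table
#'
#' One row per cohort, one `"M (SD)"` column per (stimulus category,
#' condition, valence) cell observed in any cohort — the layout of the
#' published group performance table. Cells a cohort did not run are
#' rendered as `"-"`.
#'
#' @param results a single `sdrst_cohort` or a list of them.
#' @return a data frame with a `group` column plus one character column
#'   per cell.
#' @export
cohort_table <- function(results) {
  if (inherits(results, "sdrst_cohort")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, NA, "sdrst_cohort")))
  all_cells <- unique(do.call(rbind, lapply(results, function(r) {
    r$cells[, c("category", "condition", "valence")]
  })))
  all_cells <- all_cells[cell_order(all_cells), , drop = FALSE]
  keys <- .cell_key(all_cells$category, all_cells$condition,
                    all_cells$valence)
  cols <- paste(all_cells$category, all_cells$condition, all_cells$valence,
                sep = "_")
  out <- data.frame(group = vapply(results, function(r) r$spec$group_label,
                                   ""),
                    stringsAsFactors = FALSE)
  for (j in seq_along(keys)) {
    out[[cols[j]]] <- vapply(results, function(r) {
      k <- .cell_key(r$cells$category, r$cells$condition, r$cells$valence)
      i <- match(keys[j], k)
      if (is.na(i)) "-" else
        sprintf("%.2f (%.2f)", r$cells$mean_span[i],
                if (is.na(r$cells$sd_span[i])) 0 else r$cells$sd_span[i])
    }, "")
  }
  out
}

subject_cell_means <- function(cohort, category, condition, valence) {
  sc <- cohort$subject_cells
  i <- sc$category == category & sc$condition == condition &
    sc$valence == valence
  sc$mean_span[i]
}

#' Bootstrap contrast between two cohorts
#'
#' Resamples subjects with replacement within each group and returns the
#' group mean-span difference (a - b) for one cell with a percentile
#' confidence interval. A nonparametric alternative to parametric group
#' comparisons; deterministic given `seed`.
#'
#' @param a,b `sdrst_cohort` objects.
#' @param category,condition,valence the cell to contrast.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95, percentile interval).
#' @return a list: `estimate`, `ci` (length 2), `n_boot`, `cell`.
#' @export
bootstrap_group_diff <- function(a, b, category, condition, valence,
                                 n_boot = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(inherits(a, "sdrst_cohort"), inherits(b, "sdrst_cohort"))
  n_boot <- check_count(n_boot, "n_boot", 100L)
  xa <- subject_cell_means(a, category, condition, valence)
  xb <- subject_cell_means(b, category, condition, valence)
  if (length(xa) == 0L || length(xb) == 0L) {
    stop(sprintf("cell (%s, %s, %s) missing from %s", category, condition,
                 valence,
                 if (length(xa) == 0L) a$spec$group_label else
                   b$spec$group_label), call. = FALSE)
  }
  estimate <- mean(xa) - mean(xb)
  boots <- with_rng_seed(derive_seed(seed, 6L, 0L), {
    vapply(seq_len(n_boot), function(i) {
      mean(xa[sample.int(length(xa), replace = TRUE)]) -
        mean(xb[sample.int(length(xb), replace = TRUE)])
    }, 0)
  })
  alpha <- (1 - conf) / 2
  list(estimate = estimate,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_boot = n_boot,
       cell = c(category = category, condition = condition,
                valence = valence))
}
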