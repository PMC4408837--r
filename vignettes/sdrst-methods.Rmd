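---
title: "The SDRST engine: task model, simulated participants, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SDRST engine: task model, simulated participants, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrst)
```

## The task

The Spatial Delayed Recognition Span Task probes visuospatial working
memory by asking the participant to discriminate a novel location among an
increasing array of stimuli. One trial proceeds as follows. A stimulus
appears at one of the grid locations (16 by default) and the participant
touches it. It then reappears at the same location together with a second
stimulus at a different location, and the participant must touch the
stimulus at the *new* location. Each correct touch adds another stimulus
at a fresh location, up to a ceiling of `max_items` (8 by default); the
first mistake ends the trial. The trial's **span** is the number of
consecutive correct touches from the start.

Two task conditions manipulate the identity cue: in the **unique**
condition all stimuli within a trial are the same image, so only location
distinguishes them; in the **varied** condition every stimulus is a
different image. Stimuli carry an emotional **valence** (negative,
positive, neutral for affective scenes and facial expressions; "none" for
geometric images), and sessions allocate a fixed number of trials per
valence.

## The state machine

A session is a deterministic function of its configuration. At
`start_session()` all trial plans are pre-drawn from `config$rng_seed`:
the valence sequence is a deterministic shuffle of the per-valence counts,
and trial *i*'s plan is drawn from a sub-stream derived from
`(rng_seed, i)`, so a trial's plan is invariant to how many trials precede
it. A plan fixes `max_items` (stimulus, location) pairs with
pairwise-distinct locations drawn uniformly without replacement.

The session then alternates phases:

* `awaiting_response` — `current_display()` shows the first *k* planned
  items at their original locations; the target is the *k*-th.
* `apply_response()` — a touch on the target advances to step *k+1* (or
  ends the trial as `ceiling` at `max_items`); a touch on any other
  visible location ends the trial as `mistake`; a touch on an empty
  location is logged as `invalid_response` and changes nothing (a real
  touchscreen ignores background touches), raising a typed error.
* `trial_ended` — `advance_trial()` moves to the next trial or to
  `session_ended`.

Feedback events follow the configured mode: `auditory` emits a
`correct_tone`/`wrong_tone` per response, `auditory_plus_reward`
additionally marks correct responses with a `reward` event (the mode used
with non-human primates, who receive food after each correct response).

Every event carries a millisecond timestamp. The engine does no real-time
scheduling: display onsets are paced by `interval_time_ms` (onset =
previous event time + interval), and response times come from the
response events themselves. `exposure_time_ms` and `delay_time_ms` are
part of the configuration surface and are logged verbatim, but the
headless engine attaches no behaviour to them — nothing is rendered, so
"how long a stimulus stays visible" has no operational meaning here.

## The span measure

Span counts the leading correct responses of a trial. Step 1 is included:
only one stimulus is on screen, so the first touch cannot be wrong and
spans of completed trials lie in `[1, max_items]`. This matches a measure
defined as corrected responses before a mistake without excluding the
first presentation, and puts the ceiling at 8 — consistent with observed
group means that approach but never exceed 8.

Summaries aggregate per (stimulus category × condition × valence) cell:
trial count, mean span, sample SD (n − 1 denominator; the reporting
convention "M (SD)" does not itself fix the estimator, so the standard
sample estimator is used), and mean response time, anchored as response
timestamp minus the matching display onset. Cells with no trials are
omitted, and `cohort_table()` renders them as `-`, mirroring how group
tables leave unadministered conditions blank. Trials with no valid
responses are excluded from span means. The overall mean span equals the
trial-count-weighted mean of cell means, an identity the tests enforce.

## Simulated participants

Agents close the loop for testing: they map a display to a touched
location.

**Chance agent.** Touches uniformly among the *k* visible stimuli. Its
success probability at step *k* is 1/*k*, so the probability of surviving
steps 1..*k* is 1/*k*! and

$$E[\mathrm{span}] = \sum_{k=1}^{K} \frac{1}{k!} \;\approx\; e - 1,$$

which is 1.71828 at the default ceiling of `K = 8`
(`expected_random_span()`). This is the task's chance level.

**Capacity agent** (`agent_capacity(m, epsilon)`). A parametric stand-in
for working-memory load: it retains the `m` most recent old locations
(FIFO eviction — a recency model) and, with lapse probability `epsilon`,
ignores memory and touches uniformly among everything visible; otherwise
it touches uniformly among the visible locations it does *not* remember.
After every step the **true** target location is pushed into memory,
regardless of the agent's own choice: the task's corrective structure
(the trial continues on a correct touch and stops otherwise) reveals the
answer, and this choice keeps the exact analysis tractable. Along the
all-correct path memory therefore holds `min(m, k − 1)` genuine old
locations at step *k*, the target is never remembered, and

$$p_k = \frac{\varepsilon}{k} + \frac{1-\varepsilon}{k - \min(m, k-1)},
\qquad E[\mathrm{span}] = \sum_{k=1}^{K} \prod_{j \le k} p_j$$

(`expected_capacity_span()`). The limits are exact: `m = 0, ε = 0` is the
chance agent (the implementation draws identically, so the equivalence is
distributional *and* bitwise under a shared seed), and
`m ≥ K − 1, ε = 0` scores the ceiling on every trial. The test suite
validates the closed form against an independent recursive enumerator
that tracks explicit remembered-location sets, against an engine-free
Monte-Carlo process, and against full engine simulations.

Synthetic response latencies are lognormal, moment-matched to a
configured mean and SD (defaults 1000 ± 300 ms, a plausible touch
latency scale) and floored at 1 ms so they are strictly positive.

## Cohorts

A cohort draws per-subject parameters once — capacity
`m ~ round(Normal(m_mean, m_sd))` clamped at 0, lapse
`ε ~ Normal(ε_mean, ε_sd)` clamped to `[0, 1]` (clamping rather than
rejection sampling: it is deterministic in the number of draws and every
draw is valid) — and runs each subject through an independent session.
Group cell means weight subjects equally (mean of subject means), the
standard convention for group summaries; subject-level resampling drives
`bootstrap_group_diff()`, a nonparametric contrast used instead of
parametric group comparisons.

The agent model deliberately builds in **no** condition (unique/varied)
or valence effects: those are empirical phenomena of human memory, and
simulating them mechanistically would claim more than the engine knows.
`cohort_spec(varied_m_bonus =)` can add a fixed capacity bonus in the
varied condition to illustrate the direction of the published condition
effect; it is labelled illustrative and defaults to 0.

## What the simulations do and do not show

The generator's defaults are the published task parameterizations: a
4 × 4 grid of 16 locations (the arrangement of the 16 locations is not
specified anywhere, so the simplest symmetric layout was chosen; any
geometry can be supplied via `grid_spec()`), a ceiling of 8 items,
4 × 4 cm stimulus metadata, inter-stimulus intervals of 5 s / 3 s / 1 s
and 16 / 10 / 16 trials per valence for the three study presets, with
auditory feedback in the 40-trial face study. Where the sources are
silent — exposure and delay defaults (1000 ms and 0 ms), trial ordering
(a seeded shuffle interleaving valences; blocked designs can be expressed
by running one config per valence), latency scale — a single realistic
value was chosen and documented here.

Passing tests show that the engine enforces the task's combinatorial
structure, that scoring implements the span measure exactly, and that the
simulated agents agree with their analytic expectations. They do **not**
show anything about human performance: the agents have no perceptual
noise, no fatigue, no emotional modulation, and no identity-cue benefit,
so empirical group means, condition effects and valence effects are
outside what the simulations can reproduce — only their ordinal structure
(higher capacity ⇒ higher span; everyone above chance) is checked.

## Numerical and scale choices

* All times are integer milliseconds; stimulus sizes in cm are metadata.
* JSON serialization uses 17 significant digits, so configurations and
  logs round-trip bit-exactly; canonical key order makes files
  byte-deterministic, and logs contain no wall-clock times.
* Seed sub-streams are derived with a Lehmer-style hash modulo 2³¹ − 1,
  keeping every derived seed a valid 32-bit integer.
* Simulation sizes used by the checks: 10⁵ engine trials for the chance
  oracle at the ceiling of 8 (3 × 10⁴ at ceilings 2–7), 2 × 10⁴ trials
  per capacity level, cohorts of 6 subjects × 16 trials with 10 replicate
  seeds for the ordinal checks; agreement bands are three standard errors
  of the simulated mean.

## Known limitations

* The engine is single-session; longitudinal designs are driven
  externally by varying seeds.
* `exposure_time_ms`/`delay_time_ms` have no behavioural effect (nothing
  is displayed); they exist so configurations are faithful and logs
  complete.
* The capacity agent's memory stores true targets, so it cannot model
  perseverative errors or misremembered locations; it is an oracle-
  friendly load model, not a cognitive theory.
* Bootstrap contrasts resample subjects only; trial-level uncertainty
  within subject is not propagated separately.
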