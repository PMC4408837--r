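Package: sdrst
Title: Headless Engine for the Spatial Delayed Recognition Span Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully configurable, headless implementation of the Spatial
    Delayed Recognition Span Task (SDRST), a touchscreen paradigm for
    measuring visuospatial working-memory span. Provides constrained-random
    trial generation on a configurable location grid, an event-driven session
    state machine with auditory/reward feedback events and JSON-Lines event
    logs, span scoring and per-condition summaries, simulated participants
    (a uniform-random chance agent and a capacity-limited working-memory
    agent with lapses), closed-form chance-level expectations, and cohort
    simulation with bootstrap group contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
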