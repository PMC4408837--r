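# Deterministic seed derivation and scoped RNG use.
#
# Every source of randomness in the package is driven by a user-visible
# integer seed; sub-streams (trial order, per-trial plans, per-subject
# parameters, ...) are derived with a Lehmer-style integer hash so that
# trial i's plan does not depend on how many trials precede it.

.SDRST_MOD <- 2147483647  # 2^31 - 1; multiplier 48271 keeps products < 2^53

#' Derive a sub-stream seed from a master seed
#'
#' @param seed master integer seed.
#' @param stream small integer identifying the stream (trial order, plans,
#'   subject draws, ...).
#' @param index element index within the stream.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @keywords internal
derive_seed <- function(seed, stream, index = 0L) {
  h <- abs(as.numeric(seed)) %% .SDRST_MOD
  h <- (h * 48271 + abs(as.numeric(stream)) + 1) %% .SDRST_MOD
  h <- (h * 48271 + abs(as.numeric(index)) + 1) %% .SDRST_MOD
  as.integer(h)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}
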