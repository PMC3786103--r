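# Internal helpers shared across modules.

# Classed errors so callers/tests can distinguish failure modes.
qsar_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qsarga_error", "error", "condition")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's global RNG state afterwards. All stochastic routines in the
# package funnel randomness through this so nothing touches the global
# stream and every result is a pure function of its explicit seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    qsar_abort("`seed` must be a single finite integer", "qsar_config_error")
  }
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
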