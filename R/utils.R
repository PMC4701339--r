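# Internal helpers shared across modules.

# Derive a reproducible sub-seed (< 2^31) from a master seed and up to two
# stream indices, so per-subject / per-channel randomness does not depend on
# generation order.
derive_seed <- function(master, i = 0L, j = 0L) {
  base <- (abs(as.double(master)) %% 1e6) * 2147.0
  as.integer((base + i * 8191 + j * 131 + 17) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_param <- function(msg) {
  abort(msg, class = "fallrisk_parameter_error")
}

stop_degenerate <- function(msg) {
  abort(msg, class = "fallrisk_degenerate_error")
}

stop_calibration <- function(msg) {
  abort(msg, class = "fallrisk_calibration_error")
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_param(sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max))
  }
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    stop_param(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  as.integer(x)
}
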