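# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded calls do not perturb it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# samples for a duration at a given rate (round to nearest sample)
ms_to_samples <- function(ms, sample_rate_hz) {
  as.integer(round(ms / 1000 * sample_rate_hz))
}

# wrap angles into (-pi, pi]
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

pair_key <- function(gap_width_ms, mod_depth_pct) {
  sprintf("g%g_d%g", gap_width_ms, mod_depth_pct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
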