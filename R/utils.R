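# Internal helpers.

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state
# afterwards, so generators are deterministic and side-effect free.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Trailing rolling mean/sum over a 1-s window, truncated at the series start
# (frame i averages frames max(1, i-w+1)..i).
roll_mean_trail <- function(x, w) {
  roll_sum_trail(x, w) / pmin(seq_along(x), w)
}

roll_sum_trail <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  if (n <= w) return(cs)
  cs - c(rep(0, w), cs[seq_len(n - w)])
}

euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

`%||%` <- function(a, b) if (is.null(a)) b else a
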