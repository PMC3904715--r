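# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

check_len3_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be 3 positive finite numbers", name), call. = FALSE)
  invisible(x)
}

# Squared-term helper with the 0/0 -> 0 convention used by the closed-set
# contact tests (offset 0 always passes, positive offset against a degenerate
# semi-axis never does).
sq_ratio <- function(g, a) {
  out <- ifelse(g == 0, 0, (g / a)^2)
  out[g > 0 & a == 0] <- Inf
  out
}

# Distance from points x to the closed interval [lo, hi] (0 inside).
interval_dist <- function(x, lo, hi) {
  pmax(0, pmax(lo - x, x - hi))
}
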