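# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators never leak global random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gd <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "groovedock_error")))
}

# Angular difference on the circle, degrees, in [0, 180].
angle_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
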