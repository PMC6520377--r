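## Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All generators route their randomness
# through this so that runs are bit-reproducible and never perturb global RNG
# state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Unit conversions are centralised here: sarcomere lengths are carried in um,
## laser wavelengths in nm, projection distances in cm, electrode coordinates
## in um, velocities in cm/s, trace times in s.
nm_to_um <- function(x) x * 1e-3
um_to_cm <- function(x) x * 1e-4
mm_to_cm <- function(x) x * 1e-1
um_to_mm <- function(x) x * 1e-3

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    stopf("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

# Standard error of the mean.
se <- function(x) stats::sd(x) / sqrt(length(x))

# Indices of strict local maxima of a numeric vector (plateau: first index).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # rising then falling, with plateaus collapsed to their first sample
  rise <- c(FALSE, d > 0)
  fall <- c(d < 0, FALSE)
  # propagate last rise across zero-run plateaus
  lastd <- d
  for (i in seq_along(lastd)) if (i > 1 && lastd[i] == 0) lastd[i] <- lastd[i - 1]
  rise2 <- c(FALSE, lastd > 0)
  which(rise2 & fall)
}
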