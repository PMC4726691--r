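#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: one top-level seed fans out to per-stage,
# per-unit substreams. Kept below 2^31 - 1 so they are valid R integer seeds.
substream_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage))) %% 10007L
  as.integer((abs(seed) * 7919 + h * 104729 + index * 65537) %% 2147483629)
}

# Run an expression with a local RNG state so generators never disturb the
# caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stationary AR(1) with given marginal mean, marginal sd, lag-1 correlation.
ar1_series <- function(n, mean, sd, phi) {
  if (n < 1) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  }
  mean + x
}

# Centered rolling mean with shrinking windows at the edges.
rolling_mean <- function(x, width) {
  n <- length(x)
  half <- width %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
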