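# Internal helpers shared across modules.

# Wrap angles to (-pi, pi]. The R-peak sits at the branch cut, so the
# boundary must map to +pi (equivalently -pi at the start of systole).
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# RNG state. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-unit substream seeds from a root seed, so results are
# invariant to iteration order over subjects. Kept below 2^31 - 1.
substream_seed <- function(seed, index) {
  v <- (as.double(seed) %% 2147483647) * 48271 + 1009 * as.double(index)
  as.integer(v %% 2147483647) + 1L
}

# Causal IIR/FIR filtering with explicit state so a signal can be processed
# in chunks with bit-identical results to a single pass. Direct-form:
# convolution part via stats::filter(sides = 1), recursive part via
# stats::filter(method = "recursive") whose `init` is most-recent-first.
iir_filter <- function(b, a, x, state = NULL) {
  b <- b / a[1L]
  a <- a / a[1L]
  nb <- length(b)
  na <- length(a)
  if (is.null(state)) {
    state <- list(x = numeric(max(nb - 1L, 0L)), y = numeric(max(na - 1L, 0L)))
  }
  n <- length(x)
  if (n == 0L) return(list(y = numeric(0), state = state))
  xx <- c(state$x, x)
  if (nb > 1L) {
    v <- as.numeric(stats::filter(xx, b, method = "convolution", sides = 1))
    v <- v[(nb):(nb - 1L + n)]
  } else {
    v <- b * x
  }
  if (na > 1L) {
    y <- as.numeric(stats::filter(v, -a[-1L], method = "recursive", init = state$y))
  } else {
    y <- v
  }
  list(
    y = y,
    state = list(
      x = if (nb > 1L) xx[(length(xx) - nb + 2L):length(xx)] else numeric(0),
      y = if (na > 1L) c(rev(y), state$y)[seq_len(na - 1L)] else numeric(0)
    )
  )
}

# Shortest interval containing `mass` of the draws.
hdi_interval <- function(draws, mass = 0.95) {
  draws <- sort(draws)
  m <- length(draws)
  k <- max(1L, ceiling(mass * m))
  if (k >= m) return(c(draws[1L], draws[m]))
  widths <- draws[(k + 1L):m] - draws[1L:(m - k)]
  i <- which.min(widths)
  c(draws[i], draws[i + k])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
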