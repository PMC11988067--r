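#' @keywords internal
"_PACKAGE"

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a base seed; stays below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered running mean whose window shrinks symmetrically at the edges:
# at position i the half-width is min(h, i - 1, n - i) with h = (window-1)/2.
centered_running_mean <- function(x, window) {
  if (window %% 2 != 1 || window < 1) {
    stopf("`window` must be a positive odd integer, got %s", window)
  }
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    out[i] <- mean(x[(i - hi):(i + hi)])
  }
  out
}
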