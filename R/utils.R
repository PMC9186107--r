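# Internal helpers shared across modules.

# Classed errors so callers/tests can condition on failure mode rather than
# message text.
sd_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "slowdrift_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

sd_check <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) sd_stop(class, msg, ...)
  invisible(TRUE)
}

# Derive independent child seeds from a parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  as.list(s)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  code
}

# Linear interpolation of an arousal latent onto arbitrary times (seconds).
# The latent grid is uniform, so the interpolation is done by direct indexing
# (approx() would re-validate the grid on every call).
latent_at <- function(latent, times_s) {
  t0 <- latent$time_s[1]
  step <- latent$step_s %||% (latent$time_s[2] - latent$time_s[1])
  n <- length(latent$value)
  pos <- (times_s - t0) / step
  i <- pmin(pmax(floor(pos), 0), n - 2)
  frac <- pmin(pmax(pos - i, 0), 1)
  latent$value[i + 1] * (1 - frac) + latent$value[i + 2] * frac
}

`%||%` <- function(a, b) if (is.null(a)) b else a
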