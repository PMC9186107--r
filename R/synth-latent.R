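#' Generate a slow arousal latent
#'
#' White noise on a regular grid is convolved with a Gaussian kernel of the
#' given SD and standardized to zero mean / unit variance over the session.
#' The resulting process has autocorrelation `exp(-dt^2 / (4 * sd^2))`, so the
#' smoothing SD plays the role of the process timescale. Downstream analyses
#' bin at >= 1 min, so the default 1-s grid is ample; event-level values are
#' obtained by linear interpolation.
#'
#' @param duration Session duration, minutes. Must be at least twice
#'   `timescale_sd` so the session spans several independent latent excursions.
#' @param timescale_sd Gaussian smoothing SD, minutes.
#' @param step Grid step, seconds (default 1).
#' @param seed Optional integer seed.
#' @return An object of class `arousal_latent`: list with `time_s`, `value`,
#'   `timescale_sd_min`, `step_s`.
#' @export
generate_arousal_latent <- function(duration, timescale_sd, step = 1,
                                    seed = NULL) {
  sd_check(is.numeric(duration) && duration > 0 &&
             is.numeric(timescale_sd) && timescale_sd > 0 && step > 0,
           "invalid_parameter",
           "duration, timescale_sd and step must be positive")
  sd_check(duration >= 2 * timescale_sd, "invalid_parameter",
           "duration must be at least 2 x timescale_sd")
  with_seed(seed, {
    time_s <- seq(0, duration * 60, by = step)
    n <- length(time_s)
    sd_steps <- timescale_sd * 60 / step
    half <- max(1L, as.integer(ceiling(4 * sd_steps)))
    kernel <- stats::dnorm(seq(-half, half), sd = sd_steps)
    noise <- stats::rnorm(n + 2L * half)
    # convolve() with type "filter" keeps the fully-overlapping (valid) part
    value <- stats::convolve(noise, kernel, type = "filter")
    stopifnot(length(value) == n)
    value <- (value - mean(value)) / stats::sd(value)
    structure(list(time_s = time_s, value = value,
                   timescale_sd_min = timescale_sd, step_s = step),
              class = "arousal_latent")
  })
}
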