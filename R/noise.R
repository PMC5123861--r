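#' Additive Gaussian noise model for synthetic data
#'
#' All synthetic generators perturb their noiseless signal with zero-mean
#' additive Gaussian noise of standard deviation `sigma`, expressed in the
#' units of the perturbed quantity (fluorescence, kJ, fraction bound, EPR
#' amplitude, ppm). A fixed `seed` makes the generated stream reproducible;
#' identical (parameters, seed) always yields identical output.
#'
#' @param sigma Standard deviation, >= 0, in units of the perturbed signal.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return An object of class `noise_model`.
#' @export
#' @examples
#' noise_model(sigma = 0.01, seed = 7)
noise_model <- function(sigma = 0, seed = NULL) {
  stopifnot_scalar_pos(sigma, "sigma", strict = FALSE)
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    seed <- as.integer(seed)
  }
  structure(list(kind = "additive-gaussian", sigma = sigma, seed = seed),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Additive Gaussian noise: sigma = %g, seed = %s\n",
              x$sigma, if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

## Perturb a numeric vector in-stream (callers wrap the whole generator in
## with_seed(noise$seed, ...) so multi-trace draws stay sequential).
perturb <- function(x, noise) {
  if (noise$sigma == 0) return(x)
  x + stats::rnorm(length(x), mean = 0, sd = noise$sigma)
}
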