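#' Ground-truth observer for 2AFC detection and discrimination
#'
#' Parameterizes the cumulative-normal psychometric function
#' \deqn{\Psi(x) = \gamma + (1 - \gamma - \lambda)\,\Phi((x - \mu)/\sigma)}
#' that drives all simulated two-alternative forced-choice (2AFC) responses.
#' In a 2AFC task the guess rate `gamma` is 0.5 (chance performance when the
#' stimulus is undetectable); the lapse rate `lam` defaults to 0, matching the
#' constraint used when fitting.
#'
#' @param mu Location of the psychometric function (mA). For a detection
#'   observer this is the amplitude of 75% accuracy when `gamma = 0.5`,
#'   `lam = 0`.
#' @param sigma Spread of the psychometric function (mA); must be positive.
#' @param gamma Guess rate in `[0, 1)`. Fixed at 0.5 for 2AFC.
#' @param lam Lapse rate in `[0, 0.5)`.
#' @return An object of class `observer_params`.
#' @examples
#' obs <- observer_params(mu = 2, sigma = 0.4)
#' psi_fun(obs)(2) # 0.75
#' @export
observer_params <- function(mu, sigma, gamma = 0.5, lam = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    abort("`sigma` must be a single positive number.")
  if (gamma < 0 || gamma >= 1) abort("`gamma` must lie in [0, 1).")
  if (lam < 0 || lam >= 0.5) abort("`lam` must lie in [0, 0.5).")
  structure(list(mu = mu, sigma = sigma, gamma = gamma, lam = lam),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> mu = %g mA, sigma = %g mA, gamma = %g, lapse = %g\n",
    x$mu, x$sigma, x$gamma, x$lam))
  invisible(x)
}

#' Psychometric function of an observer
#'
#' @param obs An [observer_params()] object.
#' @return A vectorized function mapping amplitude (mA) to P(correct).
#' @export
psi_fun <- function(obs) {
  stopifnot(inherits(obs, "observer_params"))
  function(x) obs$gamma + (1 - obs$gamma - obs$lam) * pnorm((x - obs$mu) / obs$sigma)
}

#' Simulate 2AFC trial outcomes
#'
#' Draws Bernoulli correct/incorrect outcomes from the observer's psychometric
#' function at the given amplitudes. Uses R's global RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @param obs An [observer_params()] object.
#' @param amplitude Numeric vector of non-negative stimulus amplitudes (mA).
#' @return Logical vector, `TRUE` where the simulated response was correct.
#' @examples
#' set.seed(1)
#' mean(simulate_2afc(observer_params(2, 0.4), rep(2, 1e4))) # ~0.75
#' @export
simulate_2afc <- function(obs, amplitude) {
  stopifnot(inherits(obs, "observer_params"))
  if (any(!is.finite(amplitude))) abort("`amplitude` must be finite.")
  if (any(amplitude < 0)) abort("`amplitude` must be non-negative.")
  runif(length(amplitude)) < psi_fun(obs)(amplitude)
}

#' Ground-truth parameters for magnitude-estimation ratings
#'
#' Perceived intensity grows linearly with stimulus amplitude; ratings are
#' never negative and amplitudes below a perceptual floor are rated 0 ("no
#' sensation perceived").
#'
#' @param slope Rating gain per mA.
#' @param intercept Rating offset (dimensionless).
#' @param noise_sd Standard deviation of additive rating noise (>= 0).
#' @param floor Amplitude (mA) below which the rating is exactly 0.
#' @param noise Noise model: additive Gaussian truncated at zero (default), or
#'   multiplicative lognormal.
#' @return An object of class `magnitude_params`.
#' @export
magnitude_params <- function(slope, intercept = 0, noise_sd = 0, floor = 0,
                             noise = c("gaussian", "lognormal")) {
  noise <- match.arg(noise)
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 floor = floor, noise = noise),
            class = "magnitude_params")
}

#' Simulate free magnitude-estimation ratings
#'
#' @param mp A [magnitude_params()] object.
#' @param amplitude Numeric vector of non-negative amplitudes (mA).
#' @return Numeric vector of non-negative ratings; 0 below the floor.
#' @examples
#' simulate_magnitude_rating(magnitude_params(slope = 1), 2.5) # 2.5
#' @export
simulate_magnitude_rating <- function(mp, amplitude) {
  stopifnot(inherits(mp, "magnitude_params"))
  if (any(!is.finite(amplitude)) || any(amplitude < 0))
    abort("`amplitude` must be finite and non-negative.")
  base <- mp$intercept + mp$slope * amplitude
  r <- if (mp$noise == "gaussian") {
    base + rnorm(length(amplitude), 0, mp$noise_sd)
  } else {
    base * exp(rnorm(length(amplitude), 0, mp$noise_sd))
  }
  r <- pmax(r, 0)
  r[amplitude < mp$floor] <- 0
  r
}
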