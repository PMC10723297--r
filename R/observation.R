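#' Ground-truth observation model for vocal responses
#'
#' The probability that a call of duration `x` elicits a response from the
#' partner is modeled as a Gaussian-shaped function of duration,
#' \deqn{\Upsilon(\theta', x) = V_{max} \exp(-(x - \theta')^2 / 2\sigma_1^2),}
#' peaking at the optimal duration `theta_true` with peak response rate
#' `v_max` (no call is answered every time) and width `sigma1`. The defaults
#' (`sigma1 = 0.9`, `v_max = 0.5`, `theta_true = 1.5` on durations 0--5 s)
#' are the simulation conditions used throughout the package.
#'
#' @param sigma1 Width of the response law (seconds), positive.
#' @param v_max Peak response probability, in (0, 1].
#' @param theta_true True optimal duration, within the grid range.
#' @param grid A [duration_grid()] giving the duration support.
#'
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(sigma1 = 0.9, v_max = 0.5, theta_true = 1.5,
                              grid = duration_grid()) {
  stopifnot(inherits(grid, "duration_grid"))
  if (!is.numeric(sigma1) || length(sigma1) != 1L || !is.finite(sigma1) || sigma1 <= 0)
    stop("observation_model: sigma1 must be a positive number")
  if (!is.numeric(v_max) || length(v_max) != 1L || v_max <= 0 || v_max > 1)
    stop("observation_model: v_max must lie in (0, 1]")
  if (!is.numeric(theta_true) || length(theta_true) != 1L ||
      theta_true < grid$lo || theta_true > grid$hi)
    stop("observation_model: theta_true must lie within the grid range")
  structure(list(sigma1 = sigma1, v_max = v_max, theta_true = theta_true,
                 grid = grid),
            class = "observation_model")
}

#' @export
print.observation_model <- function(x, ...) {
  cat(sprintf("observation_model: Upsilon peaks at %.3g s (rate %.3g), width sigma1 = %.3g s\n",
              x$theta_true, x$v_max, x$sigma1))
  invisible(x)
}

#' Ground-truth response probability of a call duration
#'
#' Evaluates `Upsilon(theta_true, x)`, the probability that a call of
#' duration `x` receives a response under the model's true optimum.
#'
#' @param model An [observation_model()].
#' @param x Call duration(s), seconds; must be finite.
#' @return Response probabilities in `(0, v_max]`, vectorized over `x`.
#' @examples
#' m <- observation_model()
#' response_likelihood(m, 1.5) # peak: 0.5
#' @export
response_likelihood <- function(model, x) {
  stopifnot(inherits(model, "observation_model"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("response_likelihood: x must be finite numeric")
  upsilon(x, model$theta_true, model$sigma1, model$v_max)
}

# Upsilon(theta, x) with an arbitrary candidate optimum; vectorized over
# either argument. Used both for the ground truth (theta = theta_true) and
# for the agent's hypothesis space (theta = each grid point).
upsilon <- function(x, theta, sigma1, v_max) {
  v_max * exp(-(x - theta)^2 / (2 * sigma1^2))
}

#' Measurement model for the perceived response likelihood
#'
#' After each call, the agent treats the (noisy) perceived response
#' likelihood `V = Upsilon(theta, x) + eps` as a measurement, with `eps`
#' zero-mean Gaussian noise of standard deviation `sigma2`. Hypothetical
#' measurements are evaluated on a fixed grid of `n_v` values spanning
#' `[0, 1]`, the admissible range of a response likelihood.
#'
#' @param sigma2 Standard deviation of the measurement noise (default 0.3).
#' @param n_v Number of hypothetical-likelihood grid points on `[0, 1]`.
#' @return An object of class `measurement_model` with elements `sigma2`,
#'   `v_grid` and `n_v`.
#' @export
measurement_model <- function(sigma2 = 0.3, n_v = 51) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0)
    stop("measurement_model: sigma2 must be a positive number")
  n_v <- as.integer(n_v)
  if (is.na(n_v) || n_v < 2L)
    stop("measurement_model: n_v must be an integer >= 2")
  structure(list(sigma2 = sigma2, v_grid = seq(0, 1, length.out = n_v),
                 n_v = n_v),
            class = "measurement_model")
}

#' @export
print.measurement_model <- function(x, ...) {
  cat(sprintf("measurement_model: sigma2 = %.3g, %d hypothetical V values on [0, 1]\n",
              x$sigma2, x$n_v))
  invisible(x)
}

#' Gaussian measurement likelihood p(V | theta, x)
#'
#' Density of observing perceived response likelihood `v` when the model
#' value is `Upsilon(theta, x) = model_value`:
#' `p(V | theta, x) = N(v; model_value, sigma2^2)`.
#'
#' @param meas A [measurement_model()].
#' @param model_value The noiseless response likelihood `Upsilon(theta, x)`.
#' @param v The hypothetical measurement.
#' @return Strictly positive density value(s).
#' @export
measurement_likelihood <- function(meas, model_value, v) {
  stopifnot(inherits(meas, "measurement_model"))
  s2 <- meas$sigma2
  exp(-(v - model_value)^2 / (2 * s2^2)) / (sqrt(2 * pi) * s2)
}
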