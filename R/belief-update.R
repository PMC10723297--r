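#' Bayesian belief update after a call-and-response outcome
#'
#' After emitting a call of duration `x` and hearing (or not hearing) a
#' response, the caller updates its belief over the optimal duration with a
#' binary-response Bayesian filter:
#' `p_{t+1}(theta) ~ Upsilon(theta, x) p_t(theta)` on a response, and
#' `p_{t+1}(theta) ~ (1 - Upsilon(theta, x)) p_t(theta)` otherwise, where
#' `Upsilon(theta, x)` is the response law evaluated at each candidate
#' optimum `theta` (the agent knows the functional form, not the true
#' optimum). The normalization constant is absorbed by renormalizing.
#'
#' @param belief Current `belief`.
#' @param model An [observation_model()]; supplies `sigma1` and `v_max`.
#' @param x Call duration, within the grid range.
#' @param responded Logical flag: did the partner respond?
#' @return The updated, normalized `belief`.
#' @examples
#' b <- uniform_belief()
#' b1 <- update_belief_with_response(b, observation_model(), 1.5, TRUE)
#' belief_mode(b1) # mass moves toward the emitted duration
#' @export
update_belief_with_response <- function(belief, model, x, responded) {
  stopifnot(inherits(belief, "belief"), inherits(model, "observation_model"),
            is.logical(responded), length(responded) == 1L, !is.na(responded))
  g <- belief$grid
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < g$lo || x > g$hi)
    stop("update_belief_with_response: x must lie within the grid range")
  ups <- upsilon(x, g$points, model$sigma1, model$v_max)
  lik <- if (responded) ups else 1 - ups
  post <- lik * belief$mass
  s <- sum(post)
  if (!is.finite(s) || s <= 0)
    stop("update_belief_with_response: degenerate update (all posterior mass zero)")
  belief(g, post / s)
}

#' Hypothetical posterior given an imagined measurement
#'
#' The one-step look-ahead used by the active-sampling policy: if the agent
#' were to call with duration `x` and perceive response likelihood `v`, its
#' belief would become
#' `p_{t+1}(theta | V, x) = p(V | theta, x) p_t(theta) / p(V | x)`,
#' with `p(V | theta, x)` the Gaussian measurement likelihood centered on
#' `Upsilon(theta, x)` for each candidate optimum `theta`.
#'
#' @param belief Current `belief`.
#' @param meas A [measurement_model()].
#' @param model_family An [observation_model()]; supplies the shared
#'   `sigma1` and `v_max` of the agent's hypothesis family.
#' @param x Candidate call duration.
#' @param v Hypothetical perceived response likelihood.
#' @return The hypothetical normalized `belief`.
#' @export
hypothetical_posterior <- function(belief, meas, model_family, x, v) {
  stopifnot(inherits(belief, "belief"), inherits(meas, "measurement_model"),
            inherits(model_family, "observation_model"))
  g <- belief$grid
  ups <- upsilon(x, g$points, model_family$sigma1, model_family$v_max)
  post <- measurement_likelihood(meas, ups, v) * belief$mass
  s <- sum(post)
  if (!is.finite(s) || s <= 0)
    stop("hypothetical_posterior: degenerate update (all posterior mass zero)")
  belief(g, post / s)
}

#' Marginal density of the hypothetical measurement, p(V | x)
#'
#' Marginalizes the Gaussian measurement likelihood over the current belief:
#' `p(V | x) = sum_theta p_t(theta) p(V | theta, x)`, a mixture of
#' unit-mass Gaussians whose integral over the whole real line is one.
#' Values are returned at the measurement grid points on `[0, 1]`; the mass
#' lying outside `[0, 1]` is handled by the renormalization inside
#' [expected_information_density()].
#'
#' @inheritParams hypothetical_posterior
#' @return Numeric vector of non-negative densities, one per `v_grid` point.
#' @export
measurement_marginal <- function(belief, meas, model_family, x) {
  stopifnot(inherits(belief, "belief"), inherits(meas, "measurement_model"),
            inherits(model_family, "observation_model"))
  g <- belief$grid
  ups <- upsilon(x, g$points, model_family$sigma1, model_family$v_max)
  # dens[i, j] = p(v_j | theta_i, x)
  dens <- measurement_likelihood(meas, ups, rep(meas$v_grid, each = g$n_points))
  dim(dens) <- c(g$n_points, meas$n_v)
  as.vector(crossprod(dens, belief$mass))
}
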