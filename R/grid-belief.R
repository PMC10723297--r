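#' Discretized support for call durations
#'
#' The belief over candidate optimal call durations, the agent's policy
#' distributions, and the ground-truth response law all live on a common
#' equally spaced grid of durations. The default grid spans 0 to 5 seconds,
#' the range of plausible contact-call durations.
#'
#' @param lo Lower end of the duration range (seconds).
#' @param hi Upper end of the duration range (seconds).
#' @param n_points Number of grid points (at least 2).
#'
#' @return An object of class `duration_grid` with elements `lo`, `hi`,
#'   `n_points`, `points` (strictly increasing, equally spaced) and `step`.
#' @examples
#' g <- duration_grid()
#' range(g$points)
#' @export
duration_grid <- function(lo = 0, hi = 5, n_points = 101) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("duration_grid: need finite lo < hi")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("duration_grid: n_points must be an integer >= 2")
  structure(
    list(lo = lo, hi = hi, n_points = n_points,
         points = seq(lo, hi, length.out = n_points),
         step = (hi - lo) / (n_points - 1L)),
    class = "duration_grid"
  )
}

#' @export
print.duration_grid <- function(x, ...) {
  cat(sprintf("duration_grid: %d points on [%g, %g] (step %g)\n",
              x$n_points, x$lo, x$hi, x$step))
  invisible(x)
}

#' Belief over the optimal call duration
#'
#' A belief is a discrete probability distribution `p_t(theta)` over
#' candidate optimal durations on a [duration_grid()]. Masses must be
#' non-negative and sum to one within `1e-9`; every operation in the
#' package that returns a belief renormalizes before returning.
#'
#' @param grid A [duration_grid()].
#' @param mass Numeric vector of probability masses, one per grid point.
#' @param normalize If `TRUE`, rescale `mass` to sum to one instead of
#'   requiring it already normalized.
#'
#' @return An object of class `belief` with elements `grid` and `mass`.
#' @seealso [uniform_belief()], [entropy()], [update_belief_with_response()]
#' @export
belief <- function(grid, mass, normalize = FALSE) {
  stopifnot(inherits(grid, "duration_grid"))
  if (!is.numeric(mass) || length(mass) != grid$n_points)
    stop("belief: mass must be numeric with one entry per grid point")
  if (any(!is.finite(mass)) || any(mass < 0))
    stop("belief: masses must be finite and non-negative")
  s <- sum(mass)
  if (normalize) {
    if (s <= 0) stop("belief: cannot normalize an all-zero mass vector")
    mass <- mass / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("belief: masses sum to %.12g, not 1 (tolerance 1e-9)", s))
  }
  structure(list(grid = grid, mass = mass), class = "belief")
}

#' Uniform belief on a duration grid
#'
#' The initial state of every simulated agent: equal mass on every grid
#' point, encoding no prior information about the optimal duration.
#'
#' @param grid A [duration_grid()].
#' @return A `belief` object.
#' @export
uniform_belief <- function(grid = duration_grid()) {
  belief(grid, rep(1 / grid$n_points, grid$n_points))
}

#' @export
print.belief <- function(x, ...) {
  cat(sprintf("belief on %d grid points [%g, %g]; mode at %g, entropy %.4f nats\n",
              x$grid$n_points, x$grid$lo, x$grid$hi,
              belief_mode(x), entropy(x)))
  invisible(x)
}

#' Shannon entropy of a belief (nats)
#'
#' Computes `S[p] = -sum_theta p(theta) log p(theta)` with the continuity
#' convention `0 log 0 = 0`. Natural logarithms are used, so the result is
#' in nats and lies in `[0, log(n_points)]`.
#'
#' @param belief A `belief` object.
#' @return Entropy in nats.
#' @examples
#' entropy(uniform_belief(duration_grid(n_points = 101))) # log(101)
#' @export
entropy <- function(belief) {
  stopifnot(inherits(belief, "belief"))
  p <- belief$mass
  if (abs(sum(p) - 1) > 1e-9)
    stop("entropy: belief is not normalized")
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Mode of a belief
#'
#' @param belief A `belief` object.
#' @return The grid point (duration, seconds) carrying the largest mass;
#'   ties resolve to the smallest such duration.
#' @export
belief_mode <- function(belief) {
  stopifnot(inherits(belief, "belief"))
  belief$grid$points[which.max(belief$mass)]
}
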