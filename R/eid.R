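#' Precomputed tables for Expected Information Density evaluation
#'
#' The measurement likelihood `p(V | theta, x)` does not depend on the
#' belief, so for a fixed grid, measurement model and observation-model
#' family it can be tabulated once and reused across every belief update of
#' a session. [run_simulation()] builds one engine per session;
#' [expected_information_density()] builds a throwaway engine when none is
#' supplied.
#'
#' @param grid A [duration_grid()]; candidate durations `x` are evaluated
#'   at the same points as the belief support `theta`.
#' @param meas A [measurement_model()] with at least 3 `v_grid` points.
#' @param model_family An [observation_model()] supplying the hypothesis
#'   family's `sigma1` and `v_max`.
#' @return An object of class `eid_engine`.
#' @export
eid_engine <- function(grid, meas, model_family) {
  stopifnot(inherits(grid, "duration_grid"), inherits(meas, "measurement_model"),
            inherits(model_family, "observation_model"))
  if (meas$n_v < 3L)
    stop("eid_engine: need at least 3 measurement grid points")
  th <- grid$points
  n <- grid$n_points
  nv <- meas$n_v
  # ups[theta, x]
  ups <- upsilon(rep(th, each = n), th, model_family$sigma1, model_family$v_max)
  dim(ups) <- c(n, n)
  # lik[theta, (x, v)] with x varying fastest: p(v | theta, x)
  lik <- array(0, dim = c(n, n, nv))
  for (iv in seq_len(nv))
    lik[, , iv] <- measurement_likelihood(meas, ups, meas$v_grid[iv])
  dim(lik) <- c(n, n * nv)
  # trapezoidal weights over the (possibly non-uniform) v grid
  dv <- diff(meas$v_grid)
  trap_w <- c(dv / 2, 0) + c(0, dv / 2)
  structure(list(grid = grid, meas = meas, model_family = model_family,
                 lik = lik, trap_w = trap_w, n = n, nv = nv),
            class = "eid_engine")
}

#' @export
print.eid_engine <- function(x, ...) {
  cat(sprintf("eid_engine: %d theta/x points x %d V points (sigma2 = %.3g)\n",
              x$n, x$nv, x$meas$sigma2))
  invisible(x)
}

# Core EID computation against a precomputed engine; returns the raw and
# normalized profiles for a mass vector.
compute_eid <- function(engine, mass) {
  n <- engine$n
  nv <- engine$nv
  w <- engine$lik * mass                 # joint p(v | theta, x) p(theta)
  z <- .colSums(w, n, n * nv)            # marginal p(v | x)
  post <- w / rep(z, each = n)           # hypothetical posteriors
  pl <- post * log(post)
  pl[!is.finite(pl)] <- 0                # 0 log 0 := 0 (mass-zero thetas)
  h <- -.colSums(pl, n, n * nv)          # posterior entropies S[p_{t+1}]
  pos <- mass > 0
  s0 <- -sum(mass[pos] * log(mass[pos])) # prior entropy S[p_t]
  zm <- matrix(z, n, nv)                 # rows: x, cols: v
  dsm <- matrix(s0 - h, n, nv)
  tw <- engine$trap_w
  norm <- drop(zm %*% tw)                # mass of p(V | x) inside [0, 1]
  raw <- drop((zm * dsm) %*% tw) / norm  # E[dS | x], V restricted to [0, 1]
  clipped <- pmax(raw, 0)
  tot <- sum(clipped)
  normalized <- if (tot > 0) clipped / tot else rep(1 / n, n)
  list(raw_eid = raw, normalized = normalized)
}

#' Expected Information Density of candidate call durations
#'
#' For each candidate duration `x` on the belief's grid, computes the
#' expected reduction in Shannon entropy of the belief after a hypothetical
#' call of that duration:
#' \deqn{EID(x) = \int_0^1 p(V | x)\, [S[p_t] - S[p_{t+1}(\theta | V, x)]]\, dV,}
#' where the hypothetical posterior comes from [hypothetical_posterior()]
#' and `p(V | x)` from [measurement_marginal()]. The integral is evaluated
#' by the trapezoidal rule on the measurement grid, with `p(V | x)`
#' renormalized over `[0, 1]` so the profile remains a proper expectation.
#' Negative raw values (quadrature artifacts, or a belief with nothing left
#' to learn) are clipped at zero before normalization; an all-zero clipped
#' profile falls back to a uniform sampling distribution.
#'
#' @param belief Current `belief`.
#' @param meas A [measurement_model()].
#' @param model_family An [observation_model()].
#' @param engine Optional [eid_engine()] matching the three arguments;
#'   pass one to amortize the likelihood tabulation across calls.
#' @return An object of class `eid_profile`: list with the `grid`,
#'   `raw_eid` (expected entropy reduction in nats per candidate `x`) and
#'   `normalized` (probability mass per candidate, summing to one).
#' @examples
#' prof <- expected_information_density(uniform_belief(duration_grid(n_points = 41)),
#'                                      measurement_model(n_v = 21),
#'                                      observation_model(grid = duration_grid(n_points = 41)))
#' prof$grid$points[which.max(prof$raw_eid)]
#' @export
expected_information_density <- function(belief, meas, model_family,
                                         engine = NULL) {
  stopifnot(inherits(belief, "belief"))
  if (is.null(engine)) {
    engine <- eid_engine(belief$grid, meas, model_family)
  } else {
    stopifnot(inherits(engine, "eid_engine"))
    if (engine$n != belief$grid$n_points)
      stop("expected_information_density: engine grid does not match belief grid")
  }
  res <- compute_eid(engine, belief$mass)
  structure(list(grid = belief$grid, raw_eid = res$raw_eid,
                 normalized = res$normalized),
            class = "eid_profile")
}

#' @export
print.eid_profile <- function(x, ...) {
  i <- which.max(x$raw_eid)
  cat(sprintf("eid_profile on %d durations; peak raw EID %.4g nats at x = %.3g s\n",
              x$grid$n_points, x$raw_eid[i], x$grid$points[i]))
  invisible(x)
}

#' @export
plot.eid_profile <- function(x, which = c("normalized", "raw"), ...) {
  which <- match.arg(which)
  y <- if (which == "raw") x$raw_eid else x$normalized
  graphics::plot(x$grid$points, y, type = "l",
                 xlab = "call duration (s)",
                 ylab = if (which == "raw") "EID (nats)" else "sampling probability",
                 ...)
  invisible(x)
}
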