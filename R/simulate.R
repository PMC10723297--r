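#' Configuration of a dyadic vocal-exchange simulation
#'
#' Two identical agents exchange calls for `n_iterations` rounds. On its
#' turn each agent (with probability `vocalize_prob`, default always)
#' derives a sampling distribution over call durations from its current
#' belief according to the chosen policy, emits a call, hears whether the
#' partner responds (a Bernoulli draw from the ground-truth response law),
#' and updates its belief. Session time advances by exponential gaps with
#' mean `inter_call_interval_s`, matching the roughly 10-second contact-call
#' rhythm of isolated marmosets.
#'
#' @param policy One of `"accommodation"` (sample the duration from the
#'   belief itself), `"active_sampling"` (sample from the normalized
#'   Expected Information Density, recomputed after every belief update) or
#'   `"uniform_baseline"` (uniform over the grid; a plumbing control, not a
#'   model of behavior).
#' @param n_iterations Number of exchange rounds (each gives both agents a
#'   turn).
#' @param observation Ground-truth [observation_model()].
#' @param measurement [measurement_model()] used by the active policy.
#' @param vocalize_prob Probability that an agent vocalizes on its turn.
#' @param inter_call_interval_s Mean gap between successive calls, seconds.
#' @param duration_jitter If `TRUE` (default), the emitted duration adds
#'   uniform jitter within half a grid step of the sampled grid point
#'   (clamped to the grid range), so realized call durations are continuous
#'   as real calls are; the grid remains the numerical support of the
#'   belief and of the policy distributions.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @param n_snapshots Number of evenly spaced iterations at which both
#'   agents' beliefs are recorded.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(policy = c("accommodation", "active_sampling",
                                         "uniform_baseline"),
                              n_iterations = 1500,
                              observation = observation_model(),
                              measurement = measurement_model(),
                              vocalize_prob = 1.0,
                              inter_call_interval_s = 10,
                              duration_jitter = TRUE,
                              seed = 1L,
                              n_snapshots = 5L) {
  policy <- match.arg(policy)
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("simulation_config: n_iterations must be >= 1")
  stopifnot(inherits(observation, "observation_model"),
            inherits(measurement, "measurement_model"))
  if (!is.numeric(vocalize_prob) || vocalize_prob <= 0 || vocalize_prob > 1)
    stop("simulation_config: vocalize_prob must lie in (0, 1]")
  if (!is.numeric(inter_call_interval_s) || inter_call_interval_s <= 0)
    stop("simulation_config: inter_call_interval_s must be positive")
  structure(list(policy = policy, n_iterations = n_iterations,
                 observation = observation, measurement = measurement,
                 vocalize_prob = vocalize_prob,
                 inter_call_interval_s = inter_call_interval_s,
                 duration_jitter = isTRUE(duration_jitter),
                 seed = as.integer(seed),
                 n_snapshots = as.integer(n_snapshots)),
            class = "simulation_config")
}

#' Draw a call duration under a policy
#'
#' Accommodation samples the duration from the belief itself
#' (`x ~ p_t(theta)`); active sampling draws from the normalized Expected
#' Information Density; the uniform baseline draws any grid point with
#' equal probability. The returned duration is always a grid point.
#'
#' @param policy Policy name, as in [simulation_config()].
#' @param belief The agent's current `belief`.
#' @param eid An `eid_profile` (required for `"active_sampling"`).
#' @return A single duration (seconds).
#' @export
choose_duration <- function(policy, belief, eid = NULL) {
  stopifnot(inherits(belief, "belief"))
  pts <- belief$grid$points
  w <- switch(policy,
    accommodation = belief$mass,
    active_sampling = {
      if (is.null(eid) || !inherits(eid, "eid_profile"))
        stop("choose_duration: the active_sampling policy requires an eid_profile")
      eid$normalized
    },
    uniform_baseline = rep(1, length(pts)),
    stop("choose_duration: unknown policy '", policy, "'")
  )
  pts[sample.int(length(pts), 1L, prob = w)]
}

#' Sample whether a call receives a response
#'
#' Bernoulli draw with success probability `Upsilon(theta_true, x)` from
#' the ground-truth response law.
#'
#' @param model An [observation_model()].
#' @param x Call duration.
#' @return Logical flag.
#' @export
sample_response <- function(model, x) {
  stats::runif(1L) < response_likelihood(model, x)
}

#' Run a dyadic vocal-exchange simulation
#'
#' Executes the exchange loop described in [simulation_config()]: per
#' iteration, agent 1 then agent 2 takes a turn; on each turn the caller's
#' policy distribution is computed from its current belief (the Expected
#' Information Density is recomputed after every update for the active
#' policy), a duration is drawn, the partner's response is drawn from the
#' ground-truth response law, and only the caller's belief is updated. Both
#' agents start from uniform beliefs. The random-number stream is a single
#' seeded generator with draws interleaved in a fixed order (per turn:
#' vocalize gate if `vocalize_prob < 1`, duration, within-cell jitter if
#' enabled, inter-call gap, response), so sessions are exactly
#' reproducible.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_session`: list with `calls` (a
#'   data frame of `iteration`, `agent`, `time_s`, `duration`, `responded`,
#'   sorted by time), `belief_snapshots` (per-agent mass matrices, one
#'   column per checkpoint), `snapshot_iterations`, `final_beliefs` and the
#'   `config`.
#' @examples
#' s <- run_simulation(simulation_config("accommodation", n_iterations = 50, seed = 7))
#' nrow(s$calls)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  obs <- config$observation
  grid <- obs$grid
  active <- config$policy == "active_sampling"
  engine <- if (active) eid_engine(grid, config$measurement, obs) else NULL

  beliefs <- list(uniform_belief(grid), uniform_belief(grid))
  n <- config$n_iterations
  snap_at <- unique(round(seq(1L, n, length.out = max(1L, config$n_snapshots))))
  snaps <- list(matrix(NA_real_, grid$n_points, length(snap_at)),
                matrix(NA_real_, grid$n_points, length(snap_at)))

  max_calls <- 2L * n
  it <- integer(max_calls); ag <- integer(max_calls)
  tm <- numeric(max_calls); du <- numeric(max_calls); rs <- logical(max_calls)
  k <- 0L
  t_now <- 0
  rate <- 1 / config$inter_call_interval_s
  gate <- config$vocalize_prob < 1

  for (i in seq_len(n)) {
    for (agent in 1:2) {
      if (gate && stats::runif(1L) >= config$vocalize_prob) next
      b <- beliefs[[agent]]
      eid <- if (active)
        expected_information_density(b, config$measurement, obs, engine = engine)
      x <- choose_duration(config$policy, b, eid)
      if (config$duration_jitter) {
        half <- grid$step / 2
        x <- min(max(x + stats::runif(1L, -half, half), grid$lo + 1e-9), grid$hi)
      }
      t_now <- t_now + stats::rexp(1L, rate)
      r <- sample_response(obs, x)
      beliefs[[agent]] <- update_belief_with_response(b, obs, x, r)
      k <- k + 1L
      it[k] <- i; ag[k] <- agent; tm[k] <- t_now; du[k] <- x; rs[k] <- r
    }
    j <- match(i, snap_at)
    if (!is.na(j)) {
      snaps[[1]][, j] <- beliefs[[1]]$mass
      snaps[[2]][, j] <- beliefs[[2]]$mass
    }
  }

  calls <- data.frame(iteration = it[seq_len(k)], agent = ag[seq_len(k)],
                      time_s = tm[seq_len(k)], duration = du[seq_len(k)],
                      responded = rs[seq_len(k)])
  structure(list(calls = calls, belief_snapshots = snaps,
                 snapshot_iterations = snap_at,
                 final_beliefs = beliefs, config = config),
            class = "simulated_session")
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("simulated_session: policy %s, %d calls over %.1f s (seed %d)\n",
              x$config$policy, nrow(x$calls), max(x$calls$time_s), x$config$seed))
  cat(sprintf("  agent belief modes: %.3g s / %.3g s\n",
              belief_mode(x$final_beliefs[[1]]), belief_mode(x$final_beliefs[[2]])))
  invisible(x)
}

#' Convert a simulated session to a call table
#'
#' Produces the same delimited-table shape consumed by the empirical
#' pipeline ([duration_clusters()], [binned_cv()], ...), so simulations and
#' recorded sessions flow through identical code.
#'
#' @param session A `simulated_session`.
#' @param session_id Session identifier used in the table.
#' @return A `call_table` data frame with columns `session_id`,
#'   `caller_id`, `onset_s`, `duration_s`, `responded`.
#' @export
as_call_table <- function(session, session_id = "sim1") {
  stopifnot(inherits(session, "simulated_session"))
  call_table(data.frame(
    session_id = session_id,
    caller_id = paste0("agent", session$calls$agent),
    onset_s = session$calls$time_s,
    duration_s = session$calls$duration,
    responded = session$calls$responded
  ))
}
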