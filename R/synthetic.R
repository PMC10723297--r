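#' Configuration of the synthetic two-caller session generator
#'
#' Generates session tables with the statistical structure the analysis
#' pipeline assumes: two callers alternating with roughly exponential
#' inter-call gaps, call durations drawn from a Gaussian mixture whose
#' component weights drift linearly from an "early" vector (favoring long,
#' variable calls) to a "late" vector (favoring short, stereotyped calls),
#' and partner responses drawn from a Gaussian-shaped function of duration
#' with an optional additive increase over the session. Defaults: a
#' 30-minute session, 10-second mean call interval, three duration
#' clusters, and a response law peaking at 0.5 for 1.5-second calls.
#'
#' The default drift moves weight from a broad early mixture (long calls
#' common) onto the middle, response-optimal cluster, emptying both
#' extremes: that is what shrinks the coefficient of variation of durations
#' over the session. Concentrating on the *short* cluster instead would
#' drive the mean down faster than the spread and make the CV rise, the
#' opposite of the long-to-stereotyped pattern the generator emulates.
#'
#' @param session_length_s Session length, seconds.
#' @param mean_interval_s Mean inter-call gap, seconds.
#' @param clusters Data frame with columns `mean` and `sd` (seconds), one
#'   row per duration cluster.
#' @param weight_early,weight_late Cluster weights at session start and
#'   end; each must sum to one. Weights at time `t` interpolate linearly.
#' @param response_optimum,response_spread,response_peak Parameters of the
#'   Gaussian response law (optimum duration s, width s, peak probability).
#' @param response_trend Additive increase in response probability from
#'   session start to end (non-negative; probabilities are capped at 1).
#' @param syllable_probs Probabilities that a call is written as 1, 2 or 3
#'   syllables with intra-call gaps under 1 s.
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(session_length_s = 1800,
                         mean_interval_s = 10,
                         clusters = data.frame(mean = c(0.5, 1.5, 3.5),
                                               sd = c(0.15, 0.15, 0.15)),
                         weight_early = c(0.30, 0.35, 0.35),
                         weight_late = c(0.10, 0.85, 0.05),
                         response_optimum = 1.5,
                         response_spread = 0.9,
                         response_peak = 0.5,
                         response_trend = 0.15,
                         syllable_probs = c(0.6, 0.3, 0.1),
                         seed = 1L) {
  if (session_length_s <= 0) stop("synth_config: session_length_s must be positive")
  if (mean_interval_s <= 0) stop("synth_config: mean_interval_s must be positive")
  clusters <- as.data.frame(clusters)
  if (!all(c("mean", "sd") %in% names(clusters)))
    stop("synth_config: clusters needs columns mean and sd")
  if (any(clusters$sd <= 0)) stop("synth_config: cluster sds must be positive")
  k <- nrow(clusters)
  if (length(weight_early) != k || length(weight_late) != k)
    stop("synth_config: weight vectors must match the number of clusters")
  if (any(weight_early < 0) || any(weight_late < 0) ||
      abs(sum(weight_early) - 1) > 1e-9 || abs(sum(weight_late) - 1) > 1e-9)
    stop("synth_config: weights must be non-negative and sum to 1")
  if (response_peak <= 0 || response_peak > 1)
    stop("synth_config: response_peak must lie in (0, 1]")
  if (response_spread <= 0) stop("synth_config: response_spread must be positive")
  if (response_trend < 0)
    stop("synth_config: response_trend must be non-negative (a negative trend can drive response probabilities below 0)")
  if (length(syllable_probs) != 3L || any(syllable_probs < 0) ||
      sum(syllable_probs) <= 0)
    stop("synth_config: syllable_probs must be 3 non-negative values")
  structure(list(session_length_s = session_length_s,
                 mean_interval_s = mean_interval_s, clusters = clusters,
                 weight_early = weight_early, weight_late = weight_late,
                 response_optimum = response_optimum,
                 response_spread = response_spread,
                 response_peak = response_peak,
                 response_trend = response_trend,
                 syllable_probs = syllable_probs / sum(syllable_probs),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("synth_config: %.0f s session, %d duration clusters, response peak %.2g at %.2g s (trend +%.2g)\n",
              x$session_length_s, nrow(x$clusters), x$response_peak,
              x$response_optimum, x$response_trend))
  invisible(x)
}

#' Generate one synthetic two-caller session
#'
#' Draws a full session under a [synth_config()]: onsets from exponential
#' gaps alternating between callers `A` and `B` (with a floor keeping a
#' caller's consecutive calls more than the 1-second merge gap apart, so
#' segmentation round-trips exactly), durations from the time-weighted
#' cluster mixture (truncated to positive values), responses from the
#' Gaussian response law plus trend, and a syllable-level rendering of each
#' call with intra-call gaps strictly under 1 second.
#'
#' @param config A [synth_config()].
#' @param session_id Session identifier.
#' @param caller_ids Two caller identifiers.
#' @return List with `syllables` (a [syllable_table()]), `calls` (a
#'   [call_table()] with `responded` set), and `ground_truth` (data frame
#'   of per-call generating cluster and realized response probability,
#'   with the config attached as attribute `config`).
#' @examples
#' s <- generate_session(synth_config(seed = 42))
#' table(s$ground_truth$cluster)
#' @export
generate_session <- function(config, session_id = "synth1",
                             caller_ids = c("A", "B")) {
  stopifnot(inherits(config, "synth_config"))
  if (length(caller_ids) != 2L || caller_ids[1L] == caller_ids[2L])
    stop("generate_session: need two distinct caller ids")
  set.seed(config$seed)
  T_len <- config$session_length_s
  rate <- 1 / config$mean_interval_s
  k <- nrow(config$clusters)

  onset <- numeric(0); caller <- integer(0); dur <- numeric(0)
  comp <- integer(0); presp <- numeric(0); resp <- logical(0)
  last_end <- c(-Inf, -Inf)
  t_now <- stats::rexp(1L, rate)
  who <- 1L
  while (t_now <= T_len) {
    # keep a caller's calls non-overlapping and un-mergeable (> 1 s apart)
    t_call <- max(t_now, last_end[who] + 1.05)
    if (t_call > T_len) break
    u <- t_call / T_len
    w <- (1 - u) * config$weight_early + u * config$weight_late
    ci <- sample.int(k, 1L, prob = w)
    d <- stats::rnorm(1L, config$clusters$mean[ci], config$clusters$sd[ci])
    while (d <= 0.05)
      d <- stats::rnorm(1L, config$clusters$mean[ci], config$clusters$sd[ci])
    p <- config$response_peak *
      exp(-(d - config$response_optimum)^2 / (2 * config$response_spread^2)) +
      config$response_trend * u
    p <- min(p, 1)
    onset <- c(onset, t_call); caller <- c(caller, who); dur <- c(dur, d)
    comp <- c(comp, ci); presp <- c(presp, p)
    resp <- c(resp, stats::runif(1L) < p)
    last_end[who] <- t_call + d
    who <- 3L - who
    t_now <- t_now + stats::rexp(1L, rate)
  }
  if (!length(onset)) stop("generate_session: session produced no calls")

  calls <- call_table(data.frame(session_id = session_id,
                                 caller_id = caller_ids[caller],
                                 onset_s = onset, duration_s = dur,
                                 responded = resp))
  syl <- split_into_syllables(onset, dur, config$syllable_probs)
  syllables <- syllable_table(data.frame(session_id = session_id,
                                         caller_id = caller_ids[rep(caller, syl$per_call)],
                                         onset_s = syl$onset,
                                         offset_s = syl$offset))
  gt <- data.frame(call = seq_along(onset), caller_id = caller_ids[caller],
                   onset_s = onset, duration_s = dur, cluster = comp,
                   p_response = presp, responded = resp)
  attr(gt, "config") <- config
  list(syllables = syllables, calls = calls, ground_truth = gt)
}

# Render each call as 1-3 syllables whose intra-call gaps are strictly
# < 1 s and whose overall span equals the call exactly. Calls too short to
# split cleanly stay single-syllable.
split_into_syllables <- function(onset, dur, probs) {
  on_out <- list(); off_out <- list(); per_call <- integer(length(onset))
  for (i in seq_along(onset)) {
    ns <- sample.int(3L, 1L, prob = probs)
    cuts <- NULL
    if (ns > 1L) {
      for (try in seq_len(20L)) {
        cand <- sort(stats::runif(2L * (ns - 1L), 0, dur[i]))
        seg <- diff(c(0, cand, dur[i]))
        gaps <- seg[seq(2L, length(seg) - 1L, by = 2L)]
        sylls <- seg[seq(1L, length(seg), by = 2L)]
        if (all(gaps > 0.01) && all(gaps < 0.99) && all(sylls > 0.02)) {
          cuts <- cand
          break
        }
      }
    }
    if (is.null(cuts)) {
      on_out[[i]] <- onset[i]; off_out[[i]] <- onset[i] + dur[i]
      per_call[i] <- 1L
    } else {
      b <- c(0, cuts, dur[i])
      s_on <- b[seq(1L, length(b) - 1L, by = 2L)]
      s_off <- b[seq(2L, length(b), by = 2L)]
      on_out[[i]] <- onset[i] + s_on; off_out[[i]] <- onset[i] + s_off
      per_call[i] <- length(s_on)
    }
  }
  list(onset = unlist(on_out), offset = unlist(off_out), per_call = per_call)
}

#' Generate a cohort of synthetic sessions
#'
#' Produces `n_pairs` independent sessions with distinct caller ids and a
#' per-pair jitter of the duration-cluster means, mimicking a small colony
#' of pairs recorded under the same protocol. With `jitter_sd = 0` every
#' pair shares the ground-truth parameters exactly.
#'
#' @param config Base [synth_config()].
#' @param n_pairs Number of pairs / sessions.
#' @param seed Integer seed governing both the jitter and per-session seeds.
#' @param jitter_sd Standard deviation (seconds) of the Gaussian jitter
#'   added to each pair's cluster means.
#' @return List of session objects as returned by [generate_session()].
#' @export
generate_cohort <- function(config, n_pairs = 3, seed = config$seed,
                            jitter_sd = 0.05) {
  stopifnot(inherits(config, "synth_config"))
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) stop("generate_cohort: n_pairs must be >= 1")
  set.seed(seed)
  jit <- matrix(stats::rnorm(n_pairs * nrow(config$clusters), 0, jitter_sd),
                n_pairs)
  sess_seeds <- sample.int(.Machine$integer.max, n_pairs)
  lapply(seq_len(n_pairs), function(i) {
    cfg <- config
    cfg$clusters$mean <- pmax(0.1, cfg$clusters$mean + jit[i, ])
    cfg$seed <- sess_seeds[i]
    generate_session(cfg, session_id = paste0("pair", i),
                     caller_ids = paste0("P", i, c("A", "B")))
  })
}

#' Pool the call tables of several sessions
#'
#' @param sessions List of session objects from [generate_session()] /
#'   [generate_cohort()], or of `call_table`s.
#' @return A single pooled [call_table()].
#' @export
bind_call_tables <- function(sessions) {
  tabs <- lapply(sessions, function(s)
    if (is.data.frame(s)) s else s$calls)
  call_table(do.call(rbind, lapply(tabs, as.data.frame)))
}
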