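test_that("policy distributions drive duration sampling correctly", {
  g <- duration_grid(n_points = 11)
  # point-mass belief: accommodation is deterministic
  m <- rep(0, 11); m[4] <- 1
  pm <- belief(g, m)
  set.seed(1)
  expect_true(all(replicate(20, choose_duration("accommodation", pm)) ==
                    g$points[4]))

  # uniform belief: every grid point drawn with frequency 1/n within a
  # binomial bound over 1e5 draws
  set.seed(42)
  draws <- replicate(1e5, choose_duration("accommodation", uniform_belief(g)))
  freq <- table(factor(draws, levels = g$points)) / 1e5
  p <- 1 / 11
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / 1e5) + 1e-12))

  # active sampling with a uniform EID profile: chi-squared uniformity
  prof <- structure(list(grid = g, raw_eid = rep(1, 11),
                         normalized = rep(1 / 11, 11)), class = "eid_profile")
  set.seed(7)
  draws2 <- replicate(1e5, choose_duration("active_sampling", uniform_belief(g), prof))
  counts <- table(factor(draws2, levels = g$points))
  expect_gt(chisq.test(counts)$p.value, 0.01)

  expect_error(choose_duration("active_sampling", uniform_belief(g)),
               "requires an eid_profile")
})

test_that("responses are Bernoulli draws from the ground-truth law", {
  m <- observation_model()
  set.seed(5)
  rate_peak <- mean(replicate(1e5, sample_response(m, 1.5)))
  expect_equal(rate_peak, 0.5, tolerance = 0.01)
  set.seed(5)
  rate_far <- mean(replicate(2e4, sample_response(m, 5)))
  expect_lt(rate_far, 0.005)  # Upsilon(1.5, 5) ~ 2.6e-4
  tiny <- observation_model(v_max = 1e-12)
  set.seed(5)
  expect_false(any(replicate(1e3, sample_response(tiny, 1.5))))
})

test_that("the exchange loop is reproducible and structurally correct", {
  cfg <- simulation_config("accommodation", n_iterations = 1, seed = 3)
  s1 <- run_simulation(cfg)
  expect_equal(nrow(s1$calls), 2L)          # one call per agent per iteration
  expect_equal(s1$calls$agent, c(1L, 2L))

  cfg2 <- simulation_config("accommodation", n_iterations = 120, seed = 9)
  a <- run_simulation(cfg2)
  b <- run_simulation(cfg2)
  expect_identical(a$calls, b$calls)
  expect_identical(a$final_beliefs, b$final_beliefs)
  expect_true(all(diff(a$calls$time_s) > 0))
  expect_true(all(a$calls$duration >= 0 & a$calls$duration <= 5))

  # different seed, different session
  c2 <- run_simulation(simulation_config("accommodation", n_iterations = 120,
                                         seed = 10))
  expect_false(identical(a$calls$duration, c2$calls$duration))

  # vocalize_prob gates turns
  set.seed(NULL)
  gated <- run_simulation(simulation_config("accommodation", n_iterations = 300,
                                            vocalize_prob = 0.5, seed = 4))
  expect_lt(nrow(gated$calls), 450)
  expect_gt(nrow(gated$calls), 150)
})

test_that("belief entropy decreases over a session for every policy", {
  g <- duration_grid(n_points = 41)
  ent <- function(m) { p <- m[m > 0]; -sum(p * log(p)) }
  for (pol in c("accommodation", "active_sampling", "uniform_baseline")) {
    drop_seen <- vapply(1:5, function(sd) {
      cfg <- simulation_config(pol, n_iterations = 80,
                               observation = observation_model(grid = g),
                               measurement = measurement_model(n_v = 21),
                               seed = sd, n_snapshots = 2)
      s <- run_simulation(cfg)
      first <- ent(s$belief_snapshots[[1]][, 1])
      last <- ent(s$belief_snapshots[[1]][, 2])
      last < first
    }, logical(1))
    expect_true(mean(drop_seen) == 1, label = paste("entropy drop under", pol))
  }
})

test_that("simulated sessions convert to the analysis table format", {
  s <- run_simulation(simulation_config("accommodation", n_iterations = 40, seed = 2))
  ct <- as_call_table(s)
  expect_s3_class(ct, "call_table")
  expect_setequal(unique(ct$caller_id), c("agent1", "agent2"))
  expect_equal(nrow(ct), nrow(s$calls))
  expect_false(anyNA(ct$responded))
})
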