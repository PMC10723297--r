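test_that("synthetic sessions are deterministic under a fixed seed", {
  cfg <- synth_config(seed = 77)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$syllables, b$syllables)
  expect_identical(a$ground_truth, b$ground_truth)
  # a different seed changes the realization
  c2 <- generate_session(synth_config(seed = 78))
  expect_false(identical(a$calls$duration_s, c2$calls$duration_s))
})

test_that("generated sessions have the advertised structure", {
  s <- generate_session(synth_config(seed = 5))
  ct <- s$calls
  expect_s3_class(ct, "call_table")
  expect_setequal(unique(ct$caller_id), c("A", "B"))
  expect_lte(max(ct$onset_s), 1800)
  # ~1800 s / 10 s mean gap
  expect_gt(nrow(ct), 100)
  expect_lt(nrow(ct), 300)
  # callers alternate, so within-caller calls never overlap
  for (cid in c("A", "B")) {
    d <- ct[ct$caller_id == cid, ]
    expect_true(all(d$onset_s[-1] - (d$onset_s[-nrow(d)] + d$duration_s[-nrow(d)]) > 1))
  }
  # one ground-truth record per call, clusters labelled
  expect_equal(nrow(s$ground_truth), nrow(ct))
  expect_true(all(s$ground_truth$cluster %in% 1:3))
  expect_true(all(s$ground_truth$p_response >= 0 & s$ground_truth$p_response <= 1))
})

test_that("syllable rendering round-trips through segment_calls", {
  s <- generate_session(synth_config(seed = 9))
  rebuilt <- segment_calls(s$syllables)
  rebuilt <- rebuilt[order(rebuilt$onset_s), ]
  orig <- s$calls[order(s$calls$onset_s), ]
  expect_equal(rebuilt$onset_s, orig$onset_s, tolerance = 1e-9)
  expect_equal(rebuilt$duration_s, orig$duration_s, tolerance = 1e-9)
  expect_equal(rebuilt$caller_id, orig$caller_id)
  # intra-call gaps are strictly below the merge threshold by construction
  expect_gte(nrow(s$syllables), nrow(s$calls))
})

test_that("three separated duration clusters are recovered from synthesis", {
  hits <- vapply(1:50, function(sd) {
    s <- generate_session(synth_config(seed = sd))
    rep <- duration_clusters(s$calls, seed = 1)
    rep$k_selected == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the generator realizes every assumption the pipeline tests", {
  s <- generate_session(synth_config(seed = 21))
  # decreasing CV: early long-call weight decays
  cv <- binned_cv(s$calls, n_bins = 6)
  n <- nrow(cv$bins)
  expect_lt(mean(cv$bins$cv[(n - 1):n]), mean(cv$bins$cv[1:2]))
  # unimodal response law: argmax bin near the configured optimum
  curve <- response_by_duration(s$calls, n_duration_bins = 10)
  expect_lt(abs(response_curve_argmax(curve) - 1.5), 1.0)
})

test_that("cohorts have independent pairs with optional parameter jitter", {
  cfg <- synth_config(seed = 3)
  coh <- generate_cohort(cfg, n_pairs = 3, seed = 3)
  expect_length(coh, 3L)
  pooled <- bind_call_tables(coh)
  expect_length(unique(pooled$caller_id), 6L)
  expect_length(unique(pooled$session_id), 3L)

  # zero jitter: all pairs share the generating cluster parameters
  coh0 <- generate_cohort(cfg, n_pairs = 2, seed = 4, jitter_sd = 0)
  m1 <- attr(coh0[[1]]$ground_truth, "config")$clusters$mean
  m2 <- attr(coh0[[2]]$ground_truth, "config")$clusters$mean
  expect_identical(m1, m2)

  # pooled population recovers the 3-cluster structure
  hits <- vapply(1:50, function(sd) {
    pooled <- bind_call_tables(generate_cohort(synth_config(seed = sd),
                                               n_pairs = 3, seed = sd))
    duration_clusters(pooled, seed = 1)$k_selected == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("infeasible synthesis configurations are rejected", {
  expect_error(synth_config(response_trend = -0.2), "non-negative")
  expect_error(synth_config(weight_early = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(synth_config(clusters = data.frame(mean = 1, sd = 0)), "positive")
  expect_error(synth_config(response_peak = 1.2), "response_peak")
})
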