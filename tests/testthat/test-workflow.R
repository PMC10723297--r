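test_that("configuration files merge over embedded defaults", {
  cfg <- read_run_config(NULL)
  expect_equal(cfg$sigma1, 0.9)
  expect_equal(cfg$v_max, 0.5)
  expect_equal(cfg$sigma2, 0.3)
  expect_equal(cfg$theta_true, 1.5)
  expect_equal(c(cfg$grid_lo, cfg$grid_hi), c(0, 5))

  dir <- withr::local_tempdir()
  p <- file.path(dir, "run.yaml")
  writeLines(c("policy: active_sampling", "n_iterations: 25", "seed: 9"), p)
  cfg2 <- read_run_config(p)
  expect_equal(cfg2$policy, "active_sampling")
  expect_equal(cfg2$n_iterations, 25)
  expect_equal(cfg2$sigma1, 0.9)  # untouched default

  writeLines("not_a_key: 1", p)
  expect_error(read_run_config(p), "unknown key")
})

test_that("cmd_simulate writes tables, snapshots and a complete run log", {
  dir <- withr::local_tempdir()
  res <- suppressMessages(
    cmd_simulate(list(n_iterations = 30L), out_dir = dir, seed = 4))
  tab <- read_call_table(file.path(dir, "calls.tsv"))
  expect_equal(nrow(tab), 60L)  # 2 calls per iteration at vocalize_prob 1
  expect_true(file.exists(file.path(dir, "beliefs_agent1.tsv")))
  expect_true(file.exists(file.path(dir, "beliefs_agent2.tsv")))
  log <- yaml::read_yaml(file.path(dir, "run_log.yaml"))
  expect_equal(log$seed, 4)
  expect_equal(log$sigma1, 0.9)

  # same seed, identical files
  dir2 <- withr::local_tempdir()
  suppressMessages(cmd_simulate(list(n_iterations = 30L), out_dir = dir2, seed = 4))
  expect_identical(readLines(file.path(dir, "calls.tsv")),
                   readLines(file.path(dir2, "calls.tsv")))
})

test_that("cmd_analyze runs the full pipeline and handles degenerate input", {
  dir <- withr::local_tempdir()
  s <- generate_session(synth_config(seed = 31))
  p <- file.path(dir, "calls.tsv")
  write_call_table(s$calls, p)
  reports <- suppressMessages(cmd_analyze(p, out_dir = dir,
                                          config = list(n_boot = 100L)))
  expect_true(file.exists(file.path(dir, "analysis_report.json")))
  expect_s3_class(reports$pooled$clustering, "clustering_report")
  expect_s3_class(reports$pooled$trend, "trend_report")
  expect_s3_class(reports$pooled$response_curve, "response_curve")
  # per-caller reports exist and skip dyadic statistics
  expect_null(reports$caller_A$trend)
  expect_s3_class(reports$caller_A$clustering, "clustering_report")

  # unset responded flags are filled in via the 12-s window, with a notice
  raw <- s$calls; raw$responded <- NA
  write_call_table(raw, p)
  expect_message(cmd_analyze(p, out_dir = dir, config = list(n_boot = 50L)),
                 "mark_responses")
})

test_that("reproduction scenarios run end to end and report their checks", {
  dir <- withr::local_tempdir()
  out <- suppressMessages(cmd_reproduce("fig4-trend", seed = 2, out_dir = dir))
  expect_true(file.exists(file.path(dir, "summary.txt")))
  txt <- readLines(file.path(dir, "summary.txt"))
  expect_true(any(grepl("slope", txt)))
  expect_true(any(grepl("result: (PASS|FAIL)", txt)))
  expect_true(out$pass)

  expect_error(suppressMessages(cmd_reproduce("no-such-thing", seed = 1,
                                              out_dir = dir)),
               "fig3-accommodation")
})

test_that("report JSON serialization covers every report class", {
  dir <- withr::local_tempdir()
  s <- generate_session(synth_config(seed = 13))
  rep <- list(clustering = duration_clusters(s$calls, seed = 1),
              cv = fit_sigmoid(binned_cv(s$calls, n_bins = 8)),
              trend = response_proportion_trend(s$calls, n_boot = 50, seed = 1),
              curve = response_by_duration(s$calls))
  p <- file.path(dir, "report.json")
  write_report_json(rep, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$clustering$k_selected, rep$clustering$k_selected)
  expect_equal(back$trend$p_value, rep$trend$p_value, tolerance = 1e-12)
  expect_named(back$cv$sigmoid$params,
               c("floor", "ceiling", "midpoint", "steepness"))
})
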