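test_that("the end-to-end run writes tables and a traceable manifest", {
  cfg <- tiny_config(T = 4, S = 2, demand_mean = 5, demand_sd = 1,
                     supply_mean = 8, supply_sd = 1, seed = 2)
  out <- tempfile()
  res <- run_base_case(cfg, out_dir = out, gap = 1e-6)
  expect_true(file.exists(file.path(out, "base_case.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 2L)
  expect_equal(man$status, "optimal")
  expect_true(man$validation_ok)
  expect_true(res$validation$ok)
  # rerun reproduces byte-identical KPI tables
  out2 <- tempfile()
  run_base_case(cfg, out_dir = out2, gap = 1e-6)
  expect_identical(readLines(file.path(out, "base_case.csv")),
                   readLines(file.path(out2, "base_case.csv")))
})

test_that("dry runs build but never solve", {
  cfg <- tiny_config(T = 3, S = 1)
  withr::with_envvar(c(PLATELETSC_PYTHON = "/nonexistent/python"), {
    res <- run_base_case(cfg, out_dir = tempfile(), dry_run = TRUE)
    expect_s3_class(res$model, "psc_model")   # no solver touched
  })
})

test_that("a malformed configuration fails before any output is written", {
  out <- tempfile()
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(horizon_days = 3), f)
  expect_error(run_base_case(f, out_dir = out), "hospitals")
  expect_false(dir.exists(out))
})

test_that("a degenerate one-window rolling horizon equals the single solve", {
  cfg <- tiny_config(T = 4, S = 2, demand_mean = 5, demand_sd = 1,
                     supply_mean = 8, supply_sd = 1, seed = 5)
  rh <- rolling_horizon(cfg, window_days = 4, implement_days = 4, gap = 1e-6)
  # the single window solved with the window seed, its orders executed
  # greedily on the held-out realization
  cfg_w <- scale_config(cfg, seed = cfg$seed + 1000L)
  sol <- optimize_network(cfg_w, gap = 1e-6)
  realization <- generate_scenarios(scale_config(cfg, n_scenarios = 1L,
                                                 seed = cfg$seed + 1L))
  rp <- replay_policy(list(ORHP = sol$first_stage$ORHP),
                      scenarios = realization,
                      config = scale_config(cfg, n_scenarios = 1L),
                      mode = "greedy")
  expect_equal(rh$realized_cost, rp$expected_cost)
})

test_that("rolling-horizon realized cost is bounded by the clairvoyant optimum", {
  cfg <- tiny_config(T = 6, S = 2, demand_mean = 5, demand_sd = 2,
                     supply_mean = 8, supply_sd = 1, seed = 8)
  rh <- rolling_horizon(cfg, window_days = 3, implement_days = 3, gap = 1e-6)
  expect_equal(dim(rh$decisions), c(1, 6))
  expect_length(rh$windows, 2L)
  # replaying the concatenated implemented orders reproduces the cost
  realization <- generate_scenarios(scale_config(cfg, n_scenarios = 1L,
                                                 seed = cfg$seed + 1L))
  rp <- replay_policy(list(ORHP = rh$decisions), scenarios = realization,
                      config = scale_config(cfg, n_scenarios = 1L),
                      mode = "greedy")
  expect_equal(rh$realized_cost, rp$expected_cost)
  # clairvoyant bound: solving against the realization itself can only do better
  cl_cfg <- scale_config(cfg, n_scenarios = 1L, seed = cfg$seed + 1L)
  clair <- optimize_network(cl_cfg, scenarios = realization, gap = 1e-6)
  expect_gte(rh$realized_cost, clair$objective - 1e-6)
})
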