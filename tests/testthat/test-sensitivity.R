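test_that("the cost-setting grid reproduces its defining rows", {
  base <- base_case_config()$costs
  expect_identical(build_cost_setting("CSET1", base), base)
  c3 <- build_cost_setting("CSET3", base)
  expect_equal(c3$blood_center$shortage, 1345)
  expect_equal(c3$hospital$shortage, base$hospital$shortage)
  c8 <- build_cost_setting("CSET8", base)
  expect_equal(c8$hospital$shortage, c(1625, 1625))
  c16 <- build_cost_setting("CSET16", base)
  expect_equal(c16$hospital$shortage, c(4875, 4875))
  c5 <- build_cost_setting("CSET5", base)
  expect_equal(c5$hospital$fixed_shipping, c(56.5, 112.5))
  c13 <- build_cost_setting("CSET13", base)
  expect_equal(c13$hospital$fixed_shipping, c(169.5, 337.5))
  c2 <- build_cost_setting("CSET2", base)
  expect_equal(c2$blood_center$holding, 54)
  expect_error(build_cost_setting("CSET99", base), "unknown")
})

test_that("raising any single cost never lowers the optimal objective", {
  cfg <- tiny_config(T = 4, S = 2, demand_mean = 6, demand_sd = 2,
                     supply_mean = 7, supply_sd = 2, seed = 21)
  scen <- generate_scenarios(cfg)
  base <- solve_model(build_model(cfg, scen), gap = 1e-6)
  for (id in c("CSET10", "CSET11", "CSET14", "CSET15", "CSET16")) {
    cfg2 <- cfg
    cfg2$costs <- build_cost_setting(id, cfg$costs)
    up <- solve_model(build_model(cfg2, scen), gap = 1e-6)
    expect_gte(up$objective_cents, base$objective_cents - 1e-6)
  }
})

test_that("a degenerate cv gives zero cost spread across scenarios", {
  cfg <- tiny_config(T = 3, S = 2, demand_mean = 5, supply_mean = 8)
  tab <- run_cv_sweep(cfg, cvs = 1e-9, seeds = cfg$seed, gap = 1e-6)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$std, 0)
})

test_that("identity cost setting reproduces the base run bit for bit", {
  cfg <- tiny_config(T = 4, S = 2, demand_mean = 6, demand_sd = 2,
                     supply_mean = 8, supply_sd = 1, seed = 33)
  tab <- run_cost_settings(cfg, setting_ids = "CSET1", seeds = 33, gap = 1e-6)
  scen <- generate_scenarios(scale_config(cfg, seed = 33))
  direct <- kpi_summary(solve_model(build_model(cfg, scen), gap = 1e-6))
  expect_equal(tab$cost, direct$entity$cost)
  expect_equal(tab$shortage, direct$entity$shortage)
})

test_that("sweeps report failed cells instead of aborting", {
  cfg <- tiny_config(T = 3, S = 1, demand_mean = 5, supply_mean = 8)
  # an unsolvable setting: impossible python interpreter
  withr::with_envvar(c(PLATELETSC_PYTHON = "/nonexistent/python"), {
    expect_warning(tab <- run_cv_sweep(cfg, cvs = c(0.1), seeds = 1),
                   "failed")
    expect_equal(nrow(tab), 0L)
    expect_s3_class(attr(tab, "failures"), "data.frame")
  })
})
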