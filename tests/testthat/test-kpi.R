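test_that("cost summaries follow the probability-weighted per-day definition", {
  # three scenarios with hand-set per-scenario daily costs 10/20/30 dollars
  T <- 2L; S <- 3L
  rp <- structure(list(
    expected_cost = 20 * T, expected_cost_cents = 2000 * T,
    per_scenario_cost = c(10, 20, 30) * T,
    shortage_hp = array(0, c(1, T, S)), expired_hp = array(0, c(1, T, S)),
    holding_hp = array(2, c(1, T, S)), purchased_hp = matrix(4, 1, T),
    shrbc = matrix(1, T, S), shebc = matrix(0, T, S),
    tshbc = matrix(1, T, S), expired_bc = matrix(0, T, S),
    holding_bc = matrix(3, T, S),
    entity_cost = array(1000 * rep(c(10, 20, 30), each = (1 + 1) * T) / 2,
                        c(2, T, S)),
    probabilities = rep(1 / 3, 3), mode = "audit"), class = "psc_replay")
  cfg <- tiny_config(T = T, S = S, demand_mean = 4, supply_mean = 4)
  sc <- generate_scenarios(cfg)
  k <- kpi_summary(rp, config = cfg, scenarios = sc)
  expect_equal(unname(k$overall["average"]), 20)
  expect_equal(unname(k$overall["best"]), 10)
  expect_equal(unname(k$overall["worst"]), 30)
  expect_equal(unname(k$overall["std"]), sqrt(mean((c(10, 20, 30) - 20)^2)))
  expect_true(k$overall["best"] <= k$overall["average"])
  expect_true(k$overall["average"] <= k$overall["worst"])
  expect_equal(k$entity$holding, c(2, 3))
  expect_equal(k$entity$purchased[1], 4)
})

test_that("unit KPIs from the replay logs equal those from the solution arrays", {
  cfg <- tiny_config(T = 5, S = 2, K = 2, lt = c(1, 2), demand_mean = 6,
                     demand_sd = 2, supply_mean = 10, supply_sd = 2, seed = 9)
  sc <- generate_scenarios(cfg)
  sol <- solve_model(build_model(cfg, sc), gap = 1e-6)
  k <- kpi_summary(sol)
  ss <- sol$second_stage
  pb <- sc$probabilities
  for (kk in 1:2) {
    expect_equal(k$entity$shortage[kk],
                 sum(t(ss$SHHP[kk, , 1, ]) * pb) / cfg$horizon_days)
    expect_equal(k$entity$outdating[kk],
                 sum(t(ss$EXHP[kk, , 1, ]) * pb) / cfg$horizon_days)
    expect_equal(k$entity$purchased[kk], mean(sol$first_stage$ORHP[kk, ]))
  }
  expect_equal(k$entity$shortage[3],
               sum(t(ss$TSHBC) * pb) / cfg$horizon_days)
  # weighted per-scenario costs recompose to the objective
  rp <- replay_policy(sol)
  expect_equal(sum(pb * rp$per_scenario_cost), sol$objective)
})

test_that("all-zero flows give zero unit KPIs and fixed-cost-only summaries", {
  h <- hospital_config(1, 0, 1, dist_spec(0, 0), list())
  bc <- blood_center_config(1, 1, dist_spec(0, 0), list())
  cfg <- network_config(list(h), bc, tiny_costs(fixed_operating_hp = 7,
                                                fixed_operating_bc = 11),
                        horizon_days = 2, n_scenarios = 1)
  sc <- generate_scenarios(cfg)
  sol <- solve_model(build_model(cfg, sc))
  k <- kpi_summary(sol)
  expect_true(all(k$entity[, c("shortage", "outdating", "holding",
                               "purchased")] == 0))
  expect_equal(unname(k$overall["average"]), 0.18)  # (7 + 11) cents per day
  expect_equal(unname(k$overall["std"]), 0)
})

test_that("tables round-trip through CSV", {
  cfg <- tiny_config(T = 3, S = 2, demand_sd = 1, supply_sd = 1)
  sc <- generate_scenarios(cfg)
  sol <- solve_model(build_model(cfg, sc))
  k <- kpi_summary(sol)
  tab <- to_table(k, "base_case")
  expect_equal(names(tab), c("measure", "hospital_1", "blood_center"))
  d <- tempfile()
  p <- write_kpi(k, d, "t")
  back <- utils::read.csv(p)
  expect_equal(back$hospital_1, tab$hospital_1)
  expect_error(to_table(k, "nope"))
  # empty/overall-only structures still produce a header
  expect_s3_class(to_table(data.frame(), "cv_sweep"), "data.frame")
})
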