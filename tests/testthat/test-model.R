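# Small-instance tests of the stochastic program and its solver bridge.

test_that("an empty network incurs only fixed operating cost", {
  h <- hospital_config(1, 0, 1, dist_spec(0, 0), list())
  bc <- blood_center_config(1, 1, dist_spec(0, 0), list())
  cfg <- network_config(list(h), bc, tiny_costs(fixed_operating_hp = 7,
                                                fixed_operating_bc = 11),
                        horizon_days = 1, n_scenarios = 1)
  sc <- generate_scenarios(cfg)
  sol <- solve_model(build_model(cfg, sc))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_cents, 18)
  expect_equal(sol$mip_gap, 0)
  expect_true(all(sol$first_stage$ORHP == 0))
  expect_true(all(sol$second_stage$SHHP == 0))
})

test_that("model dimensions follow the network layout", {
  cfg <- tiny_config(T = 4, S = 2, K = 2, lt = c(1, 2), demand_sd = 1,
                     supply_sd = 1)
  sc <- generate_scenarios(cfg)
  m <- build_model(cfg, sc)
  d <- m$dims
  expect_equal(d$ages[[1]], 2:3)   # a 1-day lead time excludes age-1 shipments
  expect_equal(d$ages[[2]], 3L)    # a 2-day lead time allows only age 3
  expect_equal(m$nvar, d$ss0 + d$S * d$B)
  expect_error(build_model(cfg, generate_scenarios(tiny_config(T = 3, S = 2))),
               "dimensions")
})

test_that("zero-variance ample-stock network reaches the closed-form optimum", {
  # sd = 0, zero hospital lead time, supply >= demand, ample initial stock:
  # no shortage, no outdating, and cost = purchasing + holding + fixed
  cfg <- tiny_config(T = 4, S = 1, lt = 0, lt_bc = 1, demand_mean = 5,
                     supply_mean = 9, ini_h = list("2" = 5),
                     ini_bc = list("2" = 5))
  sc <- generate_scenarios(cfg)
  sol <- solve_model(build_model(cfg, sc), gap = 0)
  expect_equal(sum(sol$second_stage$SHHP), 0)
  expect_equal(sum(sol$second_stage$TSHBC), 0)
  expect_equal(sum(sol$second_stage$EXHP), 0)
  expect_equal(sum(sol$second_stage$EXBC), 0)
  rp <- replay_policy(sol)
  expect_equal(rp$expected_cost_cents, sol$objective_cents)
  # hand account: day-1 demand from hospital stock, day-2 demand from the
  # center's aged stock; purchases = demand not covered by initial stock.
  expect_equal(sum(sol$first_stage$ORHP), 15)
  hand <- 15 * 650 +                                      # purchases
    130 * sum(sol$second_stage$OHHP) +                    # hospital holding
    108 * (5 + sum(sol$second_stage$OHBC[-1, , ])) +      # center holding
    113 * sum(rowSums(sol$first_stage$BCTHP[1, , ]) > 0) +
    1125 * sum(plateletsc:::bc_arrivals(cfg, sc) > 0)
  expect_equal(sol$objective_cents, hand)
})

test_that("the optimizer never loses to a naive zero-order policy", {
  for (seed in c(5, 17)) {
    cfg <- random_instance(seed)
    sc <- generate_scenarios(cfg)
    sol <- solve_model(build_model(cfg, sc), gap = 1e-6)
    K <- length(cfg$hospitals)
    z <- replay_policy(list(ORHP = matrix(0, K, cfg$horizon_days)), sc, cfg,
                       mode = "greedy")
    expect_lte(sol$objective_cents, z$expected_cost_cents + 1e-6)
  }
})

test_that("review periods silence off-cycle orders", {
  cfg <- tiny_config(T = 6, S = 1, demand_mean = 5, supply_mean = 8)
  cfg$hospitals[[1]]$review_period_days <- 3L
  sc <- generate_scenarios(cfg)
  sol <- solve_model(build_model(cfg, sc))
  off <- setdiff(1:6, c(3, 6))
  expect_true(all(sol$first_stage$ORHP[1, off] == 0))
})

test_that("the LP relaxation is labelled and bounds the integer optimum", {
  cfg <- tiny_config(T = 4, S = 2, demand_sd = 2, supply_sd = 2)
  sc <- generate_scenarios(cfg)
  m <- build_model(cfg, sc)
  lp <- solve_model(m, relax = TRUE)
  ip <- solve_model(m, gap = 1e-6)
  expect_true(lp$relaxed)
  expect_false(ip$relaxed)
  expect_lte(lp$objective_cents, ip$objective_cents + 1e-6)
})

test_that("infeasible decision streams are rejected by the replay audit", {
  cfg <- tiny_config(T = 2, S = 1, demand_mean = 3, supply_mean = 0,
                     ini_bc = list())
  sc <- generate_scenarios(cfg)
  BCTHP <- array(0, c(1, 2, 3)); BCTHP[1, 1, 2] <- 5   # no age-2 stock exists
  expect_error(replay_policy(list(BCTHP = BCTHP), sc, cfg, mode = "audit"),
               "exceed available stock")
})
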