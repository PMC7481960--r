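test_that("degenerate distributions give constant scenarios", {
  cfg <- tiny_config(T = 3, S = 2, demand_mean = 200, supply_mean = 225)
  sc <- generate_scenarios(cfg)
  expect_true(all(sc$demand == 200))
  expect_true(all(sc$supply == 225))
  expect_equal(sum(sc$probabilities), 1)
})

test_that("sampled moments recover the specified distributions", {
  cfg <- base_case_config(horizon_days = 300, n_scenarios = 100, seed = 11)
  sc <- generate_scenarios(cfg)
  means <- c(apply(sc$demand, 1, mean), mean(sc$supply))
  sds <- c(apply(sc$demand, 1, stats::sd), stats::sd(sc$supply))
  spec_means <- c(200, 100, 225)
  spec_sds <- c(32, 16, 36)
  expect_true(all(abs(means - spec_means) / spec_means < 0.01))
  expect_true(all(abs(sds - spec_sds) / spec_sds < 0.10))
  # moment recovery within 3 standard errors on >= 10,000 draws
  se <- spec_sds / sqrt(300 * 100)
  expect_true(all(abs(means - spec_means) < 3 * se))
  expect_true(all(sc$demand >= 0) && all(sc$supply >= 0))
  expect_true(all(sc$demand == round(sc$demand)))
})

test_that("scenario generation is seed-deterministic and seed-sensitive", {
  cfg <- tiny_config(T = 5, S = 3, demand_sd = 2, supply_sd = 3, seed = 42)
  a <- generate_scenarios(cfg)
  b <- generate_scenarios(cfg)
  expect_identical(a$demand, b$demand)
  expect_identical(a$supply, b$supply)
  d <- generate_scenarios(cfg, seed = 43)
  expect_false(identical(a$demand, d$demand))
})

test_that("adding a hospital leaves existing entities' draws untouched", {
  cfg1 <- tiny_config(T = 6, S = 2, K = 1, lt = 1, demand_sd = 2, supply_sd = 3)
  cfg2 <- tiny_config(T = 6, S = 2, K = 2, lt = c(1, 1), demand_sd = 2,
                      supply_sd = 3)
  a <- generate_scenarios(cfg1)
  b <- generate_scenarios(cfg2)
  expect_identical(a$demand[1, , ], b$demand[1, , ])
  expect_identical(a$supply, b$supply)
})

test_that("scenario sets round-trip through long-format CSV", {
  cfg <- tiny_config(T = 4, S = 2, K = 2, lt = c(0, 1), demand_sd = 2,
                     supply_sd = 2)
  sc <- generate_scenarios(cfg)
  f <- tempfile(fileext = ".csv")
  write_scenarios(sc, f)
  back <- read_scenarios(f)
  expect_equal(back$demand, sc$demand, ignore_attr = TRUE)
  expect_equal(back$supply, sc$supply, ignore_attr = TRUE)
})

test_that("blood-center procurement accumulates onto review days", {
  cfg <- tiny_config(T = 6, S = 1, supply_mean = 10)
  cfg$blood_center$review_period_days <- 2L
  sc <- generate_scenarios(cfg)
  stream <- plateletsc:::bc_order_stream(cfg, sc)
  expect_equal(stream[, 1], c(0, 20, 0, 20, 0, 20))
  arr <- plateletsc:::bc_arrivals(cfg, sc)   # lead time 1: lagged by one day
  expect_equal(arr[, 1], c(0, 0, 20, 0, 20, 0))
})
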