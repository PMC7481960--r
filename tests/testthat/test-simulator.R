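test_that("fifo_issue drains oldest stock first", {
  r <- fifo_issue(c(0, 0, 0), numeric(3), 5)
  expect_equal(r$issued, c(0, 0, 0))
  expect_equal(r$unmet, 5)
  r <- fifo_issue(c("1" = 3, "2" = 4), c("3" = 5), 6)
  expect_equal(r$issued, c(3, 3, 0))
  expect_equal(r$leftover, c(0, 1, 5))
  expect_equal(r$unmet, 0)
})

test_that("fifo_issue matches the unit-by-unit greedy oracle on random stock", {
  set.seed(101)
  for (i in 1:200) {
    inv <- sample(0:6, 3, replace = TRUE)
    rec <- sample(0:6, 3, replace = TRUE)
    d <- sample(0:20, 1)
    got <- fifo_issue(inv, rec, d)
    want <- greedy_issue_oracle(inv + rec, d)
    expect_equal(got$issued, want$issued)
    expect_equal(got$leftover, want$leftover)
    expect_equal(got$unmet, want$unmet)
    # conservation: issued + leftover = available
    expect_equal(got$issued + got$leftover, inv + rec)
  }
})

test_that("a hospital day ages stock, expires age-1 leftovers and prices the events", {
  costs <- list(fixed_operating = 0, fixed_shipping = 113, purchase = 650,
                holding = 130, shortage = 3250, outdating = 650)
  r <- hospital_day_step(c(0, 7), numeric(3), 0, costs)
  expect_equal(r$state, c(7, 0))
  expect_equal(r$log$shortage, 0)
  expect_equal(r$log$expired, 0)
  expect_equal(unname(r$log$cost["holding"]), 7 * 130)
  r <- hospital_day_step(c(2, 0), numeric(3), 0, costs)
  expect_equal(r$log$expired, 2)
  expect_equal(unname(r$log$cost["outdating"]), 2 * 650)
  expect_equal(r$state, c(0, 0))
  # conservation: opening + received = issued + expired + closing
  set.seed(7)
  for (i in 1:50) {
    st <- sample(0:5, 2, TRUE); rec <- sample(0:5, 3, TRUE); d <- sample(0:12, 1)
    r <- hospital_day_step(st, rec, d, costs)
    expect_equal(sum(st) + sum(rec),
                 sum(r$log$issued) + r$log$expired + sum(r$state))
  }
})

test_that("blood-center day respects age/lead-time compatibility and FIFO order", {
  bcc <- list(fixed_operating = 0, fixed_shipping = 1125, holding = 108,
              shortage = 2690, outdating = 538, processing = 0)
  # no orders: age-1 stock expires
  r <- blood_center_day_step(c(4, 0), 0, orders = numeric(0), emergency = 0,
                             lead_times = integer(0), costs = bcc)
  expect_equal(r$log$expired, 4)
  expect_equal(r$state, c(0, 0))
  # only age-3 units can reach a two-day lead-time hospital
  r <- blood_center_day_step(c(0, 0), 10, orders = 6, emergency = 0,
                             lead_times = 2L, costs = bcc)
  expect_equal(r$shipments[1, ], c(0, 0, 6))
  expect_equal(r$shrbc, 0)
  expect_equal(r$log$regular_leftover, c(0, 0, 4))
  # audit mode rejects incompatible committed shipments
  expect_error(
    blood_center_day_step(c(5, 5), 5, shipments = matrix(c(1, 0, 0), 1),
                          emergency = 0, lead_times = 1L, costs = bcc),
    "compatibility")
})

test_that("two competing hospitals are served as well as any feasible allocation", {
  bcc <- list(fixed_operating = 0, fixed_shipping = 1125, holding = 108,
              shortage = 2690, outdating = 538, processing = 0)
  # stock {1:5, 2:5} carried + 5 fresh; hospitals with lead times 1 and 2
  r <- blood_center_day_step(c(5, 5), 5, orders = c(8, 7), emergency = 0,
                             lead_times = c(1L, 2L), costs = bcc)
  expect_equal(sum(r$shipments), 8 + 7)
  expect_equal(sum(r$shipments[, 1]), 0)    # age-1 would expire in transit
  # brute-force every feasible allocation (age 2 -> H1 only, age 3 -> both)
  feas <- expand.grid(a2 = 0:5, a31 = 0:5, a32 = 0:5)
  feas <- feas[feas$a31 + feas$a32 <= 5 & feas$a2 + feas$a31 <= 8 &
                 feas$a32 <= 7, ]
  ext <- (8 - (feas$a2 + feas$a31)) + (7 - feas$a32)
  expect_equal(sum(r$shrbc), min(ext))      # greedy minimizes external units
})

test_that("pro-rata emergency allocation uses largest remainders", {
  x <- plateletsc:::largest_remainder(c(5, 3), 5)
  expect_equal(sum(x), 5)
  expect_equal(x, c(3, 2))
  expect_equal(plateletsc:::largest_remainder(c(0, 0), 4), c(0, 0))
})

test_that("an all-zero order policy replays to the closed-form penalty cost", {
  cfg <- tiny_config(T = 3, S = 1, demand_mean = 4, supply_mean = 0,
                     ini_h = list(), ini_bc = list())
  sc <- generate_scenarios(cfg)
  rp <- replay_policy(list(ORHP = matrix(0, 1, 3)), sc, cfg, mode = "greedy")
  # every demanded unit is short at the hospital and cascades to the
  # blood-center emergency stage (priced under "total")
  expect_equal(rp$expected_cost_cents, 3 * 4 * (3250 + 2690))
  expect_equal(sum(rp$shortage_hp), 12)
  expect_equal(sum(rp$shebc), 12)
})

test_that("replay is deterministic", {
  cfg <- tiny_config(T = 5, S = 2, demand_sd = 2, supply_sd = 2, seed = 3)
  sc <- generate_scenarios(cfg)
  a <- replay_policy(list(ORHP = matrix(3, 1, 5)), sc, cfg, mode = "greedy")
  b <- replay_policy(list(ORHP = matrix(3, 1, 5)), sc, cfg, mode = "greedy")
  expect_identical(a$expected_cost_cents, b$expected_cost_cents)
  expect_identical(a$entity_cost, b$entity_cost)
})
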