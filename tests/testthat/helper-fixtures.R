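# small deterministic fixtures used across the suite

tiny_costs <- function(...) {
  defaults <- list(fixed_operating_hp = 0, fixed_shipping_hp = 113,
                   purchase_hp = 650, holding_hp = 130, shortage_hp = 3250,
                   outdating_hp = 650, fixed_operating_bc = 0,
                   fixed_shipping_bc = 1125, processing_bc = 538,
                   holding_bc = 108, shortage_bc = 2690, outdating_bc = 538)
  args <- utils::modifyList(defaults, list(...))
  do.call(cost_params, args)
}

tiny_config <- function(T = 4, S = 1, K = 1, lt = 0, lt_bc = 1,
                        demand_mean = 5, demand_sd = 0,
                        supply_mean = 8, supply_sd = 0,
                        ini_h = list("2" = 5), ini_bc = list("2" = 4),
                        seed = 1, ...) {
  hospitals <- lapply(seq_len(K), function(k)
    hospital_config(k, lead_time_days = if (length(lt) > 1) lt[k] else lt,
                    review_period_days = 1,
                    demand = dist_spec(demand_mean, demand_sd),
                    initial_inventory = ini_h))
  bc <- blood_center_config(lead_time_days = lt_bc, review_period_days = 1,
                            supply = dist_spec(supply_mean, supply_sd),
                            initial_inventory = ini_bc)
  network_config(hospitals, bc, tiny_costs(), horizon_days = T,
                 n_scenarios = S, seed = seed, ...)
}

# random small instance generator for property/oracle sweeps
random_instance <- function(seed, K_max = 2, T_max = 10, S_max = 3) {
  set.seed(seed)
  K <- sample(K_max, 1)
  T <- sample(3:T_max, 1)
  S <- sample(S_max, 1)
  hospitals <- lapply(seq_len(K), function(k)
    hospital_config(k, lead_time_days = sample(0:2, 1),
                    review_period_days = sample(1:2, 1),
                    demand = dist_spec(sample(3:10, 1), sample(0:3, 1)),
                    initial_inventory = list("1" = sample(0:3, 1),
                                             "2" = sample(0:6, 1))))
  bc <- blood_center_config(lead_time_days = sample(1:3, 1),
                            review_period_days = 1,
                            supply = dist_spec(sample(5:15, 1), sample(0:4, 1)),
                            initial_inventory = list("2" = sample(0:8, 1)))
  network_config(hospitals, bc, tiny_costs(), horizon_days = T,
                 n_scenarios = S, seed = seed)
}

# brute-force oldest-first issuing oracle: enumerate unit by unit
greedy_issue_oracle <- function(avail, demand) {
  issued <- numeric(3)
  for (i in seq_len(demand)) {
    l <- which(avail - issued > 0)[1]
    if (is.na(l)) break
    issued[l] <- issued[l] + 1
  }
  list(issued = issued, leftover = avail - issued, unmet = demand - sum(issued))
}

solver_available <- function() {
  p <- tryCatch(plateletsc:::find_python(), error = function(e) "")
  nzchar(p)
}
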