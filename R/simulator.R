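#' FIFO issuing of age-tracked platelet stock
#'
#' Issues `demand` units oldest-first (shelf life 1, then 2, then 3) from the
#' opening stock plus today's receipts.
#'
#' @param inventory Numeric length-3 vector of opening units by shelf life
#'   (position = days of remaining life); positions may be named `"1".."3"`.
#' @param receipts Numeric length-3 vector of units received today by shelf
#'   life (default none).
#' @param demand Nonnegative integer demand.
#' @return List with `issued` (length 3), `leftover` (length 3) and `unmet`.
#' @export
fifo_issue <- function(inventory = numeric(3), receipts = numeric(3), demand = 0) {
  avail <- as_age3(inventory) + as_age3(receipts)
  if (any(avail < 0) || demand < 0) stop("negative stock or demand", call. = FALSE)
  issued <- numeric(3)
  left <- demand
  for (l in 1:3) {
    issued[l] <- min(avail[l], left)
    left <- left - issued[l]
  }
  list(issued = issued, leftover = avail - issued, unmet = left)
}

as_age3 <- function(x) {
  out <- numeric(3)
  nm <- names(x)
  if (!is.null(nm) && all(nm %in% c("1", "2", "3"))) {
    for (i in seq_along(x)) out[as.integer(nm[i])] <- x[[i]]
  } else {
    out[seq_along(x)] <- unname(x)
  }
  out
}

hospital_costs <- function(config, k) {
  lapply(stats::setNames(nm = names(config$costs$hospital)),
         function(nm) hp_cost(config$costs, nm, k))
}

#' One day at a hospital
#'
#' Executes the daily event sequence: open with carried age-1/2 stock, charge
#' holding on it, receive today's delivery, observe demand, fulfill it FIFO
#' (oldest first), expire unused age-1 units at day end, and age the rest.
#' The unmet demand is the day's shortage (procured through an emergency
#' shipment, at the shortage/emergency-procurement cost per unit).
#'
#' @param state Length-2 vector: opening units with 1 and 2 days of life.
#' @param receipts Length-3 vector of delivered units by remaining life.
#' @param demand Nonnegative integer.
#' @param costs List with `fixed_operating`, `fixed_shipping`, `purchase`,
#'   `holding`, `shortage`, `outdating` (cents). Shipping is charged on the
#'   day the shipment leaves the blood center, not here; see [replay_policy()].
#' @param order Units ordered today (priced at the purchase cost).
#' @return List `state` (next day's opening length-2) and `log` (opening,
#'   received, issued, shortage, expired, closing, and cost components in
#'   cents).
#' @export
hospital_day_step <- function(state, receipts, demand, costs, order = 0) {
  state <- as_age3(c(state, 0))[1:2]
  rec <- as_age3(receipts)
  f <- fifo_issue(c(state, 0), rec, demand)
  expired <- f$leftover[1]
  nxt <- f$leftover[2:3]
  cost <- c(fixed = costs$fixed_operating,
            shipping = 0,
            purchase = costs$purchase * order,
            holding = costs$holding * sum(state),
            shortage = costs$shortage * f$unmet,
            outdating = costs$outdating * expired)
  list(state = nxt,
       log = list(opening = state, received = rec, issued = f$issued,
                  shortage = f$unmet, expired = expired, closing = nxt,
                  cost = cost))
}

#' One day at the blood center
#'
#' Opens with carried stock (holding charged on it), receives fresh
#' three-day-life units from the component labs, fulfills the hospitals'
#' regular orders, then their emergency (same-day shortage) orders from the
#' remaining stock, procures any residual regular shortfall externally
#' (`SHRBC`, shipped as three-day units), books unmet emergency demand as
#' `SHEBC`, expires age-1 leftovers and ages the rest.
#'
#' Two modes: with `shipments` given (an audit of a solved model), the
#' committed per-age shipments and the stock/external split of age-3
#' shipments are taken as inputs and checked against available stock; with
#' `orders` given (standalone policy evaluation), shipments are allocated
#' greedily age-ascending in hospital index order, subject to the
#' age/lead-time compatibility rule (shipped age must exceed the lead time,
#' or the units would expire in transit).
#'
#' @param state Length-2 opening stock (life 1, 2).
#' @param lab_receipts Fresh units arriving (three-day life).
#' @param orders Length-K regular order quantities (greedy mode).
#' @param shipments K x 3 matrix of committed shipments by age (audit mode).
#' @param hp3 Length-K stock-sourced part of each age-3 shipment (audit mode;
#'   defaults to the maximum the fresh pool allows, in hospital order).
#' @param emergency Length-K same-day emergency quantities (served pro rata
#'   with largest-remainder rounding when stock is insufficient).
#' @param lead_times Length-K hospital lead times.
#' @param costs Blood-center cost list (cents).
#' @param shortage_pricing `"regular"` prices only external regular
#'   procurement; `"total"` also prices unmet emergency units.
#' @return List `state`, `shipments` (K x 3), `shrbc` (length K), `shebc`,
#'   `emergency_issued` (length 3), `emergency_by_hospital` (length K), and
#'   `log` with units and cost components (cents).
#' @export
blood_center_day_step <- function(state, lab_receipts, orders = NULL,
                                  shipments = NULL, hp3 = NULL,
                                  emergency = 0, lead_times, costs,
                                  shortage_pricing = "regular") {
  state <- as_age3(c(state, 0))[1:2]
  K <- length(lead_times)
  pool <- c(state, lab_receipts)  # stock by shelf life 1..3
  if (is.null(shipments)) {
    if (is.null(orders)) stop("either orders or shipments must be given")
    shipments <- matrix(0, K, 3)
    remaining <- orders
    for (l in 1:3) for (k in seq_len(K)) {
      if (l <= lead_times[k]) next
      q <- min(pool[l], remaining[k])
      shipments[k, l] <- q
      pool[l] <- pool[l] - q
      remaining[k] <- remaining[k] - q
    }
    shrbc <- remaining                      # external, shipped as 3-day units
    shipments[, 3] <- shipments[, 3] + shrbc
    lfr <- pool
  } else {
    shipments <- matrix(shipments, K, 3)
    bad <- which(shipments > 1e-9 & outer(lead_times, 1:3, ">="), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("shipment of age-%d units to hospital %d violates the age/lead-time compatibility rule",
                   bad[1, 2], bad[1, 1]), call. = FALSE)
    if (is.null(hp3)) {
      hp3 <- numeric(K)
      fresh <- pool[3]
      for (k in seq_len(K)) { hp3[k] <- min(fresh, shipments[k, 3]); fresh <- fresh - hp3[k] }
    }
    shrbc <- shipments[, 3] - hp3
    if (any(shrbc < -1e-9)) stop("hp3 exceeds the committed age-3 shipments", call. = FALSE)
    lfr <- c(pool[1] - sum(shipments[, 1]), pool[2] - sum(shipments[, 2]),
             pool[3] - sum(hp3))
    if (any(lfr < -1e-9))
      stop(sprintf("committed shipments exceed available stock (age %d)",
                   which(lfr < -1e-9)[1]), call. = FALSE)
  }
  # emergency stage: FIFO over the regular-stage leftovers
  E <- sum(emergency)
  f <- fifo_issue(lfr, demand = E)
  served <- E - f$unmet
  emergency_by_hospital <- largest_remainder(emergency, served)
  shebc <- f$unmet
  lfe <- f$leftover
  expired <- lfe[1]
  nxt <- lfe[2:3]
  shortage_units <- sum(shrbc) + if (shortage_pricing == "total") shebc else 0
  cost <- c(fixed = costs$fixed_operating,
            shipping = costs$fixed_shipping * (lab_receipts > 0),
            purchase = 0,
            holding = costs$holding * sum(state),
            shortage = costs$shortage * shortage_units,
            outdating = costs$outdating * expired)
  list(state = nxt, shipments = shipments, shrbc = shrbc, shebc = shebc,
       emergency_issued = f$issued, emergency_by_hospital = emergency_by_hospital,
       log = list(opening = state, received = c(0, 0, lab_receipts),
                  regular_leftover = lfr, emergency = E, shebc = shebc,
                  expired = expired, closing = nxt, cost = cost))
}

# pro-rata split of `total` over `weights` with largest-remainder rounding
largest_remainder <- function(weights, total) {
  K <- length(weights)
  if (K == 0L || total <= 0 || sum(weights) <= 0) return(numeric(K))
  raw <- weights / sum(weights) * total
  fl <- floor(raw)
  left <- round(total - sum(fl))
  if (left > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    fl[ord[seq_len(left)]] <- fl[ord[seq_len(left)]] + 1
  }
  pmin(fl, weights)
}

#' Replay fixed decisions through the daily event sequences
#'
#' Deterministically replays the hospital and blood-center event sequences
#' for every scenario, serving as an independent cost oracle for the MILP:
#' replaying a solved model's first-stage decisions (and its per-scenario
#' stock/external split of age-3 shipments) reproduces the optimizer's
#' objective exactly.
#'
#' @param decisions A `psc_solution`, or a list with `BCTHP` (K x T x 3
#'   committed shipments; audit mode) or `ORHP` (K x T orders; greedy mode).
#'   For audit mode an optional `HP3` (K x T x S) gives the stock/external
#'   split of age-3 shipments; when absent a greedy maximal-stock split is
#'   used.
#' @param scenarios,config Default to those stored in a `psc_solution`.
#' @param mode `"audit"` (committed shipments are inputs, checked against
#'   stock) or `"greedy"` (the blood center allocates by the literal daily
#'   event sequence; shipments then depend on the realized scenario).
#' @return A `psc_replay` list: `expected_cost` (dollars), `per_scenario_cost`
#'   (dollars/scenario), `expected_cost_cents`, unit KPI arrays
#'   (`shortage_hp`, `expired_hp`, `holding_hp` K x T x S; `purchased_hp`
#'   K x T; `shrbc`, `shebc`, `tshbc`, `expired_bc`, `holding_bc` T x S) and
#'   `entity_cost` ((K+1) x T x S, cents: hospitals then blood center).
#' @export
replay_policy <- function(decisions, scenarios = NULL, config = NULL,
                          mode = c("audit", "greedy")) {
  mode <- match.arg(mode)
  HP3 <- NULL
  if (inherits(decisions, "psc_solution")) {
    scenarios <- scenarios %||% decisions$scenarios
    config <- config %||% decisions$config
    HP3 <- decisions$second_stage$HP3
    BCTHP <- decisions$first_stage$BCTHP
    ORHP <- decisions$first_stage$ORHP
  } else {
    BCTHP <- decisions$BCTHP
    ORHP <- decisions$ORHP
    HP3 <- decisions$HP3
    if (is.null(ORHP) && !is.null(BCTHP)) ORHP <- apply(BCTHP, c(1, 2), sum)
  }
  if (is.null(config) || is.null(scenarios))
    stop("config and scenarios are required", call. = FALSE)
  check_dims(config, scenarios)
  if (mode == "audit" && is.null(BCTHP))
    stop("audit mode needs committed shipments (BCTHP)", call. = FALSE)
  if (is.null(ORHP)) stop("decisions must include ORHP or BCTHP", call. = FALSE)
  K <- length(config$hospitals); T <- config$horizon_days; S <- config$n_scenarios
  lt <- vapply(config$hospitals, `[[`, 1L, "lead_time_days")
  REBC <- bc_arrivals(config, scenarios)
  hc <- lapply(seq_len(K), function(k) hospital_costs(config, k))
  bcc <- config$costs$blood_center
  pricing <- config$bc_shortage_pricing
  iniH <- vapply(config$hospitals, `[[`, numeric(2), "initial_inventory")
  iniB <- config$blood_center$initial_inventory

  shortage_hp <- array(0, c(K, T, S)); expired_hp <- array(0, c(K, T, S))
  holding_hp <- array(0, c(K, T, S))
  shrbc <- matrix(0, T, S); shebc <- matrix(0, T, S)
  expired_bc <- matrix(0, T, S); holding_bc <- matrix(0, T, S)
  entity_cost <- array(0, c(K + 1, T, S))
  scen_cost <- numeric(S)
  ship_record <- if (mode == "greedy") array(0, c(K, T, 3)) else BCTHP

  for (s in seq_len(S)) {
    hstate <- lapply(seq_len(K), function(k) iniH[, k])
    bstate <- c(iniB[["1"]], iniB[["2"]])
    ship_hist <- array(0, c(K, T, 3))  # shipments sent each day (this scenario)
    for (t in seq_len(T)) {
      # --- blood center, regular fulfillment stage -------------------------
      if (mode == "audit") {
        bres <- blood_center_day_step(
          bstate, REBC[t, s], shipments = matrix(BCTHP[, t, ], K, 3),
          hp3 = if (!is.null(HP3)) HP3[, t, s] else NULL,
          emergency = 0, lead_times = lt, costs = bcc,
          shortage_pricing = pricing)
      } else {
        bres <- blood_center_day_step(
          bstate, REBC[t, s], orders = ORHP[, t],
          emergency = 0, lead_times = lt, costs = bcc,
          shortage_pricing = pricing)
      }
      ship_hist[, t, ] <- bres$shipments
      if (mode == "greedy" && s == 1L) ship_record[, t, ] <- bres$shipments
      # --- hospitals: receive (lead-time lag), observe demand, FIFO --------
      day_short <- numeric(K)
      for (k in seq_len(K)) {
        rec <- numeric(3)
        ts <- t - lt[k]
        if (ts >= 1L) {
          sh <- ship_hist[k, ts, ]
          for (l in 1:3) if (l - lt[k] >= 1) rec[l - lt[k]] <- sh[l]
        }
        opening_units <- sum(hstate[[k]])
        hres <- hospital_day_step(hstate[[k]], rec, scenarios$demand[k, t, s],
                                  hc[[k]], order = ORHP[k, t])
        hres$log$cost["shipping"] <- hc[[k]]$fixed_shipping *
          (sum(ship_hist[k, t, ]) > 0)
        hstate[[k]] <- hres$state
        shortage_hp[k, t, s] <- hres$log$shortage
        expired_hp[k, t, s] <- hres$log$expired
        holding_hp[k, t, s] <- opening_units
        day_short[k] <- hres$log$shortage
        entity_cost[k, t, s] <- sum(hres$log$cost)
      }
      # --- blood center, emergency stage on the regular leftovers ----------
      f <- fifo_issue(bres$log$regular_leftover, demand = sum(day_short))
      shebc[t, s] <- f$unmet
      expired_bc[t, s] <- f$leftover[1]
      holding_bc[t, s] <- sum(bres$log$opening)
      bstate <- f$leftover[2:3]
      shrbc[t, s] <- sum(bres$shrbc)
      bc_cost <- bres$log$cost
      bc_cost["shortage"] <- bcc$shortage *
        (shrbc[t, s] + if (pricing == "total") shebc[t, s] else 0)
      bc_cost["outdating"] <- bcc$outdating * expired_bc[t, s]
      entity_cost[K + 1, t, s] <- sum(bc_cost)
    }
    scen_cost[s] <- sum(entity_cost[, , s])
  }
  structure(list(
    expected_cost = sum(scenarios$probabilities * scen_cost) / 100,
    expected_cost_cents = sum(scenarios$probabilities * scen_cost),
    per_scenario_cost = scen_cost / 100,
    shortage_hp = shortage_hp, expired_hp = expired_hp, holding_hp = holding_hp,
    purchased_hp = ORHP,
    shrbc = shrbc, shebc = shebc, tshbc = shrbc + shebc,
    expired_bc = expired_bc, holding_bc = holding_bc,
    entity_cost = entity_cost,
    shipments = ship_record,
    probabilities = scenarios$probabilities,
    mode = mode
  ), class = "psc_replay")
}

#' @export
print.psc_replay <- function(x, ...) {
  cat(sprintf("Policy replay (%s mode): expected cost $%.2f (%d scenarios)\n",
              x$mode, x$expected_cost, length(x$per_scenario_cost)))
  invisible(x)
}
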