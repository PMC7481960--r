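#' Demand or supply distribution specification
#'
#' Daily platelet demand (or supply) is modelled as a normal distribution,
#' truncated at zero and rounded to whole units when sampled.
#'
#' @param mean Mean daily units (nonnegative).
#' @param sd Standard deviation of daily units (nonnegative).
#' @return A `psc_dist` list with elements `mean` and `sd`.
#' @export
dist_spec <- function(mean, sd) {
  check_nonneg_scalar(mean, "mean")
  check_nonneg_scalar(sd, "sd")
  structure(list(mean = mean, sd = sd), class = "psc_dist")
}

#' Coefficient of variation of a distribution specification
#' @param x A `psc_dist`.
#' @return `sd/mean`; errors when `mean == 0`.
#' @export
cv <- function(x) {
  stopifnot(inherits(x, "psc_dist"))
  if (x$mean <= 0) stop("cv undefined for mean == 0", call. = FALSE)
  x$sd / x$mean
}

normalize_inventory <- function(ini, field) {
  # age-stratified opening stock: only ages 1 and 2 can be carried overnight
  out <- c("1" = 0, "2" = 0)
  if (length(ini)) {
    nm <- names(ini)
    if (is.null(nm) || !all(nm %in% c("1", "2")))
      stop_field(field, "must map shelf life 1 and/or 2 to units (age-3 units cannot be carried from before day 1)")
    for (l in nm) {
      check_nonneg_scalar(ini[[l]], paste0(field, "[", l, "]"), integer = TRUE)
      out[l] <- ini[[l]]
    }
  }
  out
}

#' Hospital configuration
#'
#' @param id Integer hospital index.
#' @param lead_time_days Days between placing and receiving an order. Must be
#'   0, 1 or 2: platelets leave the blood center with at most a three-day
#'   shelf life, so anything longer would always arrive expired.
#' @param review_period_days Ordering cadence; orders are forced to zero on
#'   non-review days.
#' @param demand A [dist_spec()] for daily demand.
#' @param initial_inventory Named list/vector mapping shelf life (`"1"`,`"2"`)
#'   to opening units on day 1.
#' @return A `psc_hospital` list.
#' @export
hospital_config <- function(id, lead_time_days, review_period_days = 1L,
                            demand, initial_inventory = NULL) {
  check_nonneg_scalar(id, "id", integer = TRUE)
  if (!is.numeric(lead_time_days) || length(lead_time_days) != 1L ||
      !(lead_time_days %in% 0:2))
    stop_field("lead_time_days",
               "must be 0, 1 or 2: shipped platelets have at most a 3-day shelf life, so longer lead times would deliver expired units")
  check_nonneg_scalar(review_period_days, "review_period_days", integer = TRUE)
  if (review_period_days < 1) stop_field("review_period_days", "must be >= 1")
  if (!inherits(demand, "psc_dist")) demand <- do.call(dist_spec, as.list(demand))
  ini <- normalize_inventory(initial_inventory, "initial_inventory")
  structure(list(id = as.integer(id),
                 lead_time_days = as.integer(lead_time_days),
                 review_period_days = as.integer(review_period_days),
                 demand = demand,
                 initial_inventory = ini),
            class = "psc_hospital")
}

#' Blood-center configuration
#'
#' @param lead_time_days Days between a procurement order (blood drive) and
#'   the arrival of tested units from the component labs.
#' @param review_period_days Procurement cadence.
#' @param supply A [dist_spec()] for daily collected supply.
#' @param initial_inventory Named mapping of shelf life (1, 2) to opening units.
#' @return A `psc_bloodcenter` list.
#' @export
blood_center_config <- function(lead_time_days, review_period_days = 1L,
                                supply, initial_inventory = NULL) {
  check_nonneg_scalar(lead_time_days, "lead_time_days", integer = TRUE)
  if (lead_time_days < 1) stop_field("lead_time_days", "must be >= 1")
  check_nonneg_scalar(review_period_days, "review_period_days", integer = TRUE)
  if (review_period_days < 1) stop_field("review_period_days", "must be >= 1")
  if (!inherits(supply, "psc_dist")) supply <- do.call(dist_spec, as.list(supply))
  ini <- normalize_inventory(initial_inventory, "initial_inventory")
  structure(list(lead_time_days = as.integer(lead_time_days),
                 review_period_days = as.integer(review_period_days),
                 supply = supply,
                 initial_inventory = ini),
            class = "psc_bloodcenter")
}

#' Cost parameters for the supply chain
#'
#' All parameters are in cents. Eleven coefficients enter the objective: six
#' per hospital (fixed operating per day, fixed shipping per shipment,
#' purchase per unit, holding per unit-day, shortage per unit, outdating per
#' unit) and five for the blood center (fixed operating, fixed shipping,
#' holding, shortage, outdating). The blood-center processing cost
#' (`processing_bc`) is carried for reporting but excluded from the objective:
#' it is recovered through the hospitals' purchase prices.
#'
#' @param fixed_operating_hp,fixed_shipping_hp,purchase_hp,holding_hp,shortage_hp,outdating_hp
#'   Numeric vectors with one entry per hospital (recycled if length 1).
#' @param fixed_operating_bc,fixed_shipping_bc,processing_bc,holding_bc,shortage_bc,outdating_bc
#'   Blood-center scalars.
#' @return A `psc_costs` list.
#' @export
cost_params <- function(fixed_operating_hp = 0, fixed_shipping_hp, purchase_hp,
                        holding_hp, shortage_hp, outdating_hp,
                        fixed_operating_bc = 0, fixed_shipping_bc,
                        processing_bc = 0, holding_bc, shortage_bc, outdating_bc) {
  hp <- list(fixed_operating = fixed_operating_hp,
             fixed_shipping = fixed_shipping_hp,
             purchase = purchase_hp,
             holding = holding_hp,
             shortage = shortage_hp,
             outdating = outdating_hp)
  for (nm in names(hp)) {
    v <- hp[[nm]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0))
      stop_field(paste0(nm, "_hp"), "must be nonnegative")
  }
  bc <- list(fixed_operating = fixed_operating_bc,
             fixed_shipping = fixed_shipping_bc,
             processing = processing_bc,
             holding = holding_bc,
             shortage = shortage_bc,
             outdating = outdating_bc)
  for (nm in names(bc)) check_nonneg_scalar(bc[[nm]], paste0(nm, "_bc"))
  structure(list(hospital = hp, blood_center = bc), class = "psc_costs")
}

hp_cost <- function(costs, name, k) {
  v <- costs$hospital[[name]]
  if (length(v) == 1L) v else v[[k]]
}

#' Network configuration
#'
#' Bundles hospitals, blood center, costs, planning horizon, scenario count
#' and master seed into one validated object.
#'
#' @param hospitals List of [hospital_config()] objects (nonempty).
#' @param blood_center A [blood_center_config()].
#' @param costs A [cost_params()].
#' @param horizon_days Planning horizon T (days).
#' @param n_scenarios Number of sampled scenarios S.
#' @param seed Master seed for scenario generation.
#' @param bc_shortage_pricing Which shortage quantity the blood-center
#'   shortage cost multiplies in the objective: `"total"` (default; external
#'   procurement for regular orders plus unmet-emergency units, i.e. the
#'   day's total blood-center shortage) or `"regular"` (regular-stage
#'   external procurement only; requires extra structural complementarity
#'   binaries and solves far slower — see the methods vignette).
#' @return A `psc_config` list.
#' @export
network_config <- function(hospitals, blood_center, costs,
                           horizon_days, n_scenarios, seed = 1L,
                           bc_shortage_pricing = c("total", "regular")) {
  if (!is.list(hospitals) || length(hospitals) == 0L)
    stop_field("hospitals", "must be a nonempty list of hospital_config objects")
  for (h in hospitals) if (!inherits(h, "psc_hospital"))
    stop_field("hospitals", "must contain hospital_config objects")
  if (!inherits(blood_center, "psc_bloodcenter"))
    stop_field("blood_center", "must be a blood_center_config")
  if (!inherits(costs, "psc_costs")) stop_field("costs", "must be a cost_params")
  check_nonneg_scalar(horizon_days, "horizon_days", integer = TRUE)
  check_nonneg_scalar(n_scenarios, "n_scenarios", integer = TRUE)
  if (horizon_days < 1) stop_field("horizon_days", "must be >= 1")
  if (n_scenarios < 1) stop_field("n_scenarios", "must be >= 1")
  rp_max <- max(vapply(hospitals, `[[`, 1L, "review_period_days"),
                blood_center$review_period_days)
  if (horizon_days < rp_max)
    stop_field("horizon_days", "must be at least the longest review period")
  if (horizon_days < blood_center$lead_time_days)
    stop_field("horizon_days", "must be at least the blood-center lead time")
  nk <- length(costs$hospital$purchase)
  if (nk != 1L && nk != length(hospitals))
    stop_field("costs", "hospital cost vectors must have length 1 or K")
  bc_shortage_pricing <- match.arg(bc_shortage_pricing)
  structure(list(hospitals = hospitals,
                 blood_center = blood_center,
                 costs = costs,
                 horizon_days = as.integer(horizon_days),
                 n_scenarios = as.integer(n_scenarios),
                 seed = as.integer(seed),
                 bc_shortage_pricing = bc_shortage_pricing),
            class = "psc_config")
}

#' @export
print.psc_config <- function(x, ...) {
  cat(sprintf("Platelet supply-chain network: %d hospital(s) + 1 blood center\n",
              length(x$hospitals)))
  cat(sprintf("  horizon %d days, %d scenarios, seed %d\n",
              x$horizon_days, x$n_scenarios, x$seed))
  for (h in x$hospitals)
    cat(sprintf("  hospital %d: lead time %d d, review %d d, demand N(%g, %g)\n",
                h$id, h$lead_time_days, h$review_period_days,
                h$demand$mean, h$demand$sd))
  bc <- x$blood_center
  cat(sprintf("  blood center: lead time %d d, review %d d, supply N(%g, %g)\n",
              bc$lead_time_days, bc$review_period_days,
              bc$supply$mean, bc$supply$sd))
  invisible(x)
}

#' Two-hospital reference network
#'
#' The reference case used throughout: two hospitals with daily demand
#' N(200, 32) and N(100, 16), lead times 1 and 2 days, and a blood center
#' with daily supply N(225, 36) and a five-day procurement lead time; review
#' period one day everywhere. Cost parameters (cents): hospitals --
#' fixed shipping 113/225, holding 130, purchase 650, shortage 3250,
#' outdating 650; blood center -- fixed shipping 1125, holding 108,
#' processing 538, shortage 2690, outdating 538. Initial inventories default
#' to one mean day of age-2 stock at every entity (no value is prescribed by
#' the source data; see the methods vignette).
#'
#' @param horizon_days,n_scenarios Problem size (default 300 x 100).
#' @param seed Master seed.
#' @param ... Passed on to [network_config()] (e.g. `bc_shortage_pricing`).
#' @return A `psc_config`.
#' @export
base_case_config <- function(horizon_days = 300L, n_scenarios = 100L, seed = 1L, ...) {
  h1 <- hospital_config(1L, lead_time_days = 1L, review_period_days = 1L,
                        demand = dist_spec(200, 32),
                        initial_inventory = list("2" = 200))
  h2 <- hospital_config(2L, lead_time_days = 2L, review_period_days = 1L,
                        demand = dist_spec(100, 16),
                        initial_inventory = list("2" = 100))
  bc <- blood_center_config(lead_time_days = 5L, review_period_days = 1L,
                            supply = dist_spec(225, 36),
                            initial_inventory = list("2" = 225))
  costs <- cost_params(fixed_operating_hp = c(0, 0),
                       fixed_shipping_hp = c(113, 225),
                       purchase_hp = c(650, 650),
                       holding_hp = c(130, 130),
                       shortage_hp = c(3250, 3250),
                       outdating_hp = c(650, 650),
                       fixed_operating_bc = 0,
                       fixed_shipping_bc = 1125,
                       processing_bc = 538,
                       holding_bc = 108,
                       shortage_bc = 2690,
                       outdating_bc = 538)
  network_config(list(h1, h2), bc, costs,
                 horizon_days = horizon_days, n_scenarios = n_scenarios,
                 seed = seed, ...)
}

#' Rescale a configuration's problem size
#' @param config A `psc_config`.
#' @param horizon_days,n_scenarios New dimensions.
#' @param seed Optionally a new master seed.
#' @return The modified `psc_config`.
#' @export
scale_config <- function(config, horizon_days = config$horizon_days,
                         n_scenarios = config$n_scenarios, seed = config$seed) {
  stopifnot(inherits(config, "psc_config"))
  config$horizon_days <- as.integer(horizon_days)
  config$n_scenarios <- as.integer(n_scenarios)
  config$seed <- as.integer(seed)
  config
}

#' Set every demand/supply coefficient of variation
#'
#' Replaces each distribution's sd by `cv * mean` rounded half-up (so a
#' mean of 225 at cv 0.1 gives sd 23), leaving means unchanged. Idempotent
#' for a given `cv` because the sd is recomputed from the mean, never from
#' the prior sd.
#'
#' @param config A `psc_config`.
#' @param cv Coefficient of variation in (0, 1].
#' @return A modified copy of `config`.
#' @export
apply_cv_setting <- function(config, cv) {
  stopifnot(inherits(config, "psc_config"))
  if (!is.numeric(cv) || length(cv) != 1L || is.na(cv) || cv <= 0)
    stop("cv must be a positive number", call. = FALSE)
  half_up <- function(x) floor(x + 0.5)
  for (i in seq_along(config$hospitals)) {
    m <- config$hospitals[[i]]$demand$mean
    config$hospitals[[i]]$demand <- dist_spec(m, half_up(cv * m))
  }
  m <- config$blood_center$supply$mean
  config$blood_center$supply <- dist_spec(m, half_up(cv * m))
  config
}

#' Load a network configuration from YAML or JSON
#'
#' The file mirrors the constructor arguments: top-level keys `hospitals`
#' (list of hospital blocks), `blood_center`, `costs`, `horizon_days`,
#' `n_scenarios`, `seed`, and optionally `bc_shortage_pricing`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A validated `psc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$hospitals) || length(raw$hospitals) == 0L)
    stop_field("hospitals", "is missing or empty")
  hospitals <- lapply(seq_along(raw$hospitals), function(i) {
    h <- raw$hospitals[[i]]
    hospital_config(id = h$id %||% i,
                    lead_time_days = h$lead_time_days,
                    review_period_days = h$review_period_days %||% 1L,
                    demand = dist_spec(h$demand$mean, h$demand$sd),
                    initial_inventory = h$initial_inventory)
  })
  b <- raw$blood_center
  if (is.null(b)) stop_field("blood_center", "is missing")
  bc <- blood_center_config(lead_time_days = b$lead_time_days,
                            review_period_days = b$review_period_days %||% 1L,
                            supply = dist_spec(b$supply$mean, b$supply$sd),
                            initial_inventory = b$initial_inventory)
  cc <- raw$costs
  if (is.null(cc)) stop_field("costs", "is missing")
  costs <- cost_params(fixed_operating_hp = unlist(cc$fixed_operating_hp %||% 0),
                       fixed_shipping_hp = unlist(cc$fixed_shipping_hp),
                       purchase_hp = unlist(cc$purchase_hp),
                       holding_hp = unlist(cc$holding_hp),
                       shortage_hp = unlist(cc$shortage_hp),
                       outdating_hp = unlist(cc$outdating_hp),
                       fixed_operating_bc = cc$fixed_operating_bc %||% 0,
                       fixed_shipping_bc = cc$fixed_shipping_bc,
                       processing_bc = cc$processing_bc %||% 0,
                       holding_bc = cc$holding_bc,
                       shortage_bc = cc$shortage_bc,
                       outdating_bc = cc$outdating_bc)
  network_config(hospitals, bc, costs,
                 horizon_days = raw$horizon_days,
                 n_scenarios = raw$n_scenarios,
                 seed = raw$seed %||% 1L,
                 bc_shortage_pricing = raw$bc_shortage_pricing %||% "regular")
}
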