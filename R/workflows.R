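#' End-to-end run: scenarios, solve, validate, report
#'
#' Generates scenarios, builds and solves the stochastic program, validates
#' the solution's structural identities, writes the KPI tables and a JSON
#' run manifest to `out_dir`, and returns everything invisibly.
#'
#' @param config A `psc_config` or path to a YAML/JSON configuration file.
#' @param out_dir Output directory.
#' @param seed Overrides the configuration's master seed when given.
#' @param horizon_days,n_scenarios Optional problem-size overrides (e.g.
#'   desk-scale runs).
#' @param dry_run Build only: print model dimensions and exit (no solve).
#' @param ... Passed to [solve_model()].
#' @return Invisibly, a list with `solution`, `kpi`, `validation`, `manifest`.
#' @export
run_base_case <- function(config, out_dir = "psc_out", seed = NULL,
                          horizon_days = NULL, n_scenarios = NULL,
                          dry_run = FALSE, ...) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "psc_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(horizon_days)) config$horizon_days <- as.integer(horizon_days)
  if (!is.null(n_scenarios)) config$n_scenarios <- as.integer(n_scenarios)
  scen <- generate_scenarios(config)
  model <- build_model(config, scen)
  if (dry_run) {
    print(model)
    return(invisible(list(model = model)))
  }
  sol <- solve_model(model, ...)
  val <- validate_solution(sol)
  kpi <- kpi_summary(sol)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_kpi(kpi, out_dir, "base_case")
  manifest <- list(
    package_version = as.character(utils::packageVersion("plateletsc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    horizon_days = config$horizon_days,
    n_scenarios = config$n_scenarios,
    bc_shortage_pricing = config$bc_shortage_pricing,
    config_hash = config_hash(config),
    solver = "highs (scipy)",
    objective = sol$objective,
    mip_gap = sol$mip_gap,
    status = sol$status,
    validation_ok = val$ok,
    outputs = file.path(out_dir, c("base_case.csv", "base_case.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(list(solution = sol, kpi = kpi, validation = val,
                 manifest = manifest))
}

# stable fingerprint of a configuration (no external digest dependency)
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 12)),
             collapse = "\n")
  sprintf("%08x-%d", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max, nchar(s))
}

#' Rolling-horizon re-optimization
#'
#' Repeatedly solves a `window_days` stochastic program, implements only the
#' first `implement_days` of its first-stage decisions against a held-out
#' realized demand/supply path, advances the inventories through the event
#' simulator, and re-solves with fresh scenario draws for the remaining
#' horizon. Reports the realized cost of the concatenated implemented
#' policy.
#'
#' @param config A `psc_config`; `horizon_days` is the total span to cover.
#' @param window_days Length of each optimization window.
#' @param implement_days Days of each window actually implemented.
#' @param realization_seed Seed for the held-out realized path.
#' @param ... Passed to [solve_model()].
#' @return List with `realized_cost` (dollars), `decisions` (implemented
#'   daily orders, K x T), `replay` (the `psc_replay` of the implemented
#'   policy on the realization) and `windows` (per-window objectives).
#' @details Each window's optimized order quantities are implemented; on the
#'   realized path the blood center executes them through the literal daily
#'   event sequence (greedy age-ascending allocation), since the optimized
#'   shipment-age composition is tied to the window's sampled scenarios and
#'   need not be feasible against the realized stock profile.
#' @export
rolling_horizon <- function(config, window_days, implement_days = window_days,
                            realization_seed = config$seed + 1L, ...) {
  stopifnot(inherits(config, "psc_config"),
            implement_days >= 1, implement_days <= window_days)
  T_total <- config$horizon_days
  K <- length(config$hospitals)
  # held-out realization: a single-scenario draw over the full span
  real_cfg <- scale_config(config, n_scenarios = 1L, seed = realization_seed)
  realization <- generate_scenarios(real_cfg)
  ORHP_impl <- matrix(0, K, T_total)
  windows <- list()
  t0 <- 0L
  w <- 0L
  cfg_w <- config
  while (t0 < T_total) {
    w <- w + 1L
    span <- min(window_days, T_total - t0)
    impl <- min(implement_days, span)
    cfg_w <- scale_config(cfg_w, horizon_days = span,
                          seed = config$seed + 1000L * w)
    sol <- tryCatch(optimize_network(cfg_w, ...), error = function(e)
      stop(sprintf("rolling-horizon window %d (days %d-%d) failed: %s",
                   w, t0 + 1L, t0 + span, conditionMessage(e)), call. = FALSE))
    ORHP_impl[, t0 + seq_len(impl)] <-
      sol$first_stage$ORHP[, seq_len(impl), drop = FALSE]
    windows[[w]] <- list(start_day = t0 + 1L, span = span,
                         objective = sol$objective)
    # advance the realized state through the implemented days
    cfg_w <- advance_config(config, realization, ORHP_impl, t0 + impl)
    t0 <- t0 + impl
  }
  rp <- replay_policy(list(ORHP = ORHP_impl),
                      scenarios = realization,
                      config = scale_config(config, n_scenarios = 1L),
                      mode = "greedy")
  list(realized_cost = rp$expected_cost, decisions = ORHP_impl,
       replay = rp, windows = windows)
}

# replay the implemented orders greedily on the realization up to day `end`
# and return a copy of the configuration whose initial inventories are the
# resulting closing stocks
advance_config <- function(base_config, realization, ORHP_impl, end) {
  K <- length(base_config$hospitals)
  span_cfg <- scale_config(base_config, horizon_days = end, n_scenarios = 1L)
  scen <- structure(list(
    demand = realization$demand[, seq_len(end), , drop = FALSE],
    supply = realization$supply[seq_len(end), , drop = FALSE],
    probabilities = 1, seed = realization$seed), class = "psc_scenarios")
  st <- forward_state(span_cfg, scen, ORHP_impl[, seq_len(end), drop = FALSE])
  cfg_next <- base_config
  for (k in seq_len(K))
    cfg_next$hospitals[[k]]$initial_inventory <-
      c("1" = st$hospital[[k]][1], "2" = st$hospital[[k]][2])
  cfg_next$blood_center$initial_inventory <-
    c("1" = st$blood_center[1], "2" = st$blood_center[2])
  cfg_next
}

# forward-simulate one scenario under greedy order execution, returning the
# closing age-stratified stocks
forward_state <- function(config, scenarios, ORHP) {
  K <- length(config$hospitals); T <- ncol(ORHP)
  lt <- vapply(config$hospitals, `[[`, 1L, "lead_time_days")
  REBC <- bc_arrivals(config, scenarios)
  iniH <- vapply(config$hospitals, `[[`, numeric(2), "initial_inventory")
  iniB <- config$blood_center$initial_inventory
  hstate <- lapply(seq_len(K), function(k) iniH[, k])
  bstate <- c(iniB[["1"]], iniB[["2"]])
  bcc <- config$costs$blood_center
  ship_hist <- array(0, c(K, T, 3))
  for (t in seq_len(T)) {
    bres <- blood_center_day_step(bstate, REBC[t, 1], orders = ORHP[, t],
                                  emergency = 0, lead_times = lt, costs = bcc,
                                  shortage_pricing = config$bc_shortage_pricing)
    ship_hist[, t, ] <- bres$shipments
    short <- 0
    for (k in seq_len(K)) {
      rec <- numeric(3)
      ts <- t - lt[k]
      if (ts >= 1L) for (l in 1:3) if (l - lt[k] >= 1)
        rec[l - lt[k]] <- ship_hist[k, ts, l]
      hres <- hospital_day_step(hstate[[k]], rec, scenarios$demand[k, t, 1],
                                hospital_costs(config, k))
      hstate[[k]] <- hres$state
      short <- short + hres$log$shortage
    }
    f <- fifo_issue(bres$log$regular_leftover, demand = short)
    bstate <- f$leftover[2:3]
  }
  list(hospital = hstate, blood_center = bstate)
}
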