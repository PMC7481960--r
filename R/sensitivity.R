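cost_setting_grid <- function() {
  # rows 2..9 halve one parameter family; rows 10..17 multiply it by 1.5,
  # in the fixed order of the sensitivity grid
  fams <- c("bc_holding", "bc_shortage", "bc_outdating", "hp_fixed_shipping",
            "hp_holding", "hp_purchase", "hp_shortage", "hp_outdating")
  ids <- sprintf("CSET%d", 1:17)
  mult <- stats::setNames(vector("list", 17), ids)
  mult[["CSET1"]] <- list()
  for (i in seq_along(fams)) {
    mult[[sprintf("CSET%d", i + 1)]] <- stats::setNames(list(0.5), fams[i])
    mult[[sprintf("CSET%d", i + 9)]] <- stats::setNames(list(1.5), fams[i])
  }
  mult
}

#' Build one setting of the cost-sensitivity grid
#'
#' `CSET1` is the base case; `CSET2`-`CSET9` halve, and `CSET10`-`CSET17`
#' multiply by 1.5, exactly one cost family each, in the order: blood-center
#' holding, blood-center shortage, blood-center outdating, hospital fixed
#' shipping, hospital holding, hospital purchasing, hospital shortage,
#' hospital outdating.
#'
#' @param id `"CSET1"` ... `"CSET17"`.
#' @param base A `psc_costs` to modify (default: the reference network's).
#' @return A modified `psc_costs`.
#' @export
build_cost_setting <- function(id, base = base_case_config()$costs) {
  grid <- cost_setting_grid()
  if (!id %in% names(grid)) stop("unknown cost setting: ", id, call. = FALSE)
  costs <- base
  for (fam in names(grid[[id]])) {
    f <- grid[[id]][[fam]]
    if (startsWith(fam, "bc_")) {
      nm <- sub("^bc_", "", fam)
      costs$blood_center[[nm]] <- costs$blood_center[[nm]] * f
    } else {
      nm <- sub("^hp_", "", fam)
      costs$hospital[[nm]] <- costs$hospital[[nm]] * f
    }
  }
  costs
}

#' Sweep the demand/supply coefficient of variation
#'
#' For each CV, rescales every distribution's sd to `round(cv * mean)`,
#' regenerates scenarios, solves the stochastic program and summarizes the
#' overall cost measures. Each replication r uses master seed
#' `seeds[r]` for every CV (common random number streams across CVs within a
#' replication, so cost differences are attributable to the CV).
#'
#' @param config Base `psc_config`.
#' @param cvs Coefficients of variation to visit.
#' @param seeds Master seeds, one per replication.
#' @param ... Passed to [solve_model()].
#' @return A data.frame with cv, seed, average/best/worst/std daily cost;
#'   attribute `"failures"` lists any failed cells.
#' @export
run_cv_sweep <- function(config, cvs = seq(0.1, 0.5, by = 0.1),
                         seeds = config$seed, ...) {
  stopifnot(length(cvs) > 0)
  rows <- list(); fails <- list()
  for (seed in seeds) for (cv in cvs) {
    res <- tryCatch({
      cfg <- apply_cv_setting(scale_config(config, seed = seed), cv)
      sol <- optimize_network(cfg, ...)
      k <- kpi_summary(sol)
      data.frame(cv = cv, seed = seed, t(k$overall))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(cv = cv, seed = seed,
                                                error = conditionMessage(res))
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cv = numeric(), seed = integer(), average = numeric(),
               best = numeric(), worst = numeric(), std = numeric())
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else NULL
  if (length(fails))
    warning(sprintf("%d sweep cell(s) failed to solve", length(fails)))
  out
}

#' Run the cost-setting sensitivity experiments
#'
#' Re-solves the model under each requested cost setting on a common
#' scenario set (same master seed for every setting, isolating the cost
#' effect from sampling noise) and reports per-entity unit KPIs and daily
#' cost totals.
#'
#' @param config Base `psc_config` (its costs are the `CSET1` base).
#' @param setting_ids Subset of `"CSET1"`..`"CSET17"`.
#' @param seeds Master seeds, one replication each.
#' @param ... Passed to [solve_model()].
#' @return A data.frame with setting, seed, entity, shortage, outdating,
#'   holding, purchased, cost; attribute `"failures"` as in [run_cv_sweep()].
#' @export
run_cost_settings <- function(config, setting_ids = sprintf("CSET%d", 1:17),
                              seeds = config$seed, ...) {
  rows <- list(); fails <- list()
  for (seed in seeds) {
    cfg0 <- scale_config(config, seed = seed)
    scen <- generate_scenarios(cfg0)
    for (id in setting_ids) {
      res <- tryCatch({
        cfg <- cfg0
        cfg$costs <- build_cost_setting(id, cfg0$costs)
        sol <- optimize_network(cfg, scenarios = scen, ...)
        k <- kpi_summary(sol)
        cbind(setting = id, seed = seed, k$entity,
              overall_average = unname(k$overall["average"]))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(setting = id, seed = seed,
                                                  error = conditionMessage(res))
      } else rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else NULL
  if (length(fails))
    warning(sprintf("%d cost-setting cell(s) failed to solve", length(fails)))
  out
}
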