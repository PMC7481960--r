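#' Summarize a solution (or replay) into the standard performance measures
#'
#' Per entity: average daily units of shortage, outdating, holding and
#' purchases, averaged over days and (probability-weighted) scenarios.
#' Overall: the expected cost per day per scenario, the best and worst
#' scenario's daily cost, and the (population, probability-weighted) standard
#' deviation of the per-scenario daily costs. Cost figures are in dollars;
#' unit figures in platelet units/day.
#'
#' The hospitals' purchases are their regular orders; the blood center's
#' "purchased" units are its processed procurement (the supply-driven order
#' stream). The blood center's shortage is the day's total (regular external
#' procurement plus unmet emergency). Per-entity cost totals sum that
#' entity's objective components (the blood-center shortage component
#' follows the configuration's `bc_shortage_pricing`).
#'
#' @param x A `psc_solution` or `psc_replay`.
#' @param config,scenarios Defaults taken from a `psc_solution`.
#' @return A `psc_kpi` list with `entity` (data.frame, one row per hospital
#'   plus the blood center) and `overall` (average/best/worst/std daily cost).
#' @export
kpi_summary <- function(x, config = NULL, scenarios = NULL) {
  if (inherits(x, "psc_solution")) {
    config <- config %||% x$config
    scenarios <- scenarios %||% x$scenarios
    rp <- replay_policy(x, scenarios, config, mode = "audit")
  } else if (inherits(x, "psc_replay")) {
    rp <- x
    if (is.null(config)) stop("config is required for a replay", call. = FALSE)
  } else stop("x must be a psc_solution or psc_replay", call. = FALSE)
  K <- length(config$hospitals); T <- dim(rp$shortage_hp)[2]
  pb <- rp$probabilities %||% scenarios$probabilities
  wmean_ts <- function(m) sum(t(matrix(m, nrow = T)) * pb) / T    # T x S
  wmean_kts <- function(a, k) wmean_ts(a[k, , ])
  ent <- data.frame(
    entity = c(sprintf("hospital_%d", seq_len(K)), "blood_center"),
    shortage = c(vapply(seq_len(K), function(k) wmean_kts(rp$shortage_hp, k), 0),
                 wmean_ts(rp$tshbc)),
    outdating = c(vapply(seq_len(K), function(k) wmean_kts(rp$expired_hp, k), 0),
                  wmean_ts(rp$expired_bc)),
    holding = c(vapply(seq_len(K), function(k) wmean_kts(rp$holding_hp, k), 0),
                wmean_ts(rp$holding_bc)),
    purchased = c(rowMeans(rp$purchased_hp),
                  # blood center: expected processed supply per day
                  sum(t(matrix(scenarios$supply, nrow = T)) * pb) / T),
    cost = vapply(seq_len(K + 1),
                  function(e) wmean_ts(rp$entity_cost[e, , ]) / 100, 0))
  cs <- rp$per_scenario_cost / T            # dollars per day, per scenario
  avg <- sum(pb * cs)
  structure(list(
    entity = ent,
    overall = c(average = avg, best = min(cs), worst = max(cs),
                std = sqrt(sum(pb * (cs - avg)^2))),
    horizon_days = T, n_scenarios = length(pb)
  ), class = "psc_kpi")
}

#' @export
print.psc_kpi <- function(x, digits = 1, ...) {
  cat(sprintf("Average performance measures (T=%d, S=%d; units/day, cost $/day/scenario)\n",
              x$horizon_days, x$n_scenarios))
  print(cbind(x$entity[1], round(x$entity[-1], digits)), row.names = FALSE)
  cat(sprintf("overall daily cost: average %.0f, best %.0f, worst %.0f, std %.1f\n",
              x$overall["average"], x$overall["best"], x$overall["worst"],
              x$overall["std"]))
  invisible(x)
}

#' Lay a KPI report out as a table
#'
#' @param report A `psc_kpi` (or for `layout = "cv_sweep"` /
#'   `"cost_settings"`, a data.frame produced by the sweep runners).
#' @param layout `"base_case"` (entity block plus overall cost block),
#'   `"cv_sweep"` or `"cost_settings"` (pass-through of sweep tables).
#' @return A data.frame ready for `write.csv`.
#' @export
to_table <- function(report, layout = c("base_case", "cv_sweep", "cost_settings")) {
  layout <- match.arg(layout)
  if (layout == "base_case") {
    stopifnot(inherits(report, "psc_kpi"))
    ent <- report$entity
    out <- data.frame(measure = c("unit_shortage", "unit_outdating",
                                  "unit_holding", "unit_purchased", "total_cost"))
    for (i in seq_len(nrow(ent)))
      out[[ent$entity[i]]] <- round(as.numeric(ent[i, c("shortage", "outdating",
                                                        "holding", "purchased",
                                                        "cost")]))
    ov <- report$overall
    overall <- data.frame(measure = c("average_cost_per_day_per_scenario",
                                      "best", "worst", "std"))
    for (nm in names(out)[-1]) overall[[nm]] <- NA
    overall[[names(out)[2]]] <- round(as.numeric(ov))
    rbind(out, overall)
  } else {
    as.data.frame(report)
  }
}

#' Write KPI tables to an output directory
#' @param report A `psc_kpi` or sweep table.
#' @param out_dir Directory (created if needed).
#' @param name File stem.
#' @param layout Passed to [to_table()].
#' @return The CSV path, invisibly.
#' @export
write_kpi <- function(report, out_dir, name = "kpi", layout = "base_case") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(to_table(report, layout), path, row.names = FALSE)
  if (inherits(report, "psc_kpi")) {
    jsonlite::write_json(
      list(entity = report$entity, overall = as.list(report$overall),
           horizon_days = report$horizon_days,
           n_scenarios = report$n_scenarios),
      file.path(out_dir, paste0(name, ".json")),
      auto_unbox = TRUE, digits = 6)
  }
  invisible(path)
}
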