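#' Generate the demand/supply scenario set
#'
#' Samples daily platelet demand for every hospital and daily supply at the
#' blood center, i.i.d. over days and scenarios, as
#' `round(max(0, Normal(mean, sd)))` so that all quantities are whole,
#' nonnegative units. Each entity draws from its own child RNG stream derived
#' from the master seed, so adding a hospital leaves the other entities'
#' draws untouched. Scenario probabilities are uniform `1/S`.
#'
#' @param config A `psc_config`.
#' @param seed Master seed; defaults to `config$seed`.
#' @return A `psc_scenarios` list: `demand` (K x T x S integer array),
#'   `supply` (T x S integer matrix), `probabilities` (length S), `seed`.
#' @export
generate_scenarios <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "psc_config"))
  T <- config$horizon_days; S <- config$n_scenarios
  K <- length(config$hospitals)
  demand <- array(0L, dim = c(K, T, S))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  for (k in seq_len(K)) {
    d <- config$hospitals[[k]]$demand
    set.seed(child_seed(seed, k))
    demand[k, , ] <- as.integer(round(pmax(0, stats::rnorm(T * S, d$mean, d$sd))))
  }
  sp <- config$blood_center$supply
  set.seed(child_seed(seed, BC_LANE))
  supply <- matrix(as.integer(round(pmax(0, stats::rnorm(T * S, sp$mean, sp$sd)))),
                   nrow = T, ncol = S)
  structure(list(demand = demand, supply = supply,
                 probabilities = rep(1 / S, S), seed = as.integer(seed)),
            class = "psc_scenarios")
}

#' @export
print.psc_scenarios <- function(x, ...) {
  d <- dim(x$demand)
  cat(sprintf("Scenario set: %d hospital(s), %d days, %d scenarios (seed %d)\n",
              d[1], d[2], d[3], x$seed))
  cat(sprintf("  mean demand per hospital: %s; mean supply: %.1f\n",
              paste(sprintf("%.1f", apply(x$demand, 1, mean)), collapse = ", "),
              mean(x$supply)))
  invisible(x)
}

#' Long-format view of a scenario set
#'
#' @param x A `psc_scenarios`.
#' @param ... Unused.
#' @return A data.frame with columns entity, day, scenario, value, where
#'   entity is `"hospital_<k>"` or `"blood_center"`.
#' @export
as.data.frame.psc_scenarios <- function(x, ...) {
  d <- dim(x$demand); K <- d[1]; T <- d[2]; S <- d[3]
  hosp <- data.frame(
    entity = rep(sprintf("hospital_%d", seq_len(K)), times = T * S),
    day = rep(rep(seq_len(T), each = K), times = S),
    scenario = rep(seq_len(S), each = K * T),
    value = as.vector(x$demand))
  bc <- data.frame(entity = "blood_center",
                   day = rep(seq_len(T), times = S),
                   scenario = rep(seq_len(S), each = T),
                   value = as.vector(x$supply))
  rbind(hosp, bc)
}

#' Write / read a scenario set as CSV (long format)
#'
#' @param x A `psc_scenarios`.
#' @param path CSV file path.
#' @return `write_scenarios` returns `path` invisibly; `read_scenarios`
#'   returns a `psc_scenarios`.
#' @export
write_scenarios <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  hosp <- df[grepl("^hospital_", df$entity), ]
  ks <- as.integer(sub("^hospital_", "", hosp$entity))
  K <- max(ks); T <- max(df$day); S <- max(df$scenario)
  demand <- array(0L, dim = c(K, T, S))
  demand[cbind(ks, hosp$day, hosp$scenario)] <- as.integer(hosp$value)
  bc <- df[df$entity == "blood_center", ]
  supply <- matrix(0L, T, S)
  supply[cbind(bc$day, bc$scenario)] <- as.integer(bc$value)
  structure(list(demand = demand, supply = supply,
                 probabilities = rep(1 / S, S), seed = NA_integer_),
            class = "psc_scenarios")
}

check_dims <- function(config, scenarios) {
  d <- dim(scenarios$demand)
  if (d[1] != length(config$hospitals) || d[2] != config$horizon_days ||
      d[3] != config$n_scenarios ||
      nrow(scenarios$supply) != config$horizon_days ||
      ncol(scenarios$supply) != config$n_scenarios)
    stop("scenario dimensions do not match the configuration", call. = FALSE)
  if (abs(sum(scenarios$probabilities) - 1) > 1e-12)
    stop("scenario probabilities must sum to 1", call. = FALSE)
  invisible(TRUE)
}

# Blood-center procurement accumulated onto review days: with a review
# period of 1 the order stream equals the supply stream; otherwise supply
# collected between reviews is ordered in one batch on the review day.
bc_order_stream <- function(config, scenarios) {
  T <- config$horizon_days
  rp <- config$blood_center$review_period_days
  sup <- scenarios$supply
  if (rp == 1L) return(sup)
  orbc <- matrix(0L, T, ncol(sup))
  revs <- seq(rp, T, by = rp)
  prev <- 0L
  for (r in revs) {
    orbc[r, ] <- as.integer(colSums(sup[(prev + 1):r, , drop = FALSE]))
    prev <- r
  }
  orbc
}

# Arrivals of tested units at the blood center: the order stream lagged by
# the procurement lead time; cold start before that (no pre-horizon orders).
bc_arrivals <- function(config, scenarios) {
  T <- config$horizon_days; S <- config$n_scenarios
  lt <- config$blood_center$lead_time_days
  orbc <- bc_order_stream(config, scenarios)
  rebc <- matrix(0L, T, S)
  if (T > lt) rebc[(lt + 1):T, ] <- orbc[1:(T - lt), , drop = FALSE]
  rebc
}
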