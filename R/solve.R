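find_python <- function() {
  p <- Sys.getenv("PLATELETSC_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("no python interpreter found on the PATH; the HiGHS backend needs ",
         "python with numpy and scipy (set PLATELETSC_PYTHON to override)",
         call. = FALSE)
  p
}

solver_script <- function() {
  f <- system.file("python", "solve_milp.py", package = "plateletsc")
  if (!nzchar(f)) {
    # during in-source development (pkgload) inst/ is on the search path root
    f <- system.file("inst", "python", "solve_milp.py", package = "plateletsc")
  }
  if (!nzchar(f)) stop("solver script not found in the installed package", call. = FALSE)
  f
}

#' Solve a built model with HiGHS
#'
#' Hands the sparse model to the open-source HiGHS mixed-integer solver
#' (through the scipy bridge shipped with the package) and extracts all
#' decision arrays. The reported objective is recomputed in R from the
#' unperturbed cost vector, in cents, and also reported in dollars.
#'
#' @param model A `psc_model` from [build_model()].
#' @param gap Relative MIP optimality gap (default 1e-4).
#' @param time_limit Solver wall-clock limit in seconds (default 1800).
#' @param relax Solve the LP relaxation (all integrality dropped); clearly
#'   labelled in the returned object — intended for fast property checks,
#'   not production answers.
#' @param verbose Let the solver print its log.
#' @param enforce_fifo Enforce the intended FIFO semantics. The printed
#'   balance equations leave the paired remaining-demand/leftover variables
#'   complementary only when that is cheapest, and with realistic cost
#'   vectors the optimizer can profit from "free disposal" — expiring
#'   surplus stock a day early to skip a night of holding — which physical
#'   FIFO issuing forbids. When the incumbent violates complementarity
#'   anywhere, the affected scenarios are re-solved exactly (first stage
#'   fixed; scenarios decouple) with explicit complementarity disjunctions,
#'   and the reported `mip_gap` is certified against the first solve's dual
#'   bound.
#' @return A `psc_solution`; see [extract_solution()] for the fields.
#' @export
solve_model <- function(model, gap = 1e-4, time_limit = 1800, relax = FALSE,
                        verbose = FALSE, enforce_fifo = !relax) {
  stopifnot(inherits(model, "psc_model"))
  sol <- solve_model_once(model, gap, time_limit, relax, verbose)
  if (!enforce_fifo) return(sol)
  hard_scens <- integer()
  for (round in 1:6) {
    viol <- complementarity_cells(sol)
    if (is.null(viol) || nrow(viol) == 0L) return(sol)
    res <- repair_second_stage(model, sol, viol, gap = gap,
                               time_limit = time_limit, verbose = verbose)
    if (length(res$infeasible_scens) == 0L) return(res$solution)
    # A relaxed first stage can depend on withholding emergency service to
    # keep later committed shipments feasible; forced FIFO service then has
    # no feasible recourse. Put those scenarios' full complementarity
    # disjunctions into the monolithic model and re-solve.
    hard_scens <- union(hard_scens, res$infeasible_scens)
    if (verbose)
      message(sprintf("FIFO repair infeasible for scenario(s) %s; re-solving monolithically",
                      paste(res$infeasible_scens, collapse = ",")))
    d <- model$dims
    cells <- do.call(rbind, lapply(hard_scens, function(s) rbind(
      expand.grid(kind = "hospital", k = seq_len(d$K), t = seq_len(d$T),
                  l = 1:3, s = s, stringsAsFactors = FALSE),
      expand.grid(kind = "emergency", k = NA_integer_, t = seq_len(d$T),
                  l = 1:3, s = s, stringsAsFactors = FALSE))))
    cells <- unique(rbind(model$compl_cells, cells))
    model <- build_model(model$config, model$scenarios, big_M = model$big_M,
                         strict_fifo = model$strict_fifo, compl_cells = cells)
    sol <- solve_model_once(model, gap, time_limit, relax, verbose)
  }
  stop("FIFO complementarity enforcement did not converge", call. = FALSE)
}

# Re-solve the second stage of the scenarios that violate FIFO
# complementarity, with the first-stage decisions fixed and explicit
# disjunctions active. Given the first stage the scenarios are independent,
# so each repair is a small exact MIP; the stitched solution is feasible for
# the FIFO-constrained program and its optimality gap is certified against
# the relaxation's dual bound. Scenarios with no feasible FIFO recourse are
# reported back for monolithic escalation.
repair_second_stage <- function(model, sol, viol, gap = 1e-4,
                                time_limit = 1800, verbose = FALSE) {
  d <- model$dims
  K <- d$K; T <- d$T; S <- d$S
  x_new <- sol$raw_x
  bad_scen <- sort(unique(viol$s))
  if (verbose)
    message(sprintf("FIFO repair: re-solving %d of %d scenario(s) exactly",
                    length(bad_scen), S))
  cfg1 <- scale_config(model$config, n_scenarios = 1L)
  n_first <- d$ss0
  infeasible <- integer()
  for (s in bad_scen) {
    scen1 <- structure(list(
      demand = model$scenarios$demand[, , s, drop = FALSE],
      supply = model$scenarios$supply[, s, drop = FALSE],
      probabilities = 1, seed = model$scenarios$seed), class = "psc_scenarios")
    sub <- build_model(cfg1, scen1, big_M = model$big_M, strict_fifo = TRUE,
                       tiebreak = 0.01)
    # identical first-stage layout: pin the parent's decisions
    sub$col_lb[seq_len(n_first)] <- x_new[seq_len(n_first)]
    sub$col_ub[seq_len(n_first)] <- x_new[seq_len(n_first)]
    ssol <- tryCatch(
      solve_model_once(sub, gap = min(gap, 1e-6),
                       time_limit = time_limit, verbose = verbose),
      error = function(e) {
        if (grepl("[Ii]nfeasible", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(ssol)) { infeasible <- c(infeasible, s); next }
    block <- d$ss0 + (s - 1L) * d$B + seq_len(d$B)
    x_new[block] <- ssol$raw_x[sub$dims$ss0 + seq_len(d$B)]
  }
  if (length(infeasible))
    return(list(solution = NULL, infeasible_scens = infeasible))
  info <- sol$solver_info
  obj_cents <- sum(model$obj_true * x_new) + model$constant
  # certified relative gap against the phase-one dual bound
  if (!is.null(info$mip_dual_bound)) {
    bound <- info$mip_dual_bound + model$constant
    info$mip_gap <- max(0, (obj_cents - bound) / max(1, abs(obj_cents)))
  }
  out <- extract_solution(model, x_new, info, relaxed = FALSE)
  out$fifo_repaired_scenarios <- bad_scen
  list(solution = out, infeasible_scens = integer())
}

# complementarity-violating cascade cells of a solution (integer tolerance)
complementarity_cells <- function(sol, tol = 0.5) {
  ss <- sol$second_stage
  out <- list()
  w <- which(ss$RDHP * ss$LYHP > tol, arr.ind = TRUE)
  if (nrow(w))
    out[[1L]] <- data.frame(kind = "hospital", k = w[, 1], t = w[, 2],
                            l = w[, 3], s = w[, 4])
  w <- which(ss$RSHBC * ss$LFEBC > tol, arr.ind = TRUE)
  if (nrow(w))
    out[[2L]] <- data.frame(kind = "emergency", k = NA_integer_, t = w[, 1],
                            l = w[, 2], s = w[, 3])
  if (length(out)) do.call(rbind, out) else NULL
}

solve_model_once <- function(model, gap = 1e-4, time_limit = 1800,
                             relax = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "psc_model"))
  wd <- tempfile("pscmilp")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  integ <- if (relax) rep(0L, model$nvar) else model$integrality
  data.table::fwrite(data.table::data.table(
    obj = model$obj, lb = model$col_lb, ub = model$col_ub,
    integrality = integ), file.path(wd, "cols.csv"))
  data.table::fwrite(data.table::data.table(lb = model$row_lb, ub = model$row_ub),
                     file.path(wd, "rows.csv"))
  data.table::fwrite(data.table::data.table(i = model$i, j = model$j, v = model$v),
                     file.path(wd, "mat.csv"))
  jsonlite::write_json(list(ncol = model$nvar, nrow = model$nrow,
                            mip_rel_gap = gap, time_limit = time_limit,
                            verbose = verbose),
                       file.path(wd, "meta.json"), auto_unbox = TRUE)
  py <- find_python()
  out <- tryCatch(
    suppressWarnings(system2(py, c(solver_script(), wd),
                             stdout = if (verbose) "" else TRUE,
                             stderr = if (verbose) "" else TRUE)),
    error = function(e) conditionMessage(e))
  info_file <- file.path(wd, "info.json")
  if (!file.exists(info_file))
    stop("solver backend failed:\n", paste(out, collapse = "\n"), call. = FALSE)
  info <- jsonlite::read_json(info_file)
  sol_file <- file.path(wd, "solution.csv")
  if (!isTRUE(info$success) || !file.exists(sol_file)) {
    hint <- if (identical(info$status, 2L) || grepl("infeasible", tolower(info$message %||% "")))
      " (model infeasible: check that committed shipments never exceed worst-case stock and that initial inventories are consistent)" else ""
    stop("solver did not return a solution: ", info$message %||% "unknown", hint,
         call. = FALSE)
  }
  x <- as.numeric(data.table::fread(sol_file, header = FALSE)[[1]])
  if (!relax) x <- round(x)
  extract_solution(model, x, info, relaxed = relax)
}

#' Extract decision arrays from a raw solution vector
#'
#' @param model The `psc_model` that produced the vector.
#' @param x Numeric solution vector of length `model$nvar`.
#' @param info Solver info list (status, message, mip_gap, ...).
#' @param relaxed Whether this is an LP-relaxation solution.
#' @return A `psc_solution` with elements `first_stage` (ORHP `K x T`,
#'   REHP `K x T x 3`, BCTHP `K x T x 3`, binHP `K x T`), `second_stage`
#'   (RDHP/LYHP/OHHP per hospital-day-age-scenario, HP3, SHRBC, LFRBC, RSHBC,
#'   LFEBC, OHBC, plus derived SHHP, EXHP, EXBC, SHEBC, TSHBC, REBC, binBC),
#'   `objective` (dollars), `objective_cents`, `status`, `mip_gap`,
#'   `config`, `scenarios`.
#' @export
extract_solution <- function(model, x, info = list(), relaxed = FALSE) {
  d <- model$dims
  K <- d$K; T <- d$T; S <- d$S
  tseq <- seq_len(T)
  ss <- function(s, off, t) d$ss0 + (s - 1L) * d$B + off + t
  off_RD <- function(k, l) ((l - 1L) * K + (k - 1L)) * T
  off_LY <- function(k, l) 3L * K * T + ((l - 1L) * K + (k - 1L)) * T
  off_HP3 <- function(k) 6L * K * T + (k - 1L) * T
  off_SHR <- function(k) 7L * K * T + (k - 1L) * T
  off_LFR <- function(l) 8L * K * T + (l - 1L) * T
  off_RSH <- function(l) 8L * K * T + 3L * T + (l - 1L) * T
  off_LFE <- function(l) 8L * K * T + 6L * T + (l - 1L) * T

  BCTHP <- array(0, dim = c(K, T, 3))
  pos <- 0L
  for (k in seq_len(K)) for (a in d$ages[[k]]) {
    BCTHP[k, , a] <- x[pos + tseq]; pos <- pos + T
  }
  binHP <- matrix(x[d$b_off + rep((seq_len(K) - 1L) * T, each = T) + tseq],
                  nrow = K, ncol = T, byrow = TRUE)
  ORHP <- apply(BCTHP, c(1, 2), sum)
  if (K == 1L) ORHP <- matrix(ORHP, nrow = 1L)
  REHP <- array(0, dim = c(K, T, 3))
  for (k in seq_len(K)) {
    ltk <- d$lt[k]
    for (l in seq_len(3L - ltk)) {
      if (T > ltk) REHP[k, (ltk + 1L):T, l] <- BCTHP[k, 1:(T - ltk), l + ltk]
    }
  }

  RD <- array(0, dim = c(K, T, 3, S)); LY <- array(0, dim = c(K, T, 3, S))
  HP3 <- array(0, dim = c(K, T, S)); SHR <- array(0, dim = c(K, T, S))
  LFR <- array(0, dim = c(T, 3, S)); RSH <- array(0, dim = c(T, 3, S))
  LFE <- array(0, dim = c(T, 3, S))
  for (s in seq_len(S)) {
    for (k in seq_len(K)) {
      for (l in 1:3) {
        RD[k, , l, s] <- x[ss(s, off_RD(k, l), tseq)]
        LY[k, , l, s] <- x[ss(s, off_LY(k, l), tseq)]
      }
      HP3[k, , s] <- x[ss(s, off_HP3(k), tseq)]
      SHR[k, , s] <- x[ss(s, off_SHR(k), tseq)]
    }
    for (l in 1:3) {
      LFR[, l, s] <- x[ss(s, off_LFR(l), tseq)]
      RSH[, l, s] <- x[ss(s, off_RSH(l), tseq)]
      LFE[, l, s] <- x[ss(s, off_LFE(l), tseq)]
    }
  }
  # opening inventories reconstructed from the overnight-aging identities
  iniH <- vapply(model$config$hospitals, `[[`, numeric(2), "initial_inventory")
  OHHP <- array(0, dim = c(K, T, 2, S))
  for (k in seq_len(K)) {
    OHHP[k, 1, 1, ] <- iniH[1, k]; OHHP[k, 1, 2, ] <- iniH[2, k]
    if (T > 1L) {
      OHHP[k, 2:T, 1, ] <- LY[k, 1:(T - 1L), 2, , drop = FALSE]
      OHHP[k, 2:T, 2, ] <- LY[k, 1:(T - 1L), 3, , drop = FALSE]
    }
  }
  iniB <- model$config$blood_center$initial_inventory
  OHBC <- array(0, dim = c(T, 2, S))
  OHBC[1, 1, ] <- iniB[["1"]]; OHBC[1, 2, ] <- iniB[["2"]]
  if (T > 1L) {
    OHBC[2:T, 1, ] <- LFE[1:(T - 1L), 2, ]
    OHBC[2:T, 2, ] <- LFE[1:(T - 1L), 3, ]
  }
  SHEBC <- matrix(RSH[, 3, ], nrow = T)
  TSHBC <- matrix(SHEBC + apply(SHR, c(2, 3), sum), nrow = T)

  obj_cents <- sum(model$obj_true * x) + model$constant
  gap <- info$mip_gap
  structure(list(
    first_stage = list(ORHP = ORHP, REHP = REHP, BCTHP = BCTHP, binHP = binHP),
    second_stage = list(RDHP = RD, LYHP = LY, OHHP = OHHP,
                        SHHP = RD[, , 3, , drop = FALSE],
                        EXHP = LY[, , 1, , drop = FALSE],
                        HP3 = HP3, SHRBC = SHR, LFRBC = LFR, RSHBC = RSH,
                        LFEBC = LFE, OHBC = OHBC,
                        EXBC = matrix(LFE[, 1, ], nrow = T),
                        SHEBC = SHEBC, TSHBC = TSHBC,
                        REBC = model$REBC, binBC = (model$REBC > 0) * 1),
    objective = obj_cents / 100,
    objective_cents = obj_cents,
    status = if (isTRUE(info$success)) "optimal" else (info$message %||% "unknown"),
    mip_gap = if (is.null(gap)) NA_real_ else as.numeric(gap),
    relaxed = relaxed,
    raw_x = x,
    solver_info = info,
    config = model$config,
    scenarios = model$scenarios
  ), class = "psc_solution")
}

#' @export
print.psc_solution <- function(x, ...) {
  d <- dim(x$second_stage$RDHP)
  cat(sprintf("Platelet supply-chain solution (%s%s)\n", x$status,
              if (x$relaxed) ", LP relaxation" else ""))
  cat(sprintf("  expected total cost: $%.2f over %d days x %d scenarios ($%.2f /day/scenario)\n",
              x$objective, d[2], d[4], x$objective / d[2]))
  if (!is.na(x$mip_gap)) cat(sprintf("  MIP gap: %.3g\n", x$mip_gap))
  invisible(x)
}

#' @export
summary.psc_solution <- function(object, ...) {
  k <- kpi_summary(object)
  print(object)
  print(k)
  invisible(k)
}

#' Generate scenarios, build and solve in one call
#'
#' @param config A `psc_config`.
#' @param scenarios Optional pre-generated `psc_scenarios` (common random
#'   numbers across sensitivity settings); generated from `config` otherwise.
#' @param ... Passed to [solve_model()] (`gap`, `time_limit`, `relax`, ...).
#' @param big_M,strict_fifo Passed to [build_model()].
#' @return A `psc_solution`.
#' @export
optimize_network <- function(config, scenarios = NULL, big_M = NULL,
                             strict_fifo = FALSE, ...) {
  if (is.null(scenarios)) scenarios <- generate_scenarios(config)
  model <- build_model(config, scenarios, big_M = big_M, strict_fifo = strict_fifo)
  solve_model(model, ...)
}
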