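#' Build the two-stage stochastic MILP
#'
#' Constructs the scenario-based mixed-integer program that chooses
#' nonanticipative hospital orders (equivalently, blood-center shipments by
#' shelf-life age) minimizing expected supply-chain cost over the scenario
#' set. Age-tracked FIFO issuing at the hospitals and at the blood center's
#' regular/emergency fulfillment stages is written as paired
#' remaining-demand / leftover-stock balances whose complementarity is
#' enforced by the strictly positive holding, shortage and outdating costs
#' (an optional `strict_fifo` mode adds explicit big-M disjunctions for
#' degenerate cost vectors).
#'
#' First-stage variables (identical across scenarios): shipments
#' `BCTHP[k,t,l]` of age-`l` units to hospital `k` on day `t` (only ages
#' `l > lead_time` are created: younger units would expire in transit), and
#' binary shipment indicators. Hospital orders `ORHP[k,t]` are the age sums.
#' Second-stage variables per scenario: hospital remaining-demand/leftover
#' cascades, the split of committed age-3 shipments between on-hand stock
#' (`HP3`) and external procurement (`SHRBC`), and the blood center's
#' regular/emergency leftover cascades.
#'
#' Opening-inventory variables are substituted out through the overnight
#' aging identities (opening age-l stock equals yesterday's age-(l+1)
#' leftover), and blood-center procurement is fixed to the realized supply
#' stream (accumulated onto review days and lagged by the procurement lead
#' time), so the model is materially smaller than a literal transcription
#' but decision-equivalent.
#'
#' @param config A `psc_config`.
#' @param scenarios A matching `psc_scenarios`.
#' @param big_M Big-M for the shipment indicators; default
#'   `3 * ceiling(mu_tot + 6 * sigma_tot)` over all hospital demand.
#' @param tiebreak Tiny objective perturbation (cents/unit) on the otherwise
#'   uncosted end-of-horizon leftover variables so the solver returns the
#'   physically meaningful (FIFO-consistent) optimum; the reported objective
#'   is always recomputed from the unperturbed costs.
#' @param strict_fifo Add explicit big-M complementarity disjunctions for
#'   every FIFO cascade up front. The default instead relies on
#'   [solve_model()]'s lazy enforcement: with realistic cost vectors the
#'   pure cost incentive already yields FIFO-complementary solutions almost
#'   everywhere, and the few profitable "free disposal" cells (expiring
#'   surplus stock early to skip a night of holding) are closed on demand.
#' @param compl_cells Optional data.frame of individual cascade cells
#'   (`kind` in `"hospital"`/`"emergency"`, `k`, `t`, `l`, `s`) that receive
#'   an explicit complementarity disjunction; used by [solve_model()]'s lazy
#'   enforcement loop.
#' @return A `psc_model` with sparse constraint triplets, bounds, objective
#'   and index maps.
#' @export
build_model <- function(config, scenarios, big_M = NULL, tiebreak = 0.01,
                        strict_fifo = FALSE, compl_cells = NULL) {
  stopifnot(inherits(config, "psc_config"), inherits(scenarios, "psc_scenarios"))
  check_dims(config, scenarios)
  K <- length(config$hospitals)
  T <- config$horizon_days
  S <- config$n_scenarios
  pb <- scenarios$probabilities
  lt <- vapply(config$hospitals, `[[`, 1L, "lead_time_days")
  rp <- vapply(config$hospitals, `[[`, 1L, "review_period_days")
  ages <- lapply(seq_len(K), function(k) (lt[k] + 1L):MAX_AGE)
  REBC <- bc_arrivals(config, scenarios)  # exogenous arrivals T x S

  if (is.null(big_M)) {
    mu_tot <- sum(vapply(config$hospitals, function(h) h$demand$mean, 0))
    sd_tot <- sum(vapply(config$hospitals, function(h) h$demand$sd, 0))
    big_M <- max(3 * ceiling(mu_tot + 6 * sd_tot), 30)
  }

  # ---- column layout -------------------------------------------------------
  # first stage: x = BCTHP[k, t, l] for l in ages[[k]]; b = binHP[k, t]
  xoff <- vector("list", K)
  pos <- 0L
  for (k in seq_len(K)) {
    off <- stats::setNames(integer(length(ages[[k]])), as.character(ages[[k]]))
    for (a in ages[[k]]) { off[as.character(a)] <- pos; pos <- pos + T }
    xoff[[k]] <- off
  }
  nx <- pos
  b_off <- nx
  ss0 <- nx + K * T                     # start of scenario blocks
  B <- (8L * K + 9L) * T                # per-scenario block size
  nvar_main <- ss0 + S * B

  idx_x <- function(k, t, l) xoff[[k]][[as.character(l)]] + t
  idx_b <- function(k, t) b_off + (k - 1L) * T + t
  ss_at <- function(s, off, t) ss0 + (s - 1L) * B + off + t
  off_RD  <- function(k, l) ((l - 1L) * K + (k - 1L)) * T
  off_LY  <- function(k, l) 3L * K * T + ((l - 1L) * K + (k - 1L)) * T
  off_HP3 <- function(k) 6L * K * T + (k - 1L) * T
  off_SHR <- function(k) 7L * K * T + (k - 1L) * T
  off_LFR <- function(l) 8L * K * T + (l - 1L) * T
  off_RSH <- function(l) 8L * K * T + 3L * T + (l - 1L) * T
  off_LFE <- function(l) 8L * K * T + 6L * T + (l - 1L) * T

  # Explicit FIFO-complementarity binaries. The hospital cascades and the
  # priced end of the emergency cascade are already forced complementary by
  # the strictly positive costs, but when the unmet-emergency end is not
  # priced (bc_shortage_pricing = "regular") the emergency cascade must be
  # closed structurally: otherwise paired remaining-shortage/leftover
  # variables could inflate together and manufacture phantom stock.
  emer_compl <- config$bc_shortage_pricing == "regular" || strict_fifo
  nz_h <- if (strict_fifo) 3L * K * T * S else 0L
  # strict mode closes every emergency age pair (forbids cost-neutral age
  # swaps of the leftovers); the cheaper single-binary closure only blocks
  # profitable phantom stock, which suffices for the relaxation phase
  nz_e <- if (strict_fifo) 3L * T * S else if (emer_compl) T * S else 0L
  nz_c <- if (is.null(compl_cells)) 0L else nrow(compl_cells)
  z0 <- nvar_main
  nvar <- nvar_main + nz_h + nz_e + nz_c

  # ---- triplet accumulators ------------------------------------------------
  ii <- list(); jj <- list(); vv <- list()
  rlb <- list(); rub <- list()
  nrow_cur <- 0L
  push <- function(i, j, v) {
    n <- length(ii) + 1L
    ii[[n]] <<- i; jj[[n]] <<- j; vv[[n]] <<- v
  }
  new_rows <- function(lb, ub = lb) {
    n <- length(lb)
    r <- nrow_cur + seq_len(n)
    nrow_cur <<- nrow_cur + n
    m <- length(rlb) + 1L
    rlb[[m]] <<- lb; rub[[m]] <<- ub
    r
  }

  tseq <- seq_len(T)
  D <- scenarios$demand
  iniH <- vapply(config$hospitals, `[[`, numeric(2), "initial_inventory")  # 2 x K
  iniB <- config$blood_center$initial_inventory

  for (s in seq_len(S)) {
    for (k in seq_len(K)) {
      l1 <- lt[k] + 1L
      # hospital FIFO balance, age 1: RD1 - LY1 + opening1 + receipts1 = demand
      rhs <- as.numeric(D[k, , s]); rhs[1] <- rhs[1] - iniH[1, k]
      r <- new_rows(rhs)
      push(r, ss_at(s, off_RD(k, 1L), tseq), rep(1, T))
      push(r, ss_at(s, off_LY(k, 1L), tseq), rep(-1, T))
      if (T > 1L) push(r[-1L], ss_at(s, off_LY(k, 2L), tseq[-T]), rep(1, T - 1L))
      if (T > lt[k]) push(r[(lt[k] + 1L):T], idx_x(k, 1:(T - lt[k]), l1), rep(1, T - lt[k]))
      # age 2: RD2 - LY2 - RD1 + opening2 + receipts2 = 0
      rhs <- numeric(T); rhs[1] <- -iniH[2, k]
      r <- new_rows(rhs)
      push(r, ss_at(s, off_RD(k, 2L), tseq), rep(1, T))
      push(r, ss_at(s, off_LY(k, 2L), tseq), rep(-1, T))
      push(r, ss_at(s, off_RD(k, 1L), tseq), rep(-1, T))
      if (T > 1L) push(r[-1L], ss_at(s, off_LY(k, 3L), tseq[-T]), rep(1, T - 1L))
      if (lt[k] <= 1L && T > lt[k])
        push(r[(lt[k] + 1L):T], idx_x(k, 1:(T - lt[k]), lt[k] + 2L), rep(1, T - lt[k]))
      # age 3: RD3 - LY3 - RD2 + receipts3 = 0 (age-3 receipts only when lead time 0)
      r <- new_rows(numeric(T))
      push(r, ss_at(s, off_RD(k, 3L), tseq), rep(1, T))
      push(r, ss_at(s, off_LY(k, 3L), tseq), rep(-1, T))
      push(r, ss_at(s, off_RD(k, 2L), tseq), rep(-1, T))
      if (lt[k] == 0L) push(r, idx_x(k, tseq, 3L), rep(1, T))
      # committed age-3 shipments split into stock (HP3) and external (SHRBC)
      r <- new_rows(numeric(T))
      push(r, ss_at(s, off_HP3(k), tseq), rep(1, T))
      push(r, ss_at(s, off_SHR(k), tseq), rep(1, T))
      push(r, idx_x(k, tseq, 3L), rep(-1, T))
    }
    # blood-center regular fulfillment by age (committed + leftover = on hand)
    rhs <- numeric(T); rhs[1] <- iniB[["1"]]
    r <- new_rows(rhs)
    push(r, ss_at(s, off_LFR(1L), tseq), rep(1, T))
    if (T > 1L) push(r[-1L], ss_at(s, off_LFE(2L), tseq[-T]), rep(-1, T - 1L))
    for (k in seq_len(K)) if (lt[k] == 0L) push(r, idx_x(k, tseq, 1L), rep(1, T))
    rhs <- numeric(T); rhs[1] <- iniB[["2"]]
    r <- new_rows(rhs)
    push(r, ss_at(s, off_LFR(2L), tseq), rep(1, T))
    if (T > 1L) push(r[-1L], ss_at(s, off_LFE(3L), tseq[-T]), rep(-1, T - 1L))
    for (k in seq_len(K)) if (lt[k] <= 1L) push(r, idx_x(k, tseq, 2L), rep(1, T))
    r <- new_rows(as.numeric(REBC[, s]))
    push(r, ss_at(s, off_LFR(3L), tseq), rep(1, T))
    for (k in seq_len(K)) push(r, ss_at(s, off_HP3(k), tseq), rep(1, T))
    # emergency FIFO cascade over the regular-stage leftovers
    r <- new_rows(numeric(T))
    push(r, ss_at(s, off_RSH(1L), tseq), rep(1, T))
    push(r, ss_at(s, off_LFE(1L), tseq), rep(-1, T))
    push(r, ss_at(s, off_LFR(1L), tseq), rep(1, T))
    for (k in seq_len(K)) push(r, ss_at(s, off_RD(k, 3L), tseq), rep(-1, T))
    r <- new_rows(numeric(T))
    push(r, ss_at(s, off_RSH(2L), tseq), rep(1, T))
    push(r, ss_at(s, off_LFE(2L), tseq), rep(-1, T))
    push(r, ss_at(s, off_RSH(1L), tseq), rep(-1, T))
    push(r, ss_at(s, off_LFR(2L), tseq), rep(1, T))
    r <- new_rows(numeric(T))
    push(r, ss_at(s, off_RSH(3L), tseq), rep(1, T))
    push(r, ss_at(s, off_LFE(3L), tseq), rep(-1, T))
    push(r, ss_at(s, off_RSH(2L), tseq), rep(-1, T))
    push(r, ss_at(s, off_LFR(3L), tseq), rep(1, T))
  }

  # big-M shipment indicators: sum of a day's committed shipments <= M * bin
  for (k in seq_len(K)) {
    r <- new_rows(rep(-Inf, T), numeric(T))
    for (a in ages[[k]]) push(r, idx_x(k, tseq, a), rep(1, T))
    push(r, idx_b(k, tseq), rep(-big_M, T))
  }

  # explicit complementarity disjunctions: var1 <= M z, var2 <= M (1 - z)
  zi <- z0
  add_compl <- function(off1, off2, s) {
    zc <- zi + tseq; zi <<- zi + T
    r <- new_rows(rep(-Inf, T), numeric(T))
    push(r, ss_at(s, off1, tseq), rep(1, T)); push(r, zc, rep(-big_M, T))
    r <- new_rows(rep(-Inf, T), rep(big_M, T))
    push(r, ss_at(s, off2, tseq), rep(1, T)); push(r, zc, rep(big_M, T))
  }
  if (strict_fifo) {
    for (s in seq_len(S)) for (k in seq_len(K)) for (l in 1:3)
      add_compl(off_RD(k, l), off_LY(k, l), s)
    for (s in seq_len(S)) for (l in 1:3)
      add_compl(off_RSH(l), off_LFE(l), s)
  } else if (emer_compl) {
    # one binary per day-scenario closes the whole emergency cascade:
    # unmet emergency (> 0) forces every leftover to zero, and with any
    # leftover allowed the unmet end is forced to zero. The age split of
    # the leftovers then follows from optimality (younger stock dominates).
    for (s in seq_len(S)) {
      zc <- zi + tseq; zi <- zi + T
      r <- new_rows(rep(-Inf, T), numeric(T))
      push(r, ss_at(s, off_RSH(3L), tseq), rep(1, T)); push(r, zc, rep(-big_M, T))
      r <- new_rows(rep(-Inf, T), rep(big_M, T))
      for (l in 1:3) push(r, ss_at(s, off_LFE(l), tseq), rep(1, T))
      push(r, zc, rep(big_M, T))
    }
  }
  if (nz_c > 0L) {
    # lazily requested per-cell disjunctions (one binary each)
    for (r_i in seq_len(nz_c)) {
      cc <- compl_cells[r_i, ]
      zi <- zi + 1L
      if (cc$kind == "hospital") {
        o1 <- off_RD(cc$k, cc$l); o2 <- off_LY(cc$k, cc$l)
      } else {
        o1 <- off_RSH(cc$l); o2 <- off_LFE(cc$l)
      }
      r <- new_rows(-Inf, 0)
      push(r, ss_at(cc$s, o1, cc$t), 1); push(r, zi, -big_M)
      r <- new_rows(-Inf, big_M)
      push(r, ss_at(cc$s, o2, cc$t), 1); push(r, zi, big_M)
    }
  }

  # ---- bounds and integrality ----------------------------------------------
  col_lb <- numeric(nvar)
  col_ub <- rep(Inf, nvar)
  integrality <- rep(1L, nvar)
  for (k in seq_len(K)) {
    non_review <- tseq[tseq %% rp[k] != 0L]
    for (a in ages[[k]]) {
      col_ub[idx_x(k, tseq, a)] <- big_M
      if (length(non_review)) col_ub[idx_x(k, non_review, a)] <- 0
    }
    col_ub[idx_b(k, tseq)] <- 1
  }
  if (nvar > z0) col_ub[(z0 + 1L):nvar] <- 1

  # ---- objective (cents) ---------------------------------------------------
  cost <- config$costs
  obj <- numeric(nvar)
  for (k in seq_len(K)) {
    for (a in ages[[k]]) obj[idx_x(k, tseq, a)] <- hp_cost(cost, "purchase", k)
    obj[idx_b(k, tseq)] <- hp_cost(cost, "fixed_shipping", k)
  }
  for (s in seq_len(S)) {
    w <- pb[s]
    for (k in seq_len(K)) {
      obj[ss_at(s, off_RD(k, 3L), tseq)] <- w * hp_cost(cost, "shortage", k)
      obj[ss_at(s, off_LY(k, 1L), tseq)] <- w * hp_cost(cost, "outdating", k)
      if (T > 1L) {
        obj[ss_at(s, off_LY(k, 2L), tseq[-T])] <- w * hp_cost(cost, "holding", k)
        obj[ss_at(s, off_LY(k, 3L), tseq[-T])] <- w * hp_cost(cost, "holding", k)
      }
      obj[ss_at(s, off_SHR(k), tseq)] <- w * cost$blood_center$shortage
    }
    obj[ss_at(s, off_LFE(1L), tseq)] <- w * cost$blood_center$outdating
    if (T > 1L) {
      obj[ss_at(s, off_LFE(2L), tseq[-T])] <- w * cost$blood_center$holding
      obj[ss_at(s, off_LFE(3L), tseq[-T])] <- w * cost$blood_center$holding
    }
    if (config$bc_shortage_pricing == "total")
      obj[ss_at(s, off_RSH(3L), tseq)] <- w * cost$blood_center$shortage
  }
  # decision-independent terms: per-day fixed operating costs, supply-driven
  # inbound shipment indicators, and day-1 holding on the initial inventories
  constant <- T * (sum(vapply(seq_len(K), function(k) hp_cost(cost, "fixed_operating", k), 0)) +
                   cost$blood_center$fixed_operating) +
    cost$blood_center$fixed_shipping * sum(pb[col(REBC)] * (REBC > 0)) +
    sum(vapply(seq_len(K), function(k) hp_cost(cost, "holding", k) * sum(iniH[, k]), 0)) +
    cost$blood_center$holding * (iniB[["1"]] + iniB[["2"]])

  # tie-break: end-of-horizon blood-center leftovers are otherwise uncosted,
  # which would leave the reported emergency-shortage bookkeeping degenerate
  obj_solve <- obj
  for (s in seq_len(S))
    obj_solve[c(ss_at(s, off_LFE(2L), T), ss_at(s, off_LFE(3L), T))] <-
      obj_solve[c(ss_at(s, off_LFE(2L), T), ss_at(s, off_LFE(3L), T))] + tiebreak * pb[s]

  structure(list(
    config = config, scenarios = scenarios,
    nvar = nvar, nrow = nrow_cur,
    i = as.integer(unlist(ii)), j = as.integer(unlist(jj)), v = unlist(vv),
    row_lb = unlist(rlb), row_ub = unlist(rub),
    col_lb = col_lb, col_ub = col_ub,
    obj = obj_solve, obj_true = obj, constant = constant,
    integrality = integrality,
    big_M = big_M, strict_fifo = strict_fifo, compl_cells = compl_cells,
    dims = list(K = K, T = T, S = S, lt = lt, rp = rp, ages = ages,
                nx = nx, b_off = b_off, ss0 = ss0, B = B, z0 = z0),
    REBC = REBC
  ), class = "psc_model")
}

#' @export
print.psc_model <- function(x, ...) {
  cat(sprintf("Stochastic platelet supply-chain MILP: %d variables, %d constraints, %d nonzeros\n",
              x$nvar, x$nrow, length(x$v)))
  cat(sprintf("  K=%d hospitals, T=%d days, S=%d scenarios, big-M=%g\n",
              x$dims$K, x$dims$T, x$dims$S, x$big_M))
  invisible(x)
}
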