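#' Validate a solved model against its structural identities
#'
#' Checks, for every applicable index, the identities that the optimizer is
#' expected to satisfy but that are not all hard constraints:
#' FIFO complementarity at the hospitals (remaining demand x leftover stock
#' = 0 at each age) and at the blood center's emergency stage; unit
#' conservation of the hospital demand cascade; overnight aging consistency
#' (each day's opening stock equals yesterday's one-age-older leftover);
#' the blood-center total-shortage identity (total = regular external +
#' unmet emergency); and nonanticipativity of receipts and orders.
#'
#' @param solution A `psc_solution`.
#' @param config,scenarios Defaults from the solution.
#' @param tol Numeric tolerance on each identity.
#' @return A `psc_validation` list: `ok` (logical) and `violations`
#'   (data.frame with check, hospital, day, age, scenario, value).
#' @export
validate_solution <- function(solution, config = NULL, scenarios = NULL,
                              tol = 1e-6) {
  stopifnot(inherits(solution, "psc_solution"))
  config <- config %||% solution$config
  scenarios <- scenarios %||% solution$scenarios
  fs <- solution$first_stage; ss <- solution$second_stage
  K <- dim(ss$RDHP)[1]; T <- dim(ss$RDHP)[2]; S <- dim(ss$RDHP)[4]
  viol <- list()
  flag <- function(check, idx, value) {
    if (length(value) == 0) return()
    viol[[length(viol) + 1L]] <<- data.frame(check = check, idx, value = value)
  }
  # FIFO complementarity: no remaining demand while stock of that age is left
  comp <- ss$RDHP * ss$LYHP
  if (any(bad <- comp > tol)) {
    w <- which(bad, arr.ind = TRUE)
    flag("fifo_complementarity_hospital",
         data.frame(hospital = w[, 1], day = w[, 2], age = w[, 3],
                    scenario = w[, 4]),
         comp[bad])
  }
  compe <- ss$RSHBC * ss$LFEBC
  if (any(bad <- compe > tol)) {
    w <- which(bad, arr.ind = TRUE)
    flag("fifo_complementarity_emergency",
         data.frame(hospital = NA, day = w[, 1], age = w[, 2], scenario = w[, 3]),
         compe[bad])
  }

  # hospital demand cascade conservation (age 1..3 balances)
  D <- scenarios$demand
  REHP <- fs$REHP
  for (k in seq_len(K)) {
    re <- function(l) rep(REHP[k, , l], times = S)
    oh1 <- as.vector(ss$OHHP[k, , 1, ]); oh2 <- as.vector(ss$OHHP[k, , 2, ])
    r1 <- as.vector(ss$RDHP[k, , 1, ]) - as.vector(ss$LYHP[k, , 1, ]) -
      (as.vector(D[k, , ]) - oh1 - re(1))
    r2 <- as.vector(ss$RDHP[k, , 2, ]) - as.vector(ss$LYHP[k, , 2, ]) -
      (as.vector(ss$RDHP[k, , 1, ]) - oh2 - re(2))
    r3 <- as.vector(ss$RDHP[k, , 3, ]) - as.vector(ss$LYHP[k, , 3, ]) -
      (as.vector(ss$RDHP[k, , 2, ]) - re(3))
    for (l in 1:3) {
      r <- list(r1, r2, r3)[[l]]
      if (any(bad <- abs(r) > tol)) {
        w <- which(bad)
        flag("hospital_balance",
             data.frame(hospital = k, day = (w - 1L) %% T + 1L, age = l,
                        scenario = (w - 1L) %/% T + 1L), r[bad])
      }
    }
  }

  # aging consistency: opening stock = yesterday's one-age-older leftover
  if (T > 1L) {
    a1 <- ss$OHHP[, 2:T, 1, , drop = FALSE] - ss$LYHP[, 1:(T - 1), 2, , drop = FALSE]
    a2 <- ss$OHHP[, 2:T, 2, , drop = FALSE] - ss$LYHP[, 1:(T - 1), 3, , drop = FALSE]
    for (a in list(a1, a2)) if (any(bad <- abs(a) > tol)) {
      w <- which(bad, arr.ind = TRUE)
      flag("hospital_aging",
           data.frame(hospital = w[, 1], day = w[, 2] + 1L, age = w[, 3],
                      scenario = w[, 4]), a[bad])
    }
    b1 <- ss$OHBC[2:T, 1, , drop = FALSE] - ss$LFEBC[1:(T - 1), 2, , drop = FALSE]
    b2 <- ss$OHBC[2:T, 2, , drop = FALSE] - ss$LFEBC[1:(T - 1), 3, , drop = FALSE]
    for (b in list(b1, b2)) if (any(bad <- abs(b) > tol)) {
      w <- which(bad, arr.ind = TRUE)
      flag("blood_center_aging",
           data.frame(hospital = NA, day = w[, 1] + 1L, age = w[, 2],
                      scenario = w[, 3]), b[bad])
    }
  }

  # total blood-center shortage identity
  tsh <- ss$TSHBC - (apply(ss$SHRBC, c(2, 3), sum) + ss$SHEBC)
  if (any(bad <- abs(tsh) > tol)) {
    w <- which(bad, arr.ind = TRUE)
    flag("total_shortage_identity",
         data.frame(hospital = NA, day = w[, 1], age = NA, scenario = w[, 2]),
         tsh[bad])
  }

  # nonanticipativity: orders/receipts are stored scenario-invariant by
  # construction; verify the scenario-level shipments respect them
  or2 <- apply(fs$BCTHP, c(1, 2), sum) - fs$ORHP
  if (any(bad <- abs(or2) > tol)) {
    w <- which(bad, arr.ind = TRUE)
    flag("nonanticipativity",
         data.frame(hospital = w[, 1], day = w[, 2], age = NA, scenario = NA),
         or2[bad])
  }

  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(check = character(), hospital = integer(), day = integer(),
               age = integer(), scenario = integer(), value = numeric())
  structure(list(ok = nrow(viol) == 0L, violations = viol,
                 n_checked = K * T * S), class = "psc_validation")
}

#' @export
print.psc_validation <- function(x, ...) {
  if (x$ok) cat("solution validation: all identities hold\n")
  else {
    cat(sprintf("solution validation: %d violation(s)\n", nrow(x$violations)))
    print(utils::head(x$violations, 10))
  }
  invisible(x)
}
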