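# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_nonneg_scalar <- function(x, field, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_field(field, "must be a single nonnegative number")
  if (integer && x != round(x))
    stop_field(field, "must be an integer")
  invisible(x)
}

# Deterministic per-entity child seed derived from a master seed, so that
# adding a hospital never reshuffles another entity's random draws.
# Lane k (>= 1) is the k-th hospital; the blood center uses a fixed high lane.
child_seed <- function(master, lane) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(lane) * 8191 + 1) %% 2147483647)
}

BC_LANE <- 1000000L

# shelf life (days of remaining usability) of platelets at distribution
MAX_AGE <- 3L
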