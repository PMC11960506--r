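# internal helpers shared across modules

# log(exp(a) + exp(b)) without overflow; a, b may be vectors
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

# stable per-stage seed fan-out from a single run seed (kept < 2^31)
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(simulate = 11L, dose = 23L, nmc = 37L, cwm = 53L, report = 71L,
               sequences = 89L, tracks = 97L, shuffle = 101L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else 7L
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%g, %g].", name, lower, upper))
  }
  invisible(x)
}
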