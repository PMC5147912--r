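#' Derive a reproducible child seed from a top-level seed and a string key
#'
#' All stochastic stages draw their randomness from seeds derived
#' deterministically from one top-level run seed, so that per-well results do
#' not depend on processing order.  Keys are hashed with a small polynomial
#' rolling hash; the result always fits in a 32-bit signed integer.
#'
#' @param seed integer top-level seed.
#' @param key character key (e.g. a well id like "B03").
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(key), length(key) == 1L)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% m
  as.integer(h)
}

#' Convert a concentration to micromolar
#'
#' @param value numeric concentration value(s).
#' @param unit one of "M", "mM", "uM", "nM", "pM".
#' @return concentration in micromolar.
#' @export
conc_to_uM <- function(value, unit) {
  fac <- c(M = 1e6, mM = 1e3, uM = 1, nM = 1e-3, pM = 1e-6)
  unit <- as.character(unit)
  if (any(!unit %in% names(fac))) {
    stop("unknown concentration unit: ", paste(setdiff(unit, names(fac)), collapse = ", "))
  }
  value * unname(fac[unit])
}

# standard well names for an 8x12 plate ("A01".."H12")
#' Well names for a rows x cols microplate
#' @param rows,cols plate dimensions (default 8 x 12, a 96-well plate).
#' @return character vector in row-major order, e.g. "A01", "A02", ...
#' @export
well_names <- function(rows = 8, cols = 12) {
  as.vector(t(outer(LETTERS[seq_len(rows)], sprintf("%02d", seq_len(cols)), paste0)))
}
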