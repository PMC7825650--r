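# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (0.005 -> 0.01), matching
#' the convention used when reporting cohort percentages, rather than the
#' round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.125, 2)  # 0.13
#' round(0.125, 2)          # 0.12 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # small epsilon guards against representation error, e.g. 0.485 * 100
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# numeric part of a star-allele name, for canonical ordering: "*3C" -> 3
star_number <- function(allele) {
  as.numeric(sub("^\\*([0-9]+).*$", "\\1", allele))
}

# polynomial rolling hash of a string onto [0, 2^31 - 1); injective enough
# to give distinct noise streams to distinct subject/chromosome ids
string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# deterministic 31-bit stream seed derived from a base seed and indices,
# so that independent series get independent but reproducible noise
derive_seed <- function(seed, i = 0L, j = 0L) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + i * 69621 + j * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
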