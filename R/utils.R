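#' Round half away from zero
#'
#' Decimal rounding with the "half-up" rule used throughout the reports
#' (base R's `round()` rounds half to even, which does not match the usual
#' convention of published percentage tables).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.5, 0)   # 3, not 2
#' round_half_up(83.155, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge past binary representation error before taking the floor
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a total, rounded half-up
#'
#' @param n count.
#' @param total denominator, must be > 0.
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @export
percent_of <- function(n, total, digits = 2) {
  if (any(total <= 0)) stop("total must be > 0")
  round_half_up(100 * n / total, digits)
}

# reverse complement of a plain character vector of DNA strings
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# draw a random DNA string of length n from the active RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
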