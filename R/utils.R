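#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals, as used for
#' the printed percentages in FAERS baseline tables. Base R's `round()`
#' rounds half to even, which disagrees on exact .x5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.25, 0.35), 1) # 0.3 0.4
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# percentage with half-up rounding to 1 decimal, the table-printing convention
pct1 <- function(count, total) round_half_up(100 * count / total, 1)

`%||%` <- function(x, y) if (is.null(x)) y else x

# lowercase + trim, the canonical string normalisation used for PT and
# drug-name matching throughout
norm_str <- function(x) trimws(tolower(x))

stop_faersig <- function(fmt, ..., class = "faersig_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "faersig_error")))
}
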