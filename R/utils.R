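# rounding used for reported percentages: round-half-up, plus an explicit
# truncation variant (some published percentages reflect truncation)

#' Round half-up
#'
#' Rounds to `digits` decimals with halves always rounded away from zero,
#' matching how percentages are conventionally printed (in contrast to R's
#' banker's rounding in [round()]).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' roundHalfUp(86.111)   # 86.1
#' roundHalfUp(0.25, 1)  # 0.3
roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Truncate toward zero at a fixed number of decimals
#'
#' @inheritParams roundHalfUp
#' @return numeric vector.
#' @export
#' @examples
#' truncateDecimal(96.875)  # 96.8
truncateDecimal <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 1e-9) / f
}

# internal: stop unless all(cond), with a formatted message
.assertThat <- function(cond, fmt, ...) {
  if (!all(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# internal: molecule/position composite key
.posKey <- function(molecule, position) paste(molecule, position, sep = "\r")

# internal: canonical ordering of a site-like data.frame
.orderSites <- function(df) {
  df[order(df$molecule_id, df$position), , drop = FALSE]
}
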