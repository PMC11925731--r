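# Built-in modification-type catalogue.
#
# Symbols follow the MODOMICS single-character convention. The `detectable`
# flag records whether the type produces an error signal callable from
# nanopore basecalling errors: s4U, s2C, m5C, mnm5U, lysidine (k2C), m6t6A,
# i6A and m4Cm do not, all other listed types do.
.modTypes <- data.frame(
  symbol = c(
    "D", "*", "ʤ", "/", "4", "V", "M", ")", "$", "S", "{", "K", "6",
    "P", "T", "L", "Ƒ", "?", "E", "Ж", "7", "J", "#", "B",
    "Ç", "ɿ", "λ", "δ", "ζ", "⊄", "Q", "X",
    "}", "+"
  ),
  name = c(
    "D", "ms2i6A", "s2C", "m2A", "s4U", "cmo5U", "ac4C", "cmnm5Um",
    "cmnm5s2U", "mnm5s2U", "mnm5U", "m1G", "t6A", "Y", "m5U", "m2G", "m3Y",
    "m5C", "m6t6A", "m6A", "m7G", "Um", "Gm", "Cm", "ho5C", "m2A37", "m4Cm",
    "m3U", "m66A", "gluQ", "Q", "acp3U", "k2C", "i6A"
  ),
  detectable = c(
    TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
    TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
    TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
    FALSE
  ),
  stringsAsFactors = FALSE
)

#' Modification-type catalogue with detectability flags
#'
#' Returns the built-in table mapping MODOMICS-style single-character
#' modification symbols (and short names) to whether the modification type
#' is detectable by error-based calling. Types whose signal perturbation is
#' too weak to register as basecalling error (for example m5C, s4U, s2C,
#' mnm5U, lysidine, m6t6A, i6A, m4Cm) are flagged \code{FALSE}.
#'
#' @return A data.frame with columns \code{symbol}, \code{name} and
#'   \code{detectable}.
#' @export
#' @examples
#' ct <- modTypeCatalog()
#' ct[ct$name == "m5C", ]
modTypeCatalog <- function() .modTypes

# internal: look up detectability for a vector of symbols or names.
# Unknown entries return NA.
.lookupDetectable <- function(symbols, catalog = modTypeCatalog()) {
  i <- match(symbols, catalog$symbol)
  j <- match(symbols, catalog$name)
  i[is.na(i)] <- j[is.na(i)]
  catalog$detectable[i]
}
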