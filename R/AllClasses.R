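#' ThresholdSet: the four-parameter calling cutoff combination
#'
#' A position is called modified when, simultaneously, its ESB in the native
#' sample is at least \code{esbTestMin}, its ESB in the unmodified control is
#' at most \code{esbControlMax}, its odds ratio is at least \code{oddrMin},
#' and its adjusted p-value is at most \code{padjMax}. All four comparisons
#' are inclusive. ESB cutoffs are on the fraction scale in [0, 1].
#'
#' @slot esbTestMin minimum ESB in the native (test) sample, fraction.
#' @slot esbControlMax maximum ESB in the unmodified control, fraction.
#' @slot oddrMin minimum odds ratio (test vs control error).
#' @slot padjMax maximum adjusted p-value.
#'
#' @param esbTestMin,esbControlMax,oddrMin,padjMax numeric scalars.
#' @return A \code{ThresholdSet} object.
#' @export
#' @examples
#' ThresholdSet(0.1, 0.01, 3, 0.05)
ThresholdSet <- function(esbTestMin = 0.1, esbControlMax = 0.01,
                         oddrMin = 3, padjMax = 0.05) {
  new("ThresholdSet",
      esbTestMin = as.numeric(esbTestMin),
      esbControlMax = as.numeric(esbControlMax),
      oddrMin = as.numeric(oddrMin),
      padjMax = as.numeric(padjMax))
}

#' @rdname ThresholdSet
#' @export
setClass("ThresholdSet",
         representation(esbTestMin = "numeric", esbControlMax = "numeric",
                        oddrMin = "numeric", padjMax = "numeric"),
         validity = function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@esbTestMin) || object@esbTestMin < 0 || object@esbTestMin > 1)
    msg <- c(msg, "esbTestMin must be a single value in [0, 1]")
  if (!one(object@esbControlMax) || object@esbControlMax < 0 ||
      object@esbControlMax > 1)
    msg <- c(msg, "esbControlMax must be a single value in [0, 1]")
  if (!one(object@oddrMin) || object@oddrMin < 0)
    msg <- c(msg, "oddrMin must be a single nonnegative value")
  if (!one(object@padjMax) || object@padjMax < 0 || object@padjMax > 1)
    msg <- c(msg, "padjMax must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn ThresholdSet minimum test-sample ESB.
#' @param x,object a \code{ThresholdSet}.
#' @export
esbTestMin <- function(x) x@esbTestMin
#' @describeIn ThresholdSet maximum control-sample ESB.
#' @export
esbControlMax <- function(x) x@esbControlMax
#' @describeIn ThresholdSet minimum odds ratio.
#' @export
oddrMin <- function(x) x@oddrMin
#' @describeIn ThresholdSet maximum adjusted p-value.
#' @export
padjMax <- function(x) x@padjMax

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet: ESB test >= ", object@esbTestMin,
      ", ESB control <= ", object@esbControlMax,
      ", OddR >= ", object@oddrMin,
      ", adj. p <= ", object@padjMax, "\n", sep = "")
})

#' GridSpec: candidate cutoff lists for the threshold grid search
#'
#' Holds the ordered candidate values for each of the four calling
#' parameters; the grid search evaluates their full Cartesian product.
#' The default grid has 20 x 20 x 20 x 4 = 32,000 combinations and contains
#' the conventional cutoff set (0.1, 0.01, 3, 0.05) as a member; ESB values
#' are on the fraction scale.
#'
#' @slot esbTestValues,esbControlValues,oddrValues,padjValues strictly
#'   increasing numeric vectors of candidate cutoffs.
#'
#' @param esbTestValues,esbControlValues,oddrValues,padjValues numeric
#'   vectors of candidate cutoffs (strictly increasing).
#' @return A \code{GridSpec} object.
#' @export
#' @examples
#' g <- GridSpec()
#' gridSize(g)  # 32000
GridSpec <- function(esbTestValues = seq(0.01, 0.20, by = 0.01),
                     esbControlValues = seq(0.001, 0.020, by = 0.001),
                     oddrValues = seq(0.5, 10, by = 0.5),
                     padjValues = c(1e-5, 0.001, 0.01, 0.05)) {
  new("GridSpec",
      esbTestValues = as.numeric(esbTestValues),
      esbControlValues = as.numeric(esbControlValues),
      oddrValues = as.numeric(oddrValues),
      padjValues = as.numeric(padjValues))
}

#' @rdname GridSpec
#' @export
setClass("GridSpec",
         representation(esbTestValues = "numeric",
                        esbControlValues = "numeric",
                        oddrValues = "numeric",
                        padjValues = "numeric"),
         validity = function(object) {
  msg <- character()
  chk <- function(v, nm) {
    if (!length(v)) return(paste(nm, "must be nonempty"))
    if (any(!is.finite(v))) return(paste(nm, "must be finite"))
    if (is.unsorted(v, strictly = TRUE)) return(paste(nm, "must be strictly increasing"))
    NULL
  }
  msg <- c(msg, chk(object@esbTestValues, "esbTestValues"),
           chk(object@esbControlValues, "esbControlValues"),
           chk(object@oddrValues, "oddrValues"),
           chk(object@padjValues, "padjValues"))
  if (length(msg)) msg else TRUE
})

#' @describeIn GridSpec total number of threshold combinations.
#' @param x,object a \code{GridSpec}.
#' @export
gridSize <- function(x) {
  length(x@esbTestValues) * length(x@esbControlValues) *
    length(x@oddrValues) * length(x@padjValues)
}

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec with", gridSize(object), "combinations:\n")
  cat("  ESB test:   ", length(object@esbTestValues), "values in [",
      min(object@esbTestValues), ",", max(object@esbTestValues), "]\n")
  cat("  ESB control:", length(object@esbControlValues), "values in [",
      min(object@esbControlValues), ",", max(object@esbControlValues), "]\n")
  cat("  OddR:       ", length(object@oddrValues), "values in [",
      min(object@oddrValues), ",", max(object@oddrValues), "]\n")
  cat("  adj. p:     ", length(object@padjValues), "values in [",
      min(object@padjValues), ",", max(object@padjValues), "]\n")
})
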