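# Threshold application, candidate filters, five-way detection
# classification, region-tolerant precision/recall and the grid search.

#' Apply a threshold set to a site table
#'
#' A position is called modified iff \code{esb_test >= esbTestMin},
#' \code{esb_control <= esbControlMax}, \code{odds_ratio >= oddrMin} and
#' \code{p_adj <= padjMax}; all four comparisons are inclusive.
#'
#' @param sites a validated site table (see \code{\link{readSiteTable}}).
#' @param thresholds a \code{\link{ThresholdSet}}.
#' @return The subset of \code{sites} called modified, ordered by molecule
#'   and position.
#' @export
#' @examples
#' s <- data.frame(molecule_id = "16S", position = 1518, ref_base = "A",
#'                 esb_test = 0.61, esb_control = 0.002, odds_ratio = 5,
#'                 p_adj = 1e-8, depth = 100)
#' nrow(applyThresholds(s, ThresholdSet(0.1, 0.01, 3, 0.05)))  # 1
applyThresholds <- function(sites, thresholds) {
  stopifnot(is(thresholds, "ThresholdSet"))
  pass <- sites$esb_test >= thresholds@esbTestMin &
    sites$esb_control <= thresholds@esbControlMax &
    sites$odds_ratio >= thresholds@oddrMin &
    sites$p_adj <= thresholds@padjMax
  out <- .orderSites(sites[pass, , drop = FALSE])
  rownames(out) <- NULL
  out
}

# tool-specific candidate rules; comparisons preserved exactly as published
# (note DRUMMER mixes inclusive OddR with strict p cutoffs, and CHEUI-solo
# requires probability >= 0.9999 in the native sample but < 0.999 in the
# control)
.candidateRules <- list(
  eligos = function(df) df$odds_ratio >= 2.5 & df$p_adj <= 1e-5,
  nanocompore = function(df) df$p_gmm <= 0.01,
  cheui_diff = function(df) df$stoich_diff >= 0.1 & df$p_adj <= 0.05,
  drummer = function(df) df$odds_ratio >= 1.5 & df$p_g < 0.05 &
    df$p_oddr < 0.05,
  cheui_solo = function(df) df$p_wt >= 0.9999 & df$p_ivt < 0.999
)

#' Tool-specific candidate filters
#'
#' Applies the published per-tool candidate rule to a table of caller
#' output rows. Available rules and the columns they require:
#' \describe{
#'   \item{eligos}{\code{odds_ratio >= 2.5} and \code{p_adj <= 1e-5}.}
#'   \item{nanocompore}{GMM logit \code{p_gmm <= 0.01}.}
#'   \item{cheui_diff}{stoichiometry difference \code{stoich_diff >= 0.1}
#'     and \code{p_adj <= 0.05}.}
#'   \item{drummer}{\code{odds_ratio >= 1.5}, G-test \code{p_g < 0.05} and
#'     odds-ratio \code{p_oddr < 0.05}.}
#'   \item{cheui_solo}{site probability \code{p_wt >= 0.9999} in the native
#'     sample and \code{p_ivt < 0.999} in the control.}
#' }
#'
#' @param rows data.frame of caller output carrying the fields the rule
#'   tests plus \code{molecule_id} and \code{position}.
#' @param rule rule name, one of \code{names(candidateRules())}.
#' @return The retained subset of \code{rows}.
#' @export
candidateFilter <- function(rows, rule) {
  .assertThat(rule %in% names(.candidateRules), "unknown rule: %s", rule)
  keep <- .candidateRules[[rule]](rows)
  .assertThat(!anyNA(keep),
              "rows are missing fields required by rule '%s'", rule)
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn candidateFilter names of the available rules.
#' @export
candidateRules <- function() names(.candidateRules)

#' Classify known sites into five detection categories
#'
#' Each catalogued site is assigned exactly one category, by precedence:
#' \code{type_not_detectable} (the modification type produces no error
#' signal), then \code{depth_insufficient} (molecule read depth below
#' \code{minDepth}), then \code{detected} (a called position at the exact
#' site), then \code{detected_with_offset} (a called position within
#' \code{offsetWindow} nt; the nearest hit, ties resolved to the upstream,
#' i.e. smaller, position), else \code{not_detected}.
#'
#' @param called data.frame of called positions with columns
#'   \code{molecule_id} and \code{position}.
#' @param known known-site catalogue (see \code{\link{readKnownSites}}).
#' @param depth named numeric vector of read depth per molecule; must cover
#'   every molecule carrying a known site.
#' @param minDepth minimum read depth for reliable calling (default 20).
#' @param offsetWindow offset tolerance in nt (default 10).
#' @return \code{known} with added columns \code{category} and
#'   \code{offset_nt} (signed called-minus-known offset, only for
#'   \code{detected_with_offset}).
#' @export
classifyKnownSites <- function(called, known, depth, minDepth = 20,
                               offsetWindow = 10) {
  .assertThat(all(known$molecule_id %in% names(depth)),
              "no depth for molecule(s): %s",
              paste(setdiff(known$molecule_id, names(depth)), collapse = ", "))
  calledBy <- split(called$position, called$molecule_id)
  n <- nrow(known)
  category <- character(n)
  offset <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (isFALSE(known$detectable[i])) {
      category[i] <- "type_not_detectable"
    } else if (depth[[known$molecule_id[i]]] < minDepth) {
      category[i] <- "depth_insufficient"
    } else {
      pos <- calledBy[[known$molecule_id[i]]]
      d <- pos - known$position[i]
      if (any(d == 0)) {
        category[i] <- "detected"
      } else if (any(abs(d) <= offsetWindow)) {
        category[i] <- "detected_with_offset"
        d <- d[abs(d) <= offsetWindow]
        best <- d[abs(d) == min(abs(d))]
        offset[i] <- as.integer(min(best))  # tie -> upstream hit
      } else {
        category[i] <- "not_detected"
      }
    }
  }
  known$category <- category
  known$offset_nt <- offset
  known
}

#' Region-tolerant precision and exact-site recall
#'
#' Called positions are merged into maximal runs of adjacent positions
#' (signal regions). A region counts as TRUE if it contains a known site or
#' lies within \code{tolerance} nt of one on the same molecule; precision is
#' the fraction of TRUE regions. Recall is computed from known sites only:
#' a site counts as detected when a called position lies at the exact site
#' (widen with \code{recallTolerance}).
#'
#' @inheritParams classifyKnownSites
#' @param tolerance region-matching tolerance in nt (default 10).
#' @param recallTolerance matching window for recall (default 0 = exact).
#' @param detectableOnly if TRUE, known sites whose type is not detectable
#'   are excluded from both precision matching and the recall denominator
#'   (default FALSE: nothing is excluded).
#' @return A one-row data.frame (a precision/recall point) with columns
#'   \code{true_regions}, \code{false_regions}, \code{known_detected},
#'   \code{known_total}, \code{precision}, \code{recall}. With no called
#'   positions, precision is \code{NA} and recall 0.
#' @export
#' @examples
#' called <- data.frame(molecule_id = "16S", position = 5:8)
#' known <- data.frame(molecule_id = "16S", position = 12,
#'                     mod_symbol = "P", detectable = TRUE)
#' precisionRecall(called, known)$precision  # 1: region end 8 is 4 nt away
precisionRecall <- function(called, known, tolerance = 10,
                            recallTolerance = 0, detectableOnly = FALSE) {
  if (detectableOnly) {
    # unknown detectability is retained; only known-undetectable types drop
    keep <- is.na(known$detectable) | known$detectable
    known <- known[keep, , drop = FALSE]
  }
  knownTotal <- nrow(known)
  regions <- mergeRegions(called)
  nReg <- length(regions)

  if (nReg == 0L) {
    return(data.frame(true_regions = 0L, false_regions = 0L,
                      known_detected = 0L, known_total = knownTotal,
                      precision = NA_real_, recall = 0))
  }
  knownGR <- GRanges(known$molecule_id,
                     IRanges(known$position, known$position))
  padded <- suppressWarnings(
    GenomicRanges::resize(regions, width(regions) + 2 * tolerance,
                          fix = "center"))
  isTrue <- suppressWarnings(
    GenomicRanges::countOverlaps(padded, knownGR) > 0)

  if (recallTolerance == 0) {
    hit <- .posKey(known$molecule_id, known$position) %in%
      .posKey(called$molecule_id, called$position)
  } else {
    padKnown <- GRanges(known$molecule_id,
                        IRanges(known$position - recallTolerance,
                                known$position + recallTolerance))
    callGR <- GRanges(called$molecule_id,
                      IRanges(called$position, called$position))
    hit <- suppressWarnings(
      GenomicRanges::countOverlaps(padKnown, callGR) > 0)
  }
  data.frame(true_regions = sum(isTrue),
             false_regions = sum(!isTrue),
             known_detected = sum(hit),
             known_total = knownTotal,
             precision = sum(isTrue) / nReg,
             recall = if (knownTotal > 0) sum(hit) / knownTotal else NA_real_)
}

#' Grid search for the threshold combination maximizing recall at a
#' precision floor
#'
#' Evaluates \code{\link{precisionRecall}} for every combination in the
#' grid's Cartesian product and selects the combination with the highest
#' recall among those with precision at or above \code{precisionFloor}.
#' Among recall ties the least restrictive value of each parameter is
#' selected, one parameter at a time in the fixed order adjusted p, ESB
#' control, OddR, ESB test, accepting a relaxation only when it leaves both
#' precision and recall unchanged.
#'
#' @inheritParams precisionRecall
#' @param sites a validated site table.
#' @param grid a \code{\link{GridSpec}}.
#' @param precisionFloor minimum acceptable precision (default 0.85).
#' @return A list with \code{best} (a \code{\link{ThresholdSet}}, or
#'   \code{NULL} with a warning when no combination reaches the floor),
#'   \code{bestPoint} (its precision/recall row) and \code{landscape}
#'   (a data.frame of all evaluated combinations).
#' @export
gridSearch <- function(sites, known, grid, precisionFloor = 0.85,
                       tolerance = 10, recallTolerance = 0,
                       detectableOnly = FALSE) {
  stopifnot(is(grid, "GridSpec"))
  combos <- expand.grid(esb_test_min = grid@esbTestValues,
                        esb_control_max = grid@esbControlValues,
                        oddr_min = grid@oddrValues,
                        padj_max = grid@padjValues,
                        KEEP.OUT.ATTRS = FALSE)
  # per-parameter pass masks, combined per combination
  mTest <- outer(sites$esb_test, grid@esbTestValues, `>=`)
  mCtrl <- outer(sites$esb_control, grid@esbControlValues, `<=`)
  mOddr <- outer(sites$odds_ratio, grid@oddrValues, `>=`)
  mPadj <- outer(sites$p_adj, grid@padjValues, `<=`)
  iTest <- match(combos$esb_test_min, grid@esbTestValues)
  iCtrl <- match(combos$esb_control_max, grid@esbControlValues)
  iOddr <- match(combos$oddr_min, grid@oddrValues)
  iPadj <- match(combos$padj_max, grid@padjValues)

  pts <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    pass <- mTest[, iTest[k]] & mCtrl[, iCtrl[k]] & mOddr[, iOddr[k]] &
      mPadj[, iPadj[k]]
    pts[[k]] <- precisionRecall(sites[pass, , drop = FALSE], known,
                                tolerance = tolerance,
                                recallTolerance = recallTolerance,
                                detectableOnly = detectableOnly)
  }
  landscape <- cbind(combos, do.call(rbind, pts))

  feasible <- which(!is.na(landscape$precision) &
                      landscape$precision >= precisionFloor)
  if (length(feasible) == 0L) {
    warning("no threshold combination reaches precision >= ", precisionFloor)
    return(list(best = NULL, bestPoint = NULL, landscape = landscape))
  }
  maxRecall <- max(landscape$recall[feasible])
  cand <- feasible[landscape$recall[feasible] == maxRecall]
  # deterministic start: the most restrictive argmax-recall combination
  o <- order(-landscape$esb_test_min[cand], landscape$esb_control_max[cand],
             -landscape$oddr_min[cand], landscape$padj_max[cand])
  cur <- landscape[cand[o[1L]], , drop = FALSE]

  # relax one parameter at a time; "least restrictive" means the largest
  # padj_max / esb_control_max and the smallest oddr_min / esb_test_min
  relaxOrder <- list(
    list(par = "padj_max", pick = max),
    list(par = "esb_control_max", pick = max),
    list(par = "oddr_min", pick = min),
    list(par = "esb_test_min", pick = min))
  others <- function(par) setdiff(c("esb_test_min", "esb_control_max",
                                    "oddr_min", "padj_max"), par)
  for (r in relaxOrder) {
    sameOthers <- rep(TRUE, nrow(landscape))
    for (p in others(r$par)) {
      sameOthers <- sameOthers & landscape[[p]] == cur[[p]]
    }
    ok <- sameOthers & !is.na(landscape$precision) &
      landscape$precision == cur$precision & landscape$recall == cur$recall
    if (any(ok)) {
      v <- r$pick(landscape[[r$par]][ok])
      cur <- landscape[which(ok & landscape[[r$par]] == v)[1L], ,
                       drop = FALSE]
    }
  }
  best <- ThresholdSet(cur$esb_test_min, cur$esb_control_max, cur$oddr_min,
                       cur$padj_max)
  list(best = best, bestPoint = cur, landscape = landscape)
}

#' Summarize detection outcomes
#'
#' Tabulates the five detection categories and reports recall percentages
#' overall (detected plus detected-with-offset over all catalogued sites),
#' among detectable types, and among detectable types on sufficiently
#' covered molecules. Percentages are rounded half-up to one decimal; a
#' truncated-to-one-decimal column is reported alongside so either printing
#' convention can be audited against the raw fraction.
#'
#' @param outcomes data.frame from \code{\link{classifyKnownSites}}.
#' @return A list with elements \code{categories} (count, fraction, percent
#'   per category), \code{recall} (one row per denominator: overall,
#'   detectable, covered_detectable), and \code{molecules} (number of
#'   molecules carrying known sites and the fraction with sufficient
#'   depth).
#' @export
detectionSummary <- function(outcomes) {
  .assertThat(nrow(outcomes) > 0L, "no detection outcomes to summarize")
  levs <- c("detected", "detected_with_offset", "type_not_detectable",
            "depth_insufficient", "not_detected")
  counts <- table(factor(outcomes$category, levels = levs))
  total <- nrow(outcomes)
  categories <- data.frame(
    category = levs,
    count = as.integer(counts),
    fraction = as.numeric(counts) / total,
    percent = roundHalfUp(100 * as.numeric(counts) / total),
    percent_truncated = truncateDecimal(100 * as.numeric(counts) / total),
    row.names = NULL)

  identified <- sum(counts[c("detected", "detected_with_offset")])
  denoms <- c(
    overall = total,
    detectable = total - as.integer(counts["type_not_detectable"]),
    covered_detectable = total - as.integer(counts["type_not_detectable"]) -
      as.integer(counts["depth_insufficient"]))
  recall <- data.frame(
    denominator = names(denoms),
    identified = as.integer(identified),
    total = as.integer(denoms),
    fraction = ifelse(denoms > 0, identified / denoms, NA_real_),
    row.names = NULL)
  recall$percent <- roundHalfUp(100 * recall$fraction)
  recall$percent_truncated <- truncateDecimal(100 * recall$fraction)

  mols <- unique(outcomes$molecule_id)
  uncovered <- unique(outcomes$molecule_id[
    outcomes$category == "depth_insufficient"])
  molecules <- data.frame(
    n_molecules = length(mols),
    n_covered = length(mols) - length(uncovered),
    fraction_covered = (length(mols) - length(uncovered)) / length(mols))
  molecules$percent_covered <- roundHalfUp(100 * molecules$fraction_covered)

  list(categories = categories, recall = recall, molecules = molecules)
}
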