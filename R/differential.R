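# Condition comparison: delta-ESB records, shared/unique labelling and
# cross-validation against mass-spectrometry ratios.

#' Compute delta-ESB records between two conditions
#'
#' For every position called modified in either condition, computes
#' delta-ESB = ESB test - ESB control per condition. Where a position is
#' not detected (called) in a condition, its delta-ESB in that condition is
#' set to 0. The change label compares the two deltas: \code{increased}
#' when delta in condition b exceeds condition a by more than \code{eps},
#' \code{decreased} when it falls short by more than \code{eps}, else
#' \code{unchanged}.
#'
#' @param sitesA,sitesB validated site tables for conditions a and b.
#' @param calledA,calledB called subsets (e.g. from
#'   \code{\link{applyThresholds}}) with \code{molecule_id} and
#'   \code{position}.
#' @param eps half-width of the unchanged band on the fraction scale
#'   (default 1e-6).
#' @return A data.frame with one row per position in the union of called
#'   sets: ESB columns per condition, \code{delta_a}, \code{delta_b},
#'   \code{ratio} (delta_b / delta_a; \code{NA} when delta_a is 0) and
#'   \code{change}.
#' @export
computeDeltaEsb <- function(sitesA, sitesB, calledA, calledB, eps = 1e-6) {
  keyA <- .posKey(calledA$molecule_id, calledA$position)
  keyB <- .posKey(calledB$molecule_id, calledB$position)
  allCalled <- rbind(calledA[, c("molecule_id", "position")],
                     calledB[, c("molecule_id", "position")])
  allCalled <- .orderSites(allCalled[!duplicated(
    .posKey(allCalled$molecule_id, allCalled$position)), , drop = FALSE])
  key <- .posKey(allCalled$molecule_id, allCalled$position)

  lookup <- function(sites, what) {
    i <- match(key, .posKey(sites$molecule_id, sites$position))
    sites[[what]][i]
  }
  out <- data.frame(
    molecule_id = allCalled$molecule_id,
    position = allCalled$position,
    esb_test_a = lookup(sitesA, "esb_test"),
    esb_control_a = lookup(sitesA, "esb_control"),
    esb_test_b = lookup(sitesB, "esb_test"),
    esb_control_b = lookup(sitesB, "esb_control"),
    stringsAsFactors = FALSE)
  inA <- key %in% keyA
  inB <- key %in% keyB
  out$delta_a <- ifelse(inA, out$esb_test_a - out$esb_control_a, 0)
  out$delta_b <- ifelse(inB, out$esb_test_b - out$esb_control_b, 0)
  out$delta_a[is.na(out$delta_a)] <- 0
  out$delta_b[is.na(out$delta_b)] <- 0
  out$ratio <- ifelse(out$delta_a != 0, out$delta_b / out$delta_a, NA_real_)
  d <- out$delta_b - out$delta_a
  out$change <- ifelse(d > eps, "increased",
                       ifelse(d < -eps, "decreased", "unchanged"))
  rownames(out) <- NULL
  out
}

#' Label called positions as shared or unique between conditions
#'
#' Positions called in both conditions are \code{shared}. A position called
#' in only one condition is a \code{modification_in_unique_rna} when its
#' molecule falls below \code{minDepth} reads in exactly one condition
#' (the transcript itself is effectively absent there), otherwise a
#' \code{unique_modification}.
#'
#' @inheritParams computeDeltaEsb
#' @param depthA,depthB named numeric vectors of per-molecule read depth in
#'   each condition; must cover every molecule with a call.
#' @param minDepth minimum depth for a molecule to count as present
#'   (default 20).
#' @param delta optional delta-ESB records from
#'   \code{\link{computeDeltaEsb}}; when given, the summary reports the
#'   fraction of shared positions with \code{change == "increased"}.
#' @return A list with \code{status} (one row per called position:
#'   \code{molecule_id}, \code{position}, \code{status}) and \code{summary}
#'   (counts per status, plus \code{fraction_shared_increased} when
#'   \code{delta} is supplied).
#' @export
compareConditions <- function(calledA, calledB, depthA, depthB,
                              minDepth = 20, delta = NULL) {
  keyA <- .posKey(calledA$molecule_id, calledA$position)
  keyB <- .posKey(calledB$molecule_id, calledB$position)
  allCalled <- rbind(calledA[, c("molecule_id", "position")],
                     calledB[, c("molecule_id", "position")])
  allCalled <- .orderSites(allCalled[!duplicated(
    .posKey(allCalled$molecule_id, allCalled$position)), , drop = FALSE])
  mols <- unique(allCalled$molecule_id)
  .assertThat(all(mols %in% names(depthA)) && all(mols %in% names(depthB)),
              "depth map(s) missing molecule(s): %s",
              paste(setdiff(mols, intersect(names(depthA), names(depthB))),
                    collapse = ", "))
  key <- .posKey(allCalled$molecule_id, allCalled$position)
  inA <- key %in% keyA
  inB <- key %in% keyB
  lowA <- depthA[allCalled$molecule_id] < minDepth
  lowB <- depthB[allCalled$molecule_id] < minDepth
  uniqueRna <- xor(lowA, lowB)
  status <- ifelse(inA & inB, "shared",
                   ifelse(uniqueRna, "modification_in_unique_rna",
                          "unique_modification"))
  statusDf <- data.frame(molecule_id = allCalled$molecule_id,
                         position = allCalled$position,
                         status = status, stringsAsFactors = FALSE)
  levs <- c("shared", "unique_modification", "modification_in_unique_rna")
  summary <- as.list(table(factor(status, levels = levs)))
  summary <- lapply(summary, as.integer)
  if (!is.null(delta)) {
    shared <- key[status == "shared"]
    dk <- .posKey(delta$molecule_id, delta$position)
    ch <- delta$change[match(shared, dk)]
    summary$n_shared_comparable <- sum(!is.na(ch))
    summary$fraction_shared_increased <-
      if (any(!is.na(ch))) mean(ch == "increased", na.rm = TRUE) else NA_real_
  }
  list(status = statusDf, summary = summary)
}

#' Known-site positions detected in a dataset
#'
#' For stoichiometry-style analyses at catalogued sites, a position counts
#' as detected in a dataset when the caller reports it on a molecule with
#' sufficient read depth; the strict four-parameter calling cutoffs are not
#' applied. This is the detection notion under which delta-ESB is zeroed
#' for positions missing from a dataset.
#'
#' @param sites a validated site table.
#' @param known known-site catalogue (see \code{\link{readKnownSites}}).
#' @param minDepth minimum read depth (default 20).
#' @return The rows of \code{sites} at catalogued positions with depth at
#'   or above \code{minDepth}.
#' @export
detectedSites <- function(sites, known, minDepth = 20) {
  hit <- .posKey(sites$molecule_id, sites$position) %in%
    .posKey(known$molecule_id, known$position)
  out <- sites[hit & sites$depth >= minDepth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate sequencing-derived and MS-derived modification changes
#'
#' Cross-validates delta-ESB changes against mass spectrometry: for each
#' modification type, the sequencing ratio is mean(delta-ESB in condition
#' b) / mean(delta-ESB in condition a) over that type's sites, and the MS
#' ratio is mean abundance(b) / mean abundance(a). The paired ratios are
#' compared by Pearson correlation.
#'
#' @param delta delta-ESB records (from \code{\link{computeDeltaEsb}}) with
#'   an added \code{mod_type} column naming each position's modification
#'   type.
#' @param ms MS table with columns \code{mod_name}, \code{condition},
#'   \code{abundance} (see \code{\link{readAssayTables}}).
#' @param conditionA,conditionB the MS \code{condition} labels paired with
#'   delta columns a and b.
#' @return A list with \code{rho} (Pearson correlation), \code{p}
#'   (two-sided p-value) and \code{pairs} (the paired ratio table).
#' @export
msCorrelation <- function(delta, ms, conditionA, conditionB) {
  .assertThat(!is.null(delta$mod_type),
              "delta records need a mod_type column")
  msA <- ms[ms$condition == conditionA, , drop = FALSE]
  msB <- ms[ms$condition == conditionB, , drop = FALSE]
  .assertThat(nrow(msA) > 0L && nrow(msB) > 0L,
              "MS table lacks condition '%s' or '%s'", conditionA, conditionB)
  mA <- tapply(msA$abundance, msA$mod_name, mean)
  mB <- tapply(msB$abundance, msB$mod_name, mean)
  msTypes <- intersect(names(mA), names(mB))
  msRatio <- mB[msTypes] / mA[msTypes]

  da <- tapply(delta$delta_a, delta$mod_type, mean)
  db <- tapply(delta$delta_b, delta$mod_type, mean)
  seqRatio <- db / da[names(db)]

  types <- intersect(names(msRatio), names(seqRatio))
  pairs <- data.frame(mod_type = types,
                      seq_ratio = as.numeric(seqRatio[types]),
                      ms_ratio = as.numeric(msRatio[types]),
                      stringsAsFactors = FALSE)
  bad <- !is.finite(pairs$seq_ratio) | !is.finite(pairs$ms_ratio) |
    pairs$seq_ratio <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " modification type(s) with undefined or nonpositive ratios")
    pairs <- pairs[!bad, , drop = FALSE]
  }
  .assertThat(nrow(pairs) >= 3L,
              "need at least 3 paired modification types, have %d",
              nrow(pairs))
  .assertThat(stats::sd(pairs$seq_ratio) > 0 && stats::sd(pairs$ms_ratio) > 0,
              "zero variance in one of the ratio vectors")
  ct <- cor.test(pairs$seq_ratio, pairs$ms_ratio, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, pairs = pairs)
}
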