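# SELECT single-base qPCR: delta-delta-CT computation and modified /
# unmodified classification.
#
# An m6A at the interrogated base hinders single-base elongation and nick
# ligation, delaying amplification of the target oligo relative to the
# nearby unmodified-A control oligo; the delay shows up as a more negative
# delta-CT difference between the native sample and a reference sample
# (IVT RNA or a demethylase-mutant RNA) that lacks the modification.

#' Classify SELECT assays by the delta-delta-CT rule
#'
#' Per assay and sample type, delta-CT = CT(target) - CT(A control) is
#' averaged over replicates; delta-delta-CT = delta-CT(WT) -
#' delta-CT(reference). An assay classifies as modified when delta-delta-CT
#' is at or below -1.
#'
#' @param ct CT table (see \code{\link{readAssayTables}}) with columns
#'   \code{assay_id}, \code{sample_type}, \code{replicate},
#'   \code{ct_target}, \code{ct_control_a}.
#' @param refType reference sample type, \code{"IVT"} or \code{"Mut"}.
#' @return A data.frame with one row per assay: \code{delta_ct_wt},
#'   \code{delta_ct_ref}, their replicate standard deviations, \code{ddct}
#'   and \code{classified_modified}.
#' @export
#' @examples
#' ct <- data.frame(assay_id = "23S_A2030",
#'                  sample_type = rep(c("WT", "IVT"), each = 2),
#'                  replicate = c(1, 2, 1, 2),
#'                  ct_target = c(24.5, 24.5, 22.0, 22.0),
#'                  ct_control_a = c(22.0, 22.0, 22.0, 22.0))
#' selectClassify(ct, "IVT")$ddct  # -2.5
selectClassify <- function(ct, refType = c("IVT", "Mut")) {
  refType <- match.arg(refType)
  out <- lapply(split(ct, ct$assay_id), function(a) {
    dct <- a$ct_target - a$ct_control_a
    wt <- dct[a$sample_type == "WT"]
    ref <- dct[a$sample_type == refType]
    .assertThat(length(wt) >= 1L && length(ref) >= 1L,
                "assay %s lacks WT or %s replicates", a$assay_id[1L],
                refType)
    ddct <- mean(wt) - mean(ref)
    data.frame(assay_id = a$assay_id[1L],
               ref_type = refType,
               delta_ct_wt = mean(wt),
               delta_ct_ref = mean(ref),
               sd_wt = if (length(wt) > 1L) stats::sd(wt) else NA_real_,
               sd_ref = if (length(ref) > 1L) stats::sd(ref) else NA_real_,
               ddct = ddct,
               classified_modified = ddct <= -1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$assay_id), , drop = FALSE]
}
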