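# Signal-region merging, biotype annotation, biotype proportions and
# metagene positions.

.regionBiotypes <- c("tRNA", "rRNA", "CDS", "UTR5", "UTR3", "ncRNA",
                     "intergenic")

#' Merge called positions into signal regions
#'
#' A signal region is a maximal run of adjacent called positions on one
#' molecule: because a single modification perturbs basecalling up to about
#' 10 nt around it, adjacent called nucleotides are treated as one signal
#' harbouring one or more modifications.
#'
#' @param called data.frame of called positions with columns
#'   \code{molecule_id} and \code{position}; an \code{esb_test} column, if
#'   present, is averaged per region.
#' @return A \code{GRanges} (seqnames = molecule, 1-based inclusive) with
#'   metadata columns \code{n_sites} and, when available,
#'   \code{mean_esb_test}; ordered by molecule then start.
#' @export
#' @examples
#' mergeRegions(data.frame(molecule_id = "m1", position = c(10, 11, 12, 20)))
mergeRegions <- function(called) {
  if (is.null(called) || nrow(called) == 0L) {
    gr <- GRanges()
    mcols(gr)$n_sites <- integer(0)
    return(gr)
  }
  df <- .orderSites(called)
  newRun <- c(TRUE, df$molecule_id[-1L] != df$molecule_id[-nrow(df)] |
                diff(df$position) != 1L)
  runId <- cumsum(newRun)
  starts <- df$position[newRun]
  ends <- df$position[c(newRun[-1L], TRUE)]
  gr <- GRanges(df$molecule_id[newRun], IRanges(starts, ends))
  mcols(gr)$n_sites <- as.integer(width(gr))
  if (!is.null(df$esb_test)) {
    mcols(gr)$mean_esb_test <-
      as.numeric(tapply(df$esb_test, runId, mean))
  }
  gr
}

# internal: biotype of a single (molecule, position) given gene models,
# by fixed precedence tRNA > rRNA > CDS > UTR5 > UTR3 > ncRNA > intergenic
.biotypeAt <- function(molecule, pos, models) {
  m <- models[models$molecule_id == molecule, , drop = FALSE]
  labels <- character(0)
  for (i in seq_len(nrow(m))) {
    if (pos < m$gene_start[i] || pos > m$gene_end[i]) next
    bt <- m$biotype[i]
    if (bt %in% c("tRNA", "rRNA")) {
      labels <- c(labels, bt)
    } else if (bt == "mRNA") {
      inside <- function(s, e) !is.na(s) && pos >= s && pos <= e
      if (inside(m$cds_start[i], m$cds_end[i])) labels <- c(labels, "CDS")
      else if (inside(m$utr5_start[i], m$utr5_end[i])) labels <- c(labels, "UTR5")
      else if (inside(m$utr3_start[i], m$utr3_end[i])) labels <- c(labels, "UTR3")
    } else {
      # ncRNA, tmRNA, pseudogene all count as noncoding RNA features
      labels <- c(labels, "ncRNA")
    }
  }
  if (!length(labels)) return("intergenic")
  .regionBiotypes[min(match(labels, .regionBiotypes))]
}

#' Annotate signal regions with an RNA biotype
#'
#' Assigns each region the biotype of its midpoint, with precedence
#' tRNA > rRNA > CDS > 5'UTR > 3'UTR > ncRNA > intergenic when features
#' overlap. Regions overlapping no feature are intergenic.
#'
#' @param regions a \code{GRanges} from \code{\link{mergeRegions}}.
#' @param models gene models from \code{\link{readGeneModels}}.
#' @return \code{regions} with a \code{biotype} metadata column.
#' @export
annotateRegions <- function(regions, models) {
  if (length(regions) == 0L) {
    mcols(regions)$biotype <- character(0)
    return(regions)
  }
  mid <- floor((start(regions) + end(regions)) / 2)
  mol <- as.character(seqnames(regions))
  mcols(regions)$biotype <- vapply(seq_along(regions), function(i) {
    .biotypeAt(mol[i], mid[i], models)
  }, "")
  regions
}

#' Biotype proportions of signal regions
#'
#' Counts regions per biotype and reports each as a percentage of the total
#' over the included biotypes (rounded half-up to one decimal). tRNA and
#' rRNA are excluded by default, mirroring the convention of reporting
#' putative novel sites outside the heavily modified stable RNAs.
#'
#' @param regions an annotated \code{GRanges} (with a \code{biotype}
#'   metadata column), or a named integer vector of region counts per
#'   biotype.
#' @param include biotypes to include in the total.
#' @return A data.frame with columns \code{biotype}, \code{count},
#'   \code{fraction}, \code{percent}, ordered by decreasing count.
#' @export
#' @examples
#' biotypeProportions(c(CDS = 283, UTR5 = 56, intergenic = 24, UTR3 = 14,
#'                      ncRNA = 10))
biotypeProportions <- function(regions,
                               include = setdiff(.regionBiotypes,
                                                 c("tRNA", "rRNA"))) {
  .assertThat(length(include) > 0L, "include must be nonempty")
  if (is(regions, "GRanges")) {
    counts <- table(factor(mcols(regions)$biotype, levels = include))
  } else {
    .assertThat(!is.null(names(regions)),
                "counts must be named by biotype")
    counts <- regions[names(regions) %in% include]
  }
  total <- sum(counts)
  .assertThat(total > 0, "no regions in the included biotypes")
  out <- data.frame(biotype = names(counts),
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / total,
                    row.names = NULL)
  out$percent <- roundHalfUp(100 * out$fraction)
  out[order(-out$count, out$biotype), , drop = FALSE]
}

#' Metagene positions of mRNA signal regions
#'
#' Maps each region falling in a 5'UTR, CDS or 3'UTR to a normalized
#' transcript coordinate on the [0, 3) scale: 5'UTR occupies [0, 1), CDS
#' [1, 2) and 3'UTR [2, 3). Within a segment the position is the region
#' midpoint's offset from the segment's 5' end divided by the segment
#' length; minus-strand segments are traversed 3'<-5' so that 0 is always
#' the transcript 5' end.
#'
#' @param regions a \code{GRanges} of signal regions (pass width-1 regions
#'   for per-nucleotide points).
#' @param models gene models from \code{\link{readGeneModels}}.
#' @return A data.frame with columns \code{molecule_id}, \code{start},
#'   \code{end}, \code{segment} and \code{normalized_pos}; regions outside
#'   UTR5/CDS/UTR3 are dropped.
#' @export
metagenePositions <- function(regions, models) {
  if (length(regions) == 0L) {
    return(data.frame(molecule_id = character(), start = integer(),
                      end = integer(), segment = character(),
                      normalized_pos = numeric()))
  }
  mid <- floor((start(regions) + end(regions)) / 2)
  mol <- as.character(seqnames(regions))
  band <- c(UTR5 = 0, CDS = 1, UTR3 = 2)
  rows <- lapply(seq_along(regions), function(i) {
    seg <- .biotypeAt(mol[i], mid[i], models)
    if (!seg %in% names(band)) return(NULL)
    m <- models[models$molecule_id == mol[i] & models$biotype == "mRNA", ,
                drop = FALSE][1L, ]
    bounds <- switch(seg,
      UTR5 = c(m$utr5_start, m$utr5_end),
      CDS = c(m$cds_start, m$cds_end),
      UTR3 = c(m$utr3_start, m$utr3_end))
    segLen <- bounds[2L] - bounds[1L] + 1
    .assertThat(segLen > 0, "zero-length %s segment on %s", seg, mol[i])
    frac <- if (m$strand == "+") {
      (mid[i] - bounds[1L]) / segLen
    } else {
      (bounds[2L] - mid[i]) / segLen
    }
    data.frame(molecule_id = mol[i], start = start(regions)[i],
               end = end(regions)[i], segment = seg,
               normalized_pos = band[[seg]] + frac)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(molecule_id = character(), start = integer(),
                      end = integer(), segment = character(),
                      normalized_pos = numeric()))
  }
  rownames(out) <- NULL
  out
}
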