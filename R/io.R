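# Readers and writers for the delimited formats the pipeline touches.
#
# Internal conventions: positions are 1-based inclusive on the molecule
# (matching catalogue coordinates); ESB values are fractions in [0, 1].
# Dialects declare the column layout and ESB scale of the incoming table,
# so percent-scaled caller output is converted on read.

.siteColumns <- c("molecule_id", "position", "ref_base", "esb_test",
                  "esb_control", "odds_ratio", "p_adj", "depth")

.siteDialects <- list(
  native = list(
    cols = setNames(.siteColumns, .siteColumns),
    esb_scale = "fraction"),
  percent = list(
    cols = setNames(.siteColumns, .siteColumns),
    esb_scale = "percent"),
  # best-effort mapping of error-based caller output columns
  eligos = list(
    cols = c(molecule_id = "chrom", position = "start_loc", ref_base = "ref",
             esb_test = "ESB_test", esb_control = "ESB_ctrl",
             odds_ratio = "oddR", p_adj = "adjPval", depth = "total_reads"),
    esb_scale = "fraction")
)

#' Available site-table dialects
#'
#' @return Character vector of dialect names accepted by
#'   \code{\link{readSiteTable}}.
#' @export
siteDialects <- function() names(.siteDialects)

# internal: validate a normalized site table; `where` names the source in
# error messages. Returns the table ordered by (molecule, position).
.validateSiteTable <- function(df, where = "site table") {
  missing <- setdiff(.siteColumns, names(df))
  .assertThat(length(missing) == 0L, "%s: missing columns: %s", where,
              paste(missing, collapse = ", "))
  df$molecule_id <- as.character(df$molecule_id)
  df$ref_base <- toupper(as.character(df$ref_base))
  df$ref_base[df$ref_base == "T"] <- "U"
  num <- c("position", "esb_test", "esb_control", "odds_ratio", "p_adj",
           "depth")
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])

  bad <- which(is.na(df$molecule_id) | df$molecule_id == "" |
               Reduce(`|`, lapply(df[num], is.na)))
  .assertThat(length(bad) == 0L,
              "%s: missing mandatory fields in row(s) %s", where,
              paste(utils::head(bad, 5L), collapse = ", "))

  checkRows <- function(ok, what) {
    bad <- which(!ok)
    .assertThat(length(bad) == 0L, "%s: %s in row(s) %s", where, what,
                paste(utils::head(bad, 5L), collapse = ", "))
  }
  checkRows(df$position >= 1 & df$position == round(df$position),
            "position must be a positive integer")
  checkRows(df$ref_base %in% c("A", "C", "G", "U"),
            "ref_base must be one of A/C/G/U")
  checkRows(df$esb_test >= 0 & df$esb_test <= 1, "esb_test outside [0, 1]")
  checkRows(df$esb_control >= 0 & df$esb_control <= 1,
            "esb_control outside [0, 1]")
  checkRows(df$odds_ratio >= 0, "negative odds_ratio")
  checkRows(df$p_adj >= 0 & df$p_adj <= 1, "p_adj outside [0, 1]")
  checkRows(df$depth >= 0 & df$depth == round(df$depth),
            "depth must be a nonnegative integer")

  key <- .posKey(df$molecule_id, df$position)
  dup <- which(duplicated(key))
  .assertThat(length(dup) == 0L,
              "%s: duplicate (molecule, position) in row(s) %s", where,
              paste(utils::head(dup, 5L), collapse = ", "))
  df <- .orderSites(df[, .siteColumns])
  rownames(df) <- NULL
  df$position <- as.integer(df$position)
  df$depth <- as.integer(df$depth)
  df
}

#' Read a per-site table from an error-based modification caller
#'
#' Reads a tab-separated table of per-position error statistics (ESB in the
#' native sample and in the unmodified control, odds ratio, adjusted
#' p-value, read depth), normalizes it to the internal representation
#' (1-based positions, fraction-scale ESB) and validates every row.
#'
#' @param path path to a tab-separated file with a header line.
#' @param dialect column-layout dialect; one of \code{\link{siteDialects}()}.
#'   The \code{"percent"} dialect divides ESB columns by 100 on read.
#' @return A validated data.frame with columns \code{molecule_id},
#'   \code{position}, \code{ref_base}, \code{esb_test}, \code{esb_control},
#'   \code{odds_ratio}, \code{p_adj}, \code{depth}, ordered by molecule and
#'   position.
#' @seealso \code{\link{writeSiteTable}}
#' @export
readSiteTable <- function(path, dialect = "native") {
  .assertThat(file.exists(path), "file not found: %s", path)
  .assertThat(dialect %in% names(.siteDialects), "unknown dialect: %s",
              dialect)
  d <- .siteDialects[[dialect]]
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(d$cols), names(raw))
  .assertThat(length(missing) == 0L,
              "%s: dialect '%s' expects columns: %s", path, dialect,
              paste(missing, collapse = ", "))
  df <- raw[unname(d$cols)]
  names(df) <- names(d$cols)
  if (d$esb_scale == "percent") {
    df$esb_test <- as.numeric(df$esb_test) / 100
    df$esb_control <- as.numeric(df$esb_control) / 100
  }
  .validateSiteTable(df, where = path)
}

#' Write a per-site table
#'
#' Writes the native tab-separated representation (fraction-scale ESB,
#' header line, rows ordered by molecule then position).
#'
#' @param sites a validated site table.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeSiteTable <- function(sites, path) {
  sites <- .validateSiteTable(sites)
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-modification catalogue
#'
#' Reads a tab-separated catalogue of known modification sites (molecule,
#' 1-based position, modification symbol in the MODOMICS single-character
#' convention or a short name) and populates the \code{detectable} flag from
#' the built-in type catalogue. Unknown symbols are kept with
#' \code{detectable = NA} and a warning.
#'
#' @param path path to a tab-separated file with columns
#'   \code{molecule_id}, \code{position}, \code{mod_symbol}.
#' @param catalog detectability catalogue, as from
#'   \code{\link{modTypeCatalog}}; may be overridden.
#' @return A data.frame with columns \code{molecule_id}, \code{position},
#'   \code{mod_symbol}, \code{detectable}.
#' @export
readKnownSites <- function(path, catalog = modTypeCatalog()) {
  .assertThat(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(molecule_id = "character",
                                  mod_symbol = "character"))
  if (nrow(df) == 0L) {
    warning("empty known-site catalogue: ", path)
    return(data.frame(molecule_id = character(), position = integer(),
                      mod_symbol = character(), detectable = logical()))
  }
  missing <- setdiff(c("molecule_id", "position", "mod_symbol"), names(df))
  .assertThat(length(missing) == 0L, "%s: missing columns: %s", path,
              paste(missing, collapse = ", "))
  .assertThat(all(df$position >= 1), "%s: positions must be >= 1", path)
  .assertThat(all(nzchar(df$mod_symbol)), "%s: empty mod_symbol", path)
  df$position <- as.integer(df$position)
  df$detectable <- .lookupDetectable(df$mod_symbol, catalog)
  if (anyNA(df$detectable)) {
    warning("unknown modification symbol(s): ",
            paste(unique(df$mod_symbol[is.na(df$detectable)]), collapse = ", "),
            "; detectability flagged unknown")
  }
  out <- .orderSites(df[, c("molecule_id", "position", "mod_symbol",
                            "detectable")])
  rownames(out) <- NULL
  out
}

#' Write a known-modification catalogue
#'
#' @param known data.frame as returned by \code{\link{readKnownSites}}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeKnownSites <- function(known, path) {
  known <- .orderSites(known)
  write.table(known[, c("molecule_id", "position", "mod_symbol")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 plus a UTR BED file
#'
#' Parses gene and CDS features from a GFF3 file and UTR intervals from a
#' BED file (0-based half-open; converted to the internal 1-based inclusive
#' convention). BED names must be \code{"<gene_id>|utr5"} or
#' \code{"<gene_id>|utr3"}; UTRs referencing unknown genes are skipped with
#' a warning.
#'
#' @param gffPath GFF3 file with \code{gene} features (attributes \code{ID}
#'   and \code{biotype}) and \code{CDS} features (\code{Parent} = gene ID).
#' @param utrBedPath BED file of UTR intervals, or \code{NULL} for none.
#' @return A data.frame with one row per gene: \code{gene_id},
#'   \code{molecule_id}, \code{strand}, \code{biotype}, \code{gene_start},
#'   \code{gene_end}, \code{cds_start}, \code{cds_end}, \code{utr5_start},
#'   \code{utr5_end}, \code{utr3_start}, \code{utr3_end} (NA where absent).
#' @export
readGeneModels <- function(gffPath, utrBedPath = NULL) {
  .assertThat(file.exists(gffPath), "file not found: %s", gffPath)
  gr <- rtracklayer::import(gffPath, format = "gff3")
  md <- mcols(gr)
  genes <- gr[md$type == "gene"]
  .assertThat(length(genes) > 0L, "%s: no gene features", gffPath)
  gm <- data.frame(
    gene_id = as.character(mcols(genes)$ID),
    molecule_id = as.character(seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    biotype = as.character(mcols(genes)$biotype),
    gene_start = start(genes), gene_end = end(genes),
    cds_start = NA_integer_, cds_end = NA_integer_,
    utr5_start = NA_integer_, utr5_end = NA_integer_,
    utr3_start = NA_integer_, utr3_end = NA_integer_,
    stringsAsFactors = FALSE)
  .assertThat(!anyNA(gm$gene_id), "%s: gene feature without ID", gffPath)
  .assertThat(all(gm$strand %in% c("+", "-")),
              "%s: gene strand must be + or -", gffPath)

  cds <- gr[md$type == "CDS"]
  if (length(cds)) {
    parent <- as.character(unlist(mcols(cds)$Parent))
    .assertThat(length(parent) == length(cds),
                "%s: CDS feature without a single Parent", gffPath)
    i <- match(parent, gm$gene_id)
    .assertThat(!anyNA(i), "%s: CDS with unknown Parent gene", gffPath)
    gm$cds_start[i] <- start(cds)
    gm$cds_end[i] <- end(cds)
  }

  if (!is.null(utrBedPath)) {
    .assertThat(file.exists(utrBedPath), "file not found: %s", utrBedPath)
    utr <- rtracklayer::import(utrBedPath, format = "bed")
    nm <- strsplit(as.character(mcols(utr)$name), "|", fixed = TRUE)
    .assertThat(all(lengths(nm) == 2L),
                "%s: BED names must be '<gene_id>|utr5' or '<gene_id>|utr3'",
                utrBedPath)
    gid <- vapply(nm, `[`, "", 1L)
    side <- vapply(nm, `[`, "", 2L)
    .assertThat(all(side %in% c("utr5", "utr3")),
                "%s: UTR side must be utr5 or utr3", utrBedPath)
    i <- match(gid, gm$gene_id)
    if (anyNA(i)) {
      warning("UTR interval(s) referencing unknown gene(s) skipped: ",
              paste(unique(gid[is.na(i)]), collapse = ", "))
    }
    keep <- which(!is.na(i))
    for (k in keep) {
      gm[i[k], paste0(side[k], "_start")] <- start(utr)[k]
      gm[i[k], paste0(side[k], "_end")] <- end(utr)[k]
    }
  }

  ok <- is.na(gm$cds_start) | gm$cds_start <= gm$cds_end
  .assertThat(ok, "CDS start > end for gene(s): %s",
              paste(gm$gene_id[!ok], collapse = ", "))
  for (side in c("utr5", "utr3")) {
    s <- gm[[paste0(side, "_start")]]
    e <- gm[[paste0(side, "_end")]]
    ok <- is.na(s) | s <= e
    .assertThat(ok, "%s start > end for gene(s): %s", side,
                paste(gm$gene_id[!ok], collapse = ", "))
    overl <- !is.na(s) & !is.na(gm$cds_start) &
      s <= gm$cds_end & e >= gm$cds_start
    .assertThat(!overl, "%s overlaps CDS for gene(s): %s", side,
                paste(gm$gene_id[overl], collapse = ", "))
  }
  gm[order(gm$molecule_id, gm$gene_start), , drop = FALSE]
}

#' Read MS and SELECT CT assay tables
#'
#' @param msPath tab-separated MS table with columns \code{mod_name},
#'   \code{condition}, \code{replicate}, \code{abundance} (modified
#'   nucleosides per 1000 canonical nucleosides).
#' @param ctPath tab-separated CT table with columns \code{assay_id},
#'   \code{sample_type} (WT/IVT/Mut), \code{replicate}, \code{ct_target},
#'   \code{ct_control_a}.
#' @return A list with validated elements \code{ms} and \code{ct}; either
#'   may be \code{NULL} when the corresponding path is.
#' @export
readAssayTables <- function(msPath = NULL, ctPath = NULL) {
  ms <- ct <- NULL
  if (!is.null(msPath)) {
    .assertThat(file.exists(msPath), "file not found: %s", msPath)
    ms <- read.delim(msPath, stringsAsFactors = FALSE)
    missing <- setdiff(c("mod_name", "condition", "replicate", "abundance"),
                       names(ms))
    .assertThat(length(missing) == 0L, "%s: missing columns: %s", msPath,
                paste(missing, collapse = ", "))
    .assertThat(all(is.finite(ms$abundance) & ms$abundance >= 0),
                "%s: abundance must be nonnegative", msPath)
  }
  if (!is.null(ctPath)) {
    .assertThat(file.exists(ctPath), "file not found: %s", ctPath)
    ct <- read.delim(ctPath, stringsAsFactors = FALSE)
    missing <- setdiff(c("assay_id", "sample_type", "replicate", "ct_target",
                         "ct_control_a"), names(ct))
    .assertThat(length(missing) == 0L, "%s: missing columns: %s", ctPath,
                paste(missing, collapse = ", "))
    .assertThat(all(ct$sample_type %in% c("WT", "IVT", "Mut")),
                "%s: sample_type must be WT, IVT or Mut", ctPath)
    .assertThat(all(is.finite(ct$ct_target) & is.finite(ct$ct_control_a)),
                "%s: CT values must be finite", ctPath)
  }
  list(ms = ms, ct = ct)
}

#' Export signal regions as BED6
#'
#' Writes regions in BED6 (0-based half-open) with the biotype as the name
#' field and the number of called sites as the score.
#'
#' @param regions a \code{GRanges} of signal regions, as from
#'   \code{\link{mergeRegions}} / \code{\link{annotateRegions}}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeRegionsBed <- function(regions, path) {
  gr <- regions
  nm <- if (!is.null(mcols(gr)$biotype)) mcols(gr)$biotype else "region"
  mcols(gr) <- NULL
  mcols(gr)$name <- nm
  mcols(gr)$score <- mcols(regions)$n_sites
  rtracklayer::export(sort(gr), path, format = "bed")
  invisible(path)
}
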