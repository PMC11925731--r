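# End-to-end orchestration: simulate (optional) -> calibrate thresholds ->
# call -> merge/annotate regions -> differential -> SELECT, with every
# intermediate table written out and a machine-readable summary.

#' Run the full analysis pipeline
#'
#' Executes the stages end to end on supplied inputs or on a synthetic
#' experiment: threshold calibration (grid search against the known-site
#' catalogue) or direct thresholding, region merging and biotype/metagene
#' annotation, two-condition delta-ESB analysis with MS cross-validation,
#' and SELECT classification. Writes every intermediate table plus a
#' \code{summary.json} and a run log into \code{outDir}. Exactly one of
#' \code{thresholds} and \code{grid} must be supplied.
#'
#' @param outDir output directory (created if needed).
#' @param experiment inputs as returned by \code{\link{simulateExperiment}}
#'   (or an equivalently shaped list of user data); if \code{NULL}, a
#'   synthetic experiment is generated from \code{config}.
#' @param config a \code{\link{simConfig}} used when \code{experiment} is
#'   NULL; its seed governs all randomness.
#' @param thresholds a \code{\link{ThresholdSet}} to apply directly, or
#'   NULL to calibrate via \code{grid}.
#' @param grid a \code{\link{GridSpec}} for calibration, or NULL.
#' @param minDepth,tolerance,precisionFloor stage parameters (defaults 20,
#'   10, 0.85).
#' @return Invisibly, the summary list (also serialized to
#'   \code{summary.json}).
#' @export
runPipeline <- function(outDir, experiment = NULL, config = simConfig(),
                        thresholds = NULL, grid = NULL, minDepth = 20,
                        tolerance = 10, precisionFloor = 0.85) {
  .assertThat(xor(is.null(thresholds), is.null(grid)),
              "supply exactly one of thresholds and grid")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) {
    cat(paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ..., "\n"),
        file = logFile, append = TRUE)
  }
  stage <- function(name, expr) {
    logLine("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cat("", file = logFile)
  logLine("modcal ", as.character(utils::packageVersion("modcal")),
          ", R ", as.character(getRversion()))

  if (is.null(experiment)) {
    logLine("seed: ", config$seed)
    experiment <- stage("simulate", simulateExperiment(config, dir = outDir))
  }
  exp <- experiment
  summary <- list()

  cal <- stage("threshold", {
    if (!is.null(grid)) {
      gs <- gridSearch(exp$sites_a, exp$knownSites, grid,
                       precisionFloor = precisionFloor,
                       tolerance = tolerance)
      .assertThat(!is.null(gs$best),
                  "grid search found no combination at the precision floor")
      write.table(gs$landscape, file.path(outDir, "pr_landscape.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      gs
    } else {
      pr <- precisionRecall(applyThresholds(exp$sites_a, thresholds),
                            exp$knownSites, tolerance = tolerance)
      list(best = thresholds, bestPoint = pr, landscape = NULL)
    }
  })
  summary$thresholds <- list(esb_test_min = esbTestMin(cal$best),
                             esb_control_max = esbControlMax(cal$best),
                             oddr_min = oddrMin(cal$best),
                             padj_max = padjMax(cal$best))
  summary$precision <- cal$bestPoint$precision
  summary$recall <- cal$bestPoint$recall

  calledA <- stage("call", applyThresholds(exp$sites_a, cal$best))
  calledB <- stage("call", applyThresholds(exp$sites_b, cal$best))
  writeSiteTable(calledA, file.path(outDir, "called_a.tsv"))
  writeSiteTable(calledB, file.path(outDir, "called_b.tsv"))

  regions <- stage("annotate", {
    .assertThat(!is.null(exp$models), "no gene models for annotate stage")
    annotateRegions(mergeRegions(calledA), exp$models)
  })
  writeRegionsBed(regions, file.path(outDir, "regions_a.bed"))
  outside <- regions[!mcols(regions)$biotype %in% c("tRNA", "rRNA")]
  props <- biotypeProportions(regions)
  meta <- metagenePositions(regions, exp$models)
  write.table(props, file.path(outDir, "biotype_proportions_a.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, file.path(outDir, "metagene_a.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary$n_regions <- length(regions)
  summary$n_regions_outside_trna_rrna <- length(outside)
  summary$biotype_percent <- setNames(as.list(props$percent), props$biotype)

  outcomes <- stage("benchmark", classifyKnownSites(
    calledA, exp$knownSites, exp$depth_a, minDepth = minDepth))
  det <- detectionSummary(outcomes)
  write.table(outcomes, file.path(outDir, "detection_outcomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$recall_overall_percent <-
    det$recall$percent[det$recall$denominator == "overall"]

  diffRes <- stage("diff", {
    delta <- computeDeltaEsb(exp$sites_a, exp$sites_b, calledA, calledB)
    cmp <- compareConditions(calledA, calledB, exp$depth_a, exp$depth_b,
                             minDepth = minDepth, delta = delta)
    write.table(delta, file.path(outDir, "delta_esb.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cmp$status, file.path(outDir, "shared_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(delta = delta, cmp = cmp)
  })
  summary$shared <- diffRes$cmp$summary

  if (!is.null(exp$ms) && !is.null(exp$truth)) {
    summary$ms_correlation <- stage("ms", {
      # stoichiometry comparison at catalogued sites: detection here means
      # coverage in the dataset, not passing the strict calling cutoffs
      detA <- detectedSites(exp$sites_a, exp$knownSites, minDepth)
      detB <- detectedSites(exp$sites_b, exp$knownSites, minDepth)
      delta <- computeDeltaEsb(exp$sites_a, exp$sites_b, detA, detB)
      planted <- exp$truth$planted
      i <- match(.posKey(delta$molecule_id, delta$position),
                 .posKey(planted$molecule_id, planted$position))
      delta$mod_type <- planted$mod_name[i]
      keep <- !is.na(delta$mod_type) & planted$detectable[i]
      mc <- msCorrelation(delta[keep, , drop = FALSE], exp$ms, "a", "b")
      write.table(mc$pairs, file.path(outDir, "ms_pairs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(rho = mc$rho, p = mc$p)
    })
  }

  if (!is.null(exp$ct)) {
    sel <- stage("select", selectClassify(exp$ct, "IVT"))
    write.table(sel, file.path(outDir, "select_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$select <- list(n_assays = nrow(sel),
                           n_modified = sum(sel$classified_modified))
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logLine("done")
  invisible(summary)
}
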