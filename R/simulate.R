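# Ground-truthed synthetic data with the statistical structure the analysis
# assumes: elevated ESB at planted modification sites with a geometric
# neighbor smear decaying within +/- 10 nt, a sparse systemic-noise spike
# family in the background, log-normal per-molecule depth including
# molecules below the 20-read floor, two-condition stoichiometry shifts
# mirrored in an MS table, and CT delays at modified SELECT targets.

#' Configuration for the synthetic-data generator
#'
#' Defaults are sized to desk scale (80 molecules, ~250 planted sites,
#' generation well under 30 s) while retaining the features the pipeline
#' exploits: planted ESB elevations proportional to stoichiometry, a
#' +/- 10 nt geometric smear, background spikes that sub-0.1 ESB cutoffs
#' would admit as false signal, depth heterogeneity with roughly 14\% of
#' molecules below 20 reads, condition-b stoichiometry multipliers per
#' modification type, 5\% multiplicative MS noise, and a 2.5-cycle CT delay
#' at modified SELECT targets.
#'
#' @param seed integer seed; every simulate* stage derives its RNG state
#'   from it.
#' @param nMolecules named integer vector: molecules per biotype.
#' @param plantedMean named numeric vector: planted sites per molecule
#'   (exact for tRNA/rRNA, Poisson mean for mRNA/ncRNA).
#' @param esbEffect ESB elevation at a fully stoichiometric modified site.
#' @param backgroundEsbShape Beta shape parameters of background ESB.
#' @param spikeRate per-position probability of a systemic noise spike.
#' @param spikeEsbRange uniform range of spike ESB (below the 0.1 cutoff).
#' @param smearWidth,smearDecay neighbor smear half-width (nt) and per-nt
#'   multiplicative decay.
#' @param depthMeanlog,depthSdlog named per-biotype log-normal parameters
#'   of molecule abundance (shared between conditions, as transcript
#'   abundance is). Defaults emulate deep, stable rRNA coverage, moderate
#'   tRNA coverage, and heterogeneous mRNA/ncRNA coverage with roughly
#'   15\% of molecules below the 20-read detection floor.
#' @param depthCondSdlog log-sd of the condition-specific depth jitter
#'   around the shared abundance.
#' @param pKappa steepness of the deterministic monotone p-value transform.
#' @param oddsFloor floor on control ESB in the odds-ratio denominator.
#' @param stoichRange uniform range of planted site stoichiometry.
#' @param conditionBMultipliers named stoichiometry multipliers (by
#'   modification name) applied in condition b; unlisted types keep 1.
#' @param msScale MS abundance per 1000 canonical nucleosides per unit
#'   stoichiometry.
#' @param msNoiseSd,msReplicates multiplicative MS noise sd and replicates.
#' @param ctEffect,ctNoiseSd,ctReplicates magnitude of the delta-delta-CT
#'   displacement at modified SELECT targets (the assay yields
#'   ddCT = -ctEffect), per-well CT noise sd, replicates per sample type.
#' @param nSelectModified,nSelectUnmodified SELECT assays at modified /
#'   unmodified positions.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nMolecules = c(tRNA = 30, rRNA = 2, mRNA = 40,
                                     ncRNA = 8),
                      plantedMean = c(tRNA = 6, rRNA = 15, mRNA = 1.2,
                                      ncRNA = 0.5),
                      esbEffect = 0.45,
                      backgroundEsbShape = c(1, 199),
                      spikeRate = 0.004,
                      spikeEsbRange = c(0.05, 0.095),
                      smearWidth = 10, smearDecay = 0.5,
                      depthMeanlog = c(tRNA = log(80), rRNA = log(2000),
                                       mRNA = log(60), ncRNA = log(60)),
                      depthSdlog = c(tRNA = 1, rRNA = 0.5, mRNA = 1,
                                     ncRNA = 1),
                      depthCondSdlog = 0.25,
                      pKappa = 3, oddsFloor = 1e-3,
                      stoichRange = c(0.3, 0.95),
                      conditionBMultipliers = c(Y = 0.7, m66A = 1.5,
                                                m6A = 1.3, m5C = 1.25,
                                                Cm = 0.9, Um = 0.76,
                                                Gm = 1.1),
                      msScale = 3, msNoiseSd = 0.05, msReplicates = 3,
                      ctEffect = 2.5, ctNoiseSd = 0.05, ctReplicates = 2,
                      nSelectModified = 6, nSelectUnmodified = 4) {
  cfg <- list(seed = as.integer(seed), nMolecules = nMolecules,
              plantedMean = plantedMean, esbEffect = esbEffect,
              backgroundEsbShape = backgroundEsbShape,
              spikeRate = spikeRate, spikeEsbRange = spikeEsbRange,
              smearWidth = smearWidth, smearDecay = smearDecay,
              depthMeanlog = depthMeanlog, depthSdlog = depthSdlog,
              depthCondSdlog = depthCondSdlog,
              pKappa = pKappa, oddsFloor = oddsFloor,
              stoichRange = stoichRange,
              conditionBMultipliers = conditionBMultipliers,
              msScale = msScale, msNoiseSd = msNoiseSd,
              msReplicates = msReplicates, ctEffect = ctEffect,
              ctNoiseSd = ctNoiseSd, ctReplicates = ctReplicates,
              nSelectModified = nSelectModified,
              nSelectUnmodified = nSelectUnmodified)
  .assertThat(cfg$smearWidth >= 0, "smearWidth must be >= 0")
  .assertThat(cfg$spikeRate >= 0 && cfg$spikeRate <= 1,
              "spikeRate must be in [0, 1]")
  .assertThat(all(cfg$conditionBMultipliers > 0),
              "condition-b multipliers must be positive")
  .assertThat(all(cfg$stoichRange >= 0 & cfg$stoichRange <= 1),
              "stoichRange must lie in [0, 1]")
  .assertThat(cfg$esbEffect >= 0 && cfg$esbEffect <= 1,
              "esbEffect must be a fraction in [0, 1]")
  .assertThat(all(names(cfg$nMolecules) %in%
                    c("tRNA", "rRNA", "mRNA", "ncRNA")),
              "nMolecules must be named by biotype")
  structure(cfg, class = "SimConfig")
}

# flanking bases around each gene so intergenic positions exist
.simFlank <- 10L

# modification-type pools per biotype (names per modTypeCatalog; weights
# down-weight the non-detectable types)
.simTypePools <- list(
  tRNA = data.frame(
    name = c("D", "Y", "m5U", "m7G", "Gm", "Cm", "Um", "m1G", "t6A",
             "s4U", "m5C"),
    weight = c(1.5, 2, 1, 1, 1, 1, 1, 1, 1, 0.5, 0.5)),
  rRNA = data.frame(
    name = c("Y", "m6A", "m66A", "m2G", "m3U", "m5C", "m4Cm"),
    weight = c(2, 1.5, 1, 1, 1, 0.5, 0.5)),
  mRNA = data.frame(name = c("Y", "m6A"), weight = c(1, 1)),
  ncRNA = data.frame(name = c("Y", "m6A"), weight = c(1, 1)))

# base written under each modification name
.simRefBase <- function(modName) {
  c(D = "U", Y = "U", m5U = "U", m3U = "U", Um = "U", s4U = "U",
    m7G = "G", Gm = "G", m1G = "G", m2G = "G",
    Cm = "C", m5C = "C", m4Cm = "C",
    m6A = "A", m66A = "A", t6A = "A", acp3U = "U")[modName]
}

#' Simulate a toy annotation
#'
#' Generates one molecule per gene: mRNAs carry a 5'UTR/CDS/3'UTR layout on
#' a random strand (minus-strand genes have the 5'UTR on the right in
#' molecule coordinates), tRNA/rRNA/ncRNA genes are standalone transcripts;
#' every gene is padded by a 10-nt intergenic flank.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir if non-NULL, the annotation is also written to
#'   \code{genes.gff3} and \code{utrs.bed} under this directory.
#' @return A list with \code{models} (as from \code{\link{readGeneModels}})
#'   and \code{molecules} (molecule_id, biotype, length); plus \code{gff}
#'   and \code{bed} paths when written.
#' @export
simulateAnnotation <- function(config, dir = NULL) {
  set.seed(config$seed)
  fl <- .simFlank
  rows <- list()
  mk <- function(biotype, i, featLen, cds = NULL, utr5 = NULL, utr3 = NULL,
                 strand = "+") {
    id <- sprintf("%s_%03d", biotype, i)
    L <- featLen + 2L * fl
    data.frame(gene_id = paste0("gene_", id), molecule_id = id,
               strand = strand, biotype = biotype,
               gene_start = fl + 1L, gene_end = fl + featLen,
               cds_start = if (is.null(cds)) NA_integer_ else cds[1L],
               cds_end = if (is.null(cds)) NA_integer_ else cds[2L],
               utr5_start = if (is.null(utr5)) NA_integer_ else utr5[1L],
               utr5_end = if (is.null(utr5)) NA_integer_ else utr5[2L],
               utr3_start = if (is.null(utr3)) NA_integer_ else utr3[1L],
               utr3_end = if (is.null(utr3)) NA_integer_ else utr3[2L],
               length = L, stringsAsFactors = FALSE)
  }
  n <- config$nMolecules
  for (i in seq_len(n[["tRNA"]])) rows <- c(rows, list(mk("tRNA", i, 76L)))
  rLens <- rep(c(1542L, 2904L), length.out = n[["rRNA"]])
  for (i in seq_len(n[["rRNA"]])) rows <- c(rows, list(mk("rRNA", i, rLens[i])))
  for (i in seq_len(n[["mRNA"]])) {
    u5 <- sample(20:60, 1L)
    u3 <- sample(15:50, 1L)
    cdsLen <- sample(180:750, 1L)
    L <- u5 + cdsLen + u3
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      utr5 <- fl + c(1L, u5)
      cds <- fl + c(u5 + 1L, u5 + cdsLen)
      utr3 <- fl + c(u5 + cdsLen + 1L, L)
    } else {
      utr3 <- fl + c(1L, u3)
      cds <- fl + c(u3 + 1L, u3 + cdsLen)
      utr5 <- fl + c(u3 + cdsLen + 1L, L)
    }
    rows <- c(rows, list(mk("mRNA", i, L, cds, utr5, utr3, strand)))
  }
  for (i in seq_len(n[["ncRNA"]])) {
    rows <- c(rows, list(mk("ncRNA", i, sample(80:300, 1L))))
  }
  models <- do.call(rbind, rows)
  molecules <- models[, c("molecule_id", "biotype", "length")]
  models$length <- NULL
  out <- list(models = models, molecules = molecules)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$gff <- file.path(dir, "genes.gff3")
    out$bed <- file.path(dir, "utrs.bed")
    .writeAnnotation(models, molecules, out$gff, out$bed)
  }
  out
}

# internal: export gene models as GFF3 + UTR BED
.writeAnnotation <- function(models, molecules, gffPath, bedPath) {
  sl <- setNames(molecules$length, molecules$molecule_id)
  genes <- GRanges(models$molecule_id,
                   IRanges(models$gene_start, models$gene_end),
                   strand = models$strand, seqlengths = sl)
  mcols(genes)$type <- "gene"
  mcols(genes)$ID <- models$gene_id
  mcols(genes)$biotype <- models$biotype
  hasCds <- !is.na(models$cds_start)
  cds <- GRanges(models$molecule_id[hasCds],
                 IRanges(models$cds_start[hasCds], models$cds_end[hasCds]),
                 strand = models$strand[hasCds], seqlengths = sl)
  mcols(cds)$type <- "CDS"
  mcols(cds)$phase <- 0L
  mcols(cds)$Parent <- models$gene_id[hasCds]
  rtracklayer::export(c(genes, cds), gffPath, format = "gff3")

  utrRows <- list()
  for (side in c("utr5", "utr3")) {
    s <- models[[paste0(side, "_start")]]
    e <- models[[paste0(side, "_end")]]
    has <- !is.na(s)
    if (!any(has)) next
    gr <- GRanges(models$molecule_id[has], IRanges(s[has], e[has]),
                  strand = models$strand[has], seqlengths = sl)
    mcols(gr)$name <- paste0(models$gene_id[has], "|", side)
    utrRows <- c(utrRows, list(gr))
  }
  utr <- suppressWarnings(do.call(c, utrRows))
  rtracklayer::export(utr, bedPath, format = "bed")
  invisible(NULL)
}

#' Plant ground-truth modification sites
#'
#' Draws planted sites per molecule (modification type from a per-biotype
#' pool, stoichiometry uniform in \code{stoichRange}), applies the
#' condition-b stoichiometry multipliers, and records the threshold set
#' that separates planted signal from background by construction.
#'
#' @param config a \code{\link{simConfig}}.
#' @param annotation result of \code{\link{simulateAnnotation}}.
#' @return A list of class \code{GroundTruth}: \code{planted} (molecule,
#'   position, mod_name, mod_symbol, detectable, stoich_a, stoich_b),
#'   \code{trueThresholds} (a \code{\link{ThresholdSet}}), \code{models}
#'   and \code{molecules}.
#' @export
simulateGroundTruth <- function(config, annotation) {
  set.seed(config$seed + 3L)
  catalog <- modTypeCatalog()
  mols <- annotation$molecules
  planted <- list()
  for (i in seq_len(nrow(mols))) {
    bt <- mols$biotype[i]
    nSites <- if (bt %in% c("tRNA", "rRNA")) {
      as.integer(config$plantedMean[[bt]])
    } else {
      rpois(1L, config$plantedMean[[bt]])
    }
    span <- c(.simFlank + 1L, mols$length[i] - .simFlank)
    nSites <- min(nSites, span[2L] - span[1L] + 1L)
    if (nSites <= 0L) next
    pos <- sort(sample(span[1L]:span[2L], nSites))
    pool <- .simTypePools[[bt]]
    type <- sample(pool$name, nSites, replace = TRUE, prob = pool$weight)
    planted <- c(planted, list(data.frame(
      molecule_id = mols$molecule_id[i], position = pos, mod_name = type,
      stringsAsFactors = FALSE)))
  }
  planted <- do.call(rbind, planted)
  planted$mod_symbol <- catalog$symbol[match(planted$mod_name, catalog$name)]
  planted$detectable <- catalog$detectable[match(planted$mod_name,
                                                 catalog$name)]
  planted$stoich_a <- runif(nrow(planted), config$stoichRange[1L],
                            config$stoichRange[2L])
  mult <- config$conditionBMultipliers[planted$mod_name]
  mult[is.na(mult)] <- 1
  planted$stoich_b <- pmin(1, planted$stoich_a * unname(mult))
  molecules <- annotation$molecules
  # molecule abundance shared between conditions; per-condition depth is
  # this abundance with a small log-normal jitter
  molecules$abundance <- rlnorm(nrow(molecules),
                                config$depthMeanlog[molecules$biotype],
                                config$depthSdlog[molecules$biotype])
  list(planted = planted,
       trueThresholds = ThresholdSet(0.1, 0.01, 3, 0.05),
       models = annotation$models, molecules = molecules)
}

# internal: one condition's site table. stoichCol selects the per-site
# stoichiometry ("stoich_a"/"stoich_b"), or NULL for a background-only
# (IVT-like) table.
.simSites <- function(config, truth, stoichCol) {
  mols <- truth$molecules
  tables <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    L <- mols$length[i]
    id <- mols$molecule_id[i]
    esbControl <- rbeta(L, config$backgroundEsbShape[1L],
                        config$backgroundEsbShape[2L])
    esbTest <- rbeta(L, config$backgroundEsbShape[1L],
                     config$backgroundEsbShape[2L])
    spike <- runif(L) < config$spikeRate
    esbTest[spike] <- runif(sum(spike), config$spikeEsbRange[1L],
                            config$spikeEsbRange[2L])
    esbControl[spike] <- runif(sum(spike), 5e-4, 5e-3)
    base <- sample(c("A", "C", "G", "U"), L, replace = TRUE)

    if (!is.null(stoichCol)) {
      p <- truth$planted[truth$planted$molecule_id == id, , drop = FALSE]
      for (j in seq_len(nrow(p))) {
        amp <- config$esbEffect * p[[stoichCol]][j]
        if (!p$detectable[j]) amp <- 0  # no error signal for these types
        off <- -config$smearWidth:config$smearWidth
        at <- p$position[j] + off
        ok <- at >= 1L & at <= L
        esbTest[at[ok]] <- esbTest[at[ok]] +
          amp * config$smearDecay^abs(off[ok])
        base[p$position[j]] <- .simRefBase(p$mod_name[j])
      }
    }
    esbTest <- pmin(esbTest, 0.98)
    depth <- max(1L, round(mols$abundance[i] *
                             rlnorm(1L, 0, config$depthCondSdlog)))
    delta <- pmax(esbTest - esbControl, 0)
    padj <- 10^(-config$pKappa * delta * sqrt(min(depth, 400)))
    tables[[i]] <- data.frame(
      molecule_id = id, position = seq_len(L), ref_base = base,
      esb_test = esbTest, esb_control = esbControl,
      odds_ratio = esbTest / pmax(esbControl, config$oddsFloor),
      p_adj = padj, depth = depth, stringsAsFactors = FALSE)
  }
  .validateSiteTable(do.call(rbind, tables), where = "simulated site table")
}

#' Simulate per-site error tables for two conditions and an IVT-like
#' control
#'
#' Modified positions receive an ESB elevation of effect x stoichiometry;
#' neighbors within the smear width receive a geometrically decayed
#' elevation; the control table carries background (plus systemic spikes)
#' only. Read depth is drawn per molecule and condition; the odds ratio is
#' ESB test over floored ESB control, and the adjusted p-value is a
#' deterministic monotone transform of the ESB excess and depth.
#'
#' @param config a \code{\link{simConfig}}.
#' @param truth a \code{GroundTruth} from \code{\link{simulateGroundTruth}}.
#' @return A list with validated site tables \code{sites_a},
#'   \code{sites_b}, \code{sites_control}.
#' @export
simulateSiteTables <- function(config, truth) {
  set.seed(config$seed + 1L)
  list(sites_a = .simSites(config, truth, "stoich_a"),
       sites_b = .simSites(config, truth, "stoich_b"),
       sites_control = .simSites(config, truth, NULL))
}

#' Simulate MS and SELECT CT tables consistent with the planted truth
#'
#' MS abundance per modification type and condition is the mean planted
#' stoichiometry scaled to per-1000-nucleoside units with multiplicative
#' Gaussian noise. SELECT assays target a sample of planted (modifiable)
#' mRNA sites plus unmodified control positions; a modified target shifts
#' the WT delta-CT by \code{-ctEffect} cycles relative to the IVT
#' reference, so noise-free assays read ddCT = -ctEffect.
#'
#' @inheritParams simulateSiteTables
#' @return A list with \code{ms}, \code{ct} and \code{selectTargets}
#'   (assay_id, molecule_id, position, modified).
#' @export
simulateAssays <- function(config, truth) {
  set.seed(config$seed + 2L)
  p <- truth$planted
  msRows <- list()
  for (ty in sort(unique(p$mod_name))) {
    sa <- mean(p$stoich_a[p$mod_name == ty])
    sb <- mean(p$stoich_b[p$mod_name == ty])
    for (cond in c("a", "b")) {
      mu <- (if (cond == "a") sa else sb) * config$msScale
      ab <- pmax(0, mu * (1 + rnorm(config$msReplicates, 0,
                                    config$msNoiseSd)))
      msRows <- c(msRows, list(data.frame(
        mod_name = ty, condition = cond,
        replicate = seq_len(config$msReplicates), abundance = ab,
        stringsAsFactors = FALSE)))
    }
  }
  ms <- do.call(rbind, msRows)

  pm <- p[grepl("^mRNA", p$molecule_id) & p$detectable, , drop = FALSE]
  nMod <- min(config$nSelectModified, nrow(pm))
  modIdx <- if (nMod > 0L) sample(nrow(pm), nMod) else integer(0)
  targets <- data.frame(
    molecule_id = pm$molecule_id[modIdx], position = pm$position[modIdx],
    modified = rep(TRUE, nMod), stringsAsFactors = FALSE)
  mols <- truth$molecules[truth$molecules$biotype == "mRNA", , drop = FALSE]
  for (k in seq_len(config$nSelectUnmodified)) {
    repeat {
      i <- sample(nrow(mols), 1L)
      pos <- sample(seq(.simFlank + 1L, mols$length[i] - .simFlank), 1L)
      near <- p$molecule_id == mols$molecule_id[i] &
        abs(p$position - pos) <= config$smearWidth
      if (!any(near)) break
    }
    targets <- rbind(targets, data.frame(
      molecule_id = mols$molecule_id[i], position = pos, modified = FALSE,
      stringsAsFactors = FALSE))
  }
  targets$assay_id <- sprintf("%s_p%d", targets$molecule_id,
                              targets$position)

  ctRows <- list()
  for (k in seq_len(nrow(targets))) {
    baseCt <- runif(1L, 20, 26)
    for (st in c("WT", "IVT")) {
      nz <- function() rnorm(config$ctReplicates, 0, config$ctNoiseSd)
      # a modified target displaces the WT target-minus-control delta-CT
      # by -ctEffect relative to the unmodified reference, matching the
      # sign convention of the published assay (modified iff ddCT <= -1)
      shift <- if (st == "WT" && targets$modified[k]) -config$ctEffect else 0
      ctRows <- c(ctRows, list(data.frame(
        assay_id = targets$assay_id[k], sample_type = st,
        replicate = seq_len(config$ctReplicates),
        ct_target = baseCt + shift + nz(),
        ct_control_a = baseCt + nz(), stringsAsFactors = FALSE)))
    }
  }
  list(ms = ms, ct = do.call(rbind, ctRows),
       selectTargets = targets[, c("assay_id", "molecule_id", "position",
                                   "modified")])
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining \code{\link{simulateAnnotation}},
#' \code{\link{simulateGroundTruth}}, \code{\link{simulateSiteTables}} and
#' \code{\link{simulateAssays}} under the configured seed, and deriving the
#' known-site catalogue and per-molecule depth maps the downstream stages
#' consume.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir optional directory to write annotation files into.
#' @return A list with \code{config}, \code{models}, \code{molecules},
#'   \code{truth}, site tables (\code{sites_a}, \code{sites_b},
#'   \code{sites_control}), depth maps (\code{depth_a}, \code{depth_b}),
#'   the catalogue \code{knownSites}, and assay tables \code{ms},
#'   \code{ct}, \code{selectTargets}.
#' @export
simulateExperiment <- function(config = simConfig(), dir = NULL) {
  ann <- simulateAnnotation(config, dir = dir)
  truth <- simulateGroundTruth(config, ann)
  sites <- simulateSiteTables(config, truth)
  assays <- simulateAssays(config, truth)
  known <- truth$planted[, c("molecule_id", "position", "mod_symbol",
                             "detectable")]
  list(config = config, models = ann$models, molecules = ann$molecules,
       truth = truth,
       sites_a = sites$sites_a, sites_b = sites$sites_b,
       sites_control = sites$sites_control,
       depth_a = depthByMolecule(sites$sites_a),
       depth_b = depthByMolecule(sites$sites_b),
       knownSites = known,
       ms = assays$ms, ct = assays$ct,
       selectTargets = assays$selectTargets)
}

#' Per-molecule read depth from a site table
#'
#' @param sites a validated site table.
#' @return A named numeric vector: maximum reported depth per molecule.
#' @export
depthByMolecule <- function(sites) {
  tapply(sites$depth, sites$molecule_id, max)
}
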