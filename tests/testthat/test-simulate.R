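test_that("the generator is deterministic under a fixed seed", {
  cfg <- smallSimConfig(seed = 71)
  e1 <- simulateExperiment(cfg)
  e2 <- simulateExperiment(cfg)
  expect_identical(e1$sites_a, e2$sites_a)
  expect_identical(e1$sites_b, e2$sites_b)
  expect_identical(e1$ms, e2$ms)
  expect_identical(e1$ct, e2$ct)
  expect_identical(e1$truth$planted, e2$truth$planted)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  simulateAnnotation(cfg, dir = dir1)
  simulateAnnotation(cfg, dir = dir2)
  expect_identical(readLines(file.path(dir1, "genes.gff3")),
                   readLines(file.path(dir2, "genes.gff3")))
  expect_identical(readLines(file.path(dir1, "utrs.bed")),
                   readLines(file.path(dir2, "utrs.bed")))
})

test_that("emitted tables pass the readers' validation round-trip", {
  e <- simulateExperiment(smallSimConfig(seed = 72))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSiteTable(e$sites_a, path)
  back <- readSiteTable(path)
  expect_equal(nrow(back), nrow(e$sites_a))
  writeKnownSites(e$knownSites, path)
  expect_silent(back <- readKnownSites(path))
  expect_equal(nrow(back), nrow(e$knownSites))
  expect_equal(sum(!back$detectable), sum(!e$knownSites$detectable))
})

test_that("planted sites carry elevated ESB with a smear decaying within 10 nt", {
  cfg <- smallSimConfig(seed = 73)
  e <- simulateExperiment(cfg)
  p <- e$truth$planted[e$truth$planted$detectable, ]
  sa <- e$sites_a
  key <- paste(sa$molecule_id, sa$position)
  atSite <- sa$esb_test[match(paste(p$molecule_id, p$position), key)]
  # every detectable planted site clears effect x min stoichiometry
  expect_true(all(atSite >= cfg$esbEffect * cfg$stoichRange[1] - 0.01))
  # positions far from every planted site stay at background
  far <- rep(TRUE, nrow(sa))
  for (i in seq_len(nrow(e$truth$planted))) {
    hit <- sa$molecule_id == e$truth$planted$molecule_id[i] &
      abs(sa$position - e$truth$planted$position[i]) <= cfg$smearWidth
    far[hit] <- FALSE
  }
  bg <- sa$esb_test[far & sa$esb_test < 0.05]  # exclude spike family
  expect_lt(mean(bg), 0.02)
  # immediate neighbors are elevated, decayed by the smear factor
  nb <- sa$esb_test[match(paste(p$molecule_id, p$position + 1), key)]
  nb <- nb[!is.na(nb)]
  expect_gt(mean(nb), 0.05)
  expect_lt(mean(nb), mean(atSite))
})

test_that("zero stoichiometry makes condition tables match the control", {
  cfg <- smallSimConfig(seed = 74, stoichRange = c(0, 0))
  e <- simulateExperiment(cfg)
  ks <- suppressWarnings(
    stats::ks.test(sample(e$sites_a$esb_test, 1000),
                   sample(e$sites_control$esb_test, 1000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("noise-free assays reproduce the planted effects exactly", {
  cfg <- smallSimConfig(seed = 75, msNoiseSd = 0, ctNoiseSd = 0)
  e <- simulateExperiment(cfg)
  p <- e$truth$planted
  for (ty in unique(e$ms$mod_name)) {
    ra <- mean(e$ms$abundance[e$ms$mod_name == ty & e$ms$condition == "a"])
    rb <- mean(e$ms$abundance[e$ms$mod_name == ty & e$ms$condition == "b"])
    expect_equal(rb / ra, mean(p$stoich_b[p$mod_name == ty]) /
                   mean(p$stoich_a[p$mod_name == ty]))
  }
  sel <- selectClassify(e$ct, "IVT")
  mod <- e$selectTargets$assay_id[e$selectTargets$modified]
  expect_equal(unname(sel$ddct[match(mod, sel$assay_id)]),
               rep(-cfg$ctEffect, length(mod)))
  expect_equal(unname(sel$ddct[!sel$assay_id %in% mod]),
               rep(0, sum(!sel$assay_id %in% mod)))
})

test_that("replicate CT noise propagates to ddCT with the closed-form sd", {
  # ddCT = mean over n replicates of two differenced wells, WT minus ref:
  # Var = 2 * (2 sigma^2 / n), so sd = 2 * sigma / sqrt(n)
  sigma <- 0.3
  nrep <- 2
  cfg <- smallSimConfig(seed = 76, ctNoiseSd = sigma,
                        nSelectModified = 0, nSelectUnmodified = 12)
  dd <- unlist(lapply(1:25, function(s) {
    e <- simulateAssays(simConfig(seed = s, ctNoiseSd = sigma,
                                  nSelectModified = 0,
                                  nSelectUnmodified = 12),
                        simulateGroundTruth(
                          smallSimConfig(seed = s),
                          simulateAnnotation(smallSimConfig(seed = s))))
    selectClassify(e$ct, "IVT")$ddct
  }))
  expect_equal(sd(dd), 2 * sigma / sqrt(nrep), tolerance = 0.15)
})

test_that("depth heterogeneity leaves some molecules under the 20-read floor", {
  e <- simulateExperiment(simConfig(seed = 77))
  expect_gt(sum(e$depth_a < 20), 0)
  expect_gt(sum(e$depth_a >= 20), length(e$depth_a) / 2)
  # rRNA coverage is always ample
  expect_true(all(e$depth_a[grep("^rRNA", names(e$depth_a))] > 100))
})

test_that("differential recovery: change labels track planted stoichiometry shifts", {
  hits <- 0L
  total <- 0L
  for (s in 1:10) {
    cfg <- smallSimConfig(seed = s,
                          conditionBMultipliers = c(Y = 0.2, m6A = 5))
    e <- simulateExperiment(cfg)
    detA <- detectedSites(e$sites_a, e$knownSites)
    detB <- detectedSites(e$sites_b, e$knownSites)
    d <- computeDeltaEsb(e$sites_a, e$sites_b, detA, detB)
    p <- e$truth$planted
    i <- match(paste(d$molecule_id, d$position),
               paste(p$molecule_id, p$position))
    keep <- !is.na(i) & p$detectable[i] & p$mod_name[i] %in% c("Y", "m6A") &
      d$delta_a != 0 & d$delta_b != 0
    want <- ifelse(p$stoich_b[i] > p$stoich_a[i], "increased", "decreased")
    hits <- hits + sum(d$change[keep] == want[keep])
    total <- total + sum(keep)
  }
  expect_gt(hits / total, 0.95)
})
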