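test_that("threshold application uses four inclusive criteria", {
  th <- ThresholdSet(0.1, 0.01, 3, 0.05)
  strong <- siteRow("16S", 1518, esb_test = 0.61, esb_control = 0.002,
                    odds_ratio = 5, p_adj = 1e-8)
  expect_equal(nrow(applyThresholds(strong, th)), 1L)
  # exact boundary values are all called (>= / <= as printed)
  edge <- siteRow("m1", 1, esb_test = 0.1, esb_control = 0.01,
                  odds_ratio = 3, p_adj = 0.05)
  expect_equal(nrow(applyThresholds(edge, th)), 1L)
  expect_equal(nrow(applyThresholds(
    siteRow("m1", 1, esb_test = 0.0999999, esb_control = 0.01,
            odds_ratio = 3, p_adj = 0.05), th)), 0L)
})

test_that("threshold application matches a row-by-row filter on random tables", {
  set.seed(41)
  for (rep in 1:10) {
    sites <- randomSiteTable(n = 200, nMolecules = 4)
    th <- ThresholdSet(runif(1, 0, 0.5), runif(1, 0, 0.2),
                       runif(1, 0, 6), runif(1, 0, 0.5))
    got <- applyThresholds(sites, th)
    want <- naiveApply(sites, esbTestMin(th), esbControlMax(th),
                       oddrMin(th), padjMax(th))
    want <- want[order(want$molecule_id, want$position), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("tool-specific candidate rules preserve printed comparisons", {
  row <- function(...) data.frame(molecule_id = "m", position = 1, ...)
  # boundary odds ratio and p-value are retained under the suggested rule
  expect_equal(nrow(candidateFilter(
    row(odds_ratio = 2.5, p_adj = 1e-5), "eligos")), 1L)
  expect_equal(nrow(candidateFilter(
    row(odds_ratio = 2.49, p_adj = 1e-5), "eligos")), 0L)
  # mixed inclusivity: OddR >= 1.5 but strict p cutoffs
  expect_equal(nrow(candidateFilter(
    row(odds_ratio = 1.5, p_g = 0.04, p_oddr = 0.04), "drummer")), 1L)
  expect_equal(nrow(candidateFilter(
    row(odds_ratio = 1.5, p_g = 0.05, p_oddr = 0.04), "drummer")), 0L)
  # both clauses must hold: control probability 0.9995 is not < 0.999
  expect_equal(nrow(candidateFilter(
    row(p_wt = 0.99995, p_ivt = 0.9995), "cheui_solo")), 0L)
  expect_equal(nrow(candidateFilter(
    row(p_wt = 0.99995, p_ivt = 0.9985), "cheui_solo")), 1L)
  expect_equal(nrow(candidateFilter(
    row(stoich_diff = 0.1, p_adj = 0.05), "cheui_diff")), 1L)
  expect_equal(nrow(candidateFilter(row(p_gmm = 0.01), "nanocompore")), 1L)
  expect_error(candidateFilter(row(p_gmm = 0.01), "unknown_tool"),
               "unknown rule")
})

test_that("known-site classification follows the category precedence", {
  depth <- c(`16S` = 100, tlow = 5)
  known <- data.frame(
    molecule_id = c("16S", "16S", "tlow", "16S"),
    position = c(1498L, 900L, 30L, 50L),
    mod_symbol = c("δ", "?", "P", "P"),
    detectable = c(TRUE, FALSE, TRUE, TRUE))
  # an offset signal 5 nt upstream of the known site
  called <- data.frame(molecule_id = c("16S", "16S", "tlow"),
                       position = c(1493L, 900L, 30L))
  out <- classifyKnownSites(called, known, depth)
  expect_equal(out$category,
               c("detected_with_offset", "type_not_detectable",
                 "depth_insufficient", "not_detected"))
  expect_equal(out$offset_nt[1], -5L)
  # not-detectable wins even over an exact call; low depth wins over a call
  expect_error(classifyKnownSites(called, rbind(known, data.frame(
    molecule_id = "ghost", position = 1L, mod_symbol = "P",
    detectable = TRUE)), depth), "no depth")
})

test_that("offset matching takes the nearest hit, ties upstream", {
  depth <- c(m = 100)
  known <- data.frame(molecule_id = "m", position = 50L, mod_symbol = "P",
                      detectable = TRUE)
  called <- data.frame(molecule_id = "m", position = c(47L, 53L))
  out <- classifyKnownSites(called, known, depth)
  expect_equal(out$offset_nt, -3L)
  out <- classifyKnownSites(data.frame(molecule_id = "m",
                                       position = c(46L, 53L)),
                            known, depth)
  expect_equal(out$offset_nt, 3L)
})

test_that("classification matches the brute-force oracle and partitions the catalogue", {
  set.seed(42)
  for (rep in 1:25) {
    called <- randomCalled()
    known <- randomKnown()
    depth <- setNames(sample(c(5, 30, 100), 3, replace = TRUE),
                      sprintf("mol%d", 1:3))
    got <- classifyKnownSites(called, known, depth)
    want <- naiveClassify(called, known, depth)
    expect_equal(got$category, want$category)
    expect_equal(got$offset_nt, want$offset_nt)
    expect_equal(sum(table(got$category)), nrow(known))
  }
})

test_that("region-tolerant precision counts near-miss regions as true", {
  known <- data.frame(molecule_id = "16S", position = 12L,
                      mod_symbol = "P", detectable = TRUE)
  called <- data.frame(molecule_id = "16S", position = 5:8)
  pr <- precisionRecall(called, known)
  expect_equal(pr$precision, 1)   # region end 8 is within 10 nt of site 12
  expect_equal(pr$recall, 0)      # recall needs the exact position
  pr <- precisionRecall(data.frame(molecule_id = "16S", position = 12L),
                        known)
  expect_equal(pr$recall, 1)

  empty <- precisionRecall(data.frame(molecule_id = character(),
                                      position = integer()), known)
  expect_true(is.na(empty$precision))
  expect_equal(empty$recall, 0)
})

test_that("precision/recall equals brute-force enumeration on random instances", {
  set.seed(43)
  for (rep in 1:30) {
    called <- randomCalled()
    known <- randomKnown()
    tol <- sample(c(0, 3, 10), 1)
    got <- precisionRecall(called, known, tolerance = tol)
    want <- naivePR(called, known, tolerance = tol)
    expect_equal(got$true_regions, want$true_regions)
    expect_equal(got$false_regions, want$false_regions)
    expect_equal(got$known_detected, want$known_detected)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
  }
})

test_that("recall is monotone under more restrictive thresholds", {
  set.seed(44)
  sites <- randomSiteTable(n = 300, nMolecules = 4)
  known <- randomKnown(nMolecules = 4, nSites = 10)
  base <- ThresholdSet(0.2, 0.05, 2, 0.2)
  prBase <- precisionRecall(applyThresholds(sites, base), known)
  for (tighter in list(ThresholdSet(0.4, 0.05, 2, 0.2),
                       ThresholdSet(0.2, 0.02, 2, 0.2),
                       ThresholdSet(0.2, 0.05, 5, 0.2),
                       ThresholdSet(0.2, 0.05, 2, 0.05))) {
    pr <- precisionRecall(applyThresholds(sites, tighter), known)
    expect_lte(pr$recall, prBase$recall)
  }
})

test_that("grid search equals exhaustive enumeration with the stated tie-break", {
  set.seed(45)
  for (rep in 1:4) {
    sites <- randomSiteTable(n = 120, nMolecules = 3)
    known <- randomKnown(nMolecules = 3, nSites = 6)
    grid <- GridSpec(sort(runif(3, 0.05, 0.6)), sort(runif(3, 0.01, 0.2)),
                     sort(runif(3, 0.5, 8)), sort(runif(2, 0.05, 0.6)))
    floor <- 0.5
    got <- suppressWarnings(gridSearch(sites, known, grid,
                                       precisionFloor = floor))
    want <- naiveGridSearch(sites, known, grid, floor = floor)
    if (is.null(want)) {
      expect_null(got$best)
    } else {
      expect_equal(esbTestMin(got$best), want$et)
      expect_equal(esbControlMax(got$best), want$ec)
      expect_equal(oddrMin(got$best), want$or)
      expect_equal(padjMax(got$best), want$pa)
    }
    expect_equal(nrow(got$landscape), gridSize(grid))
  }
})

test_that("a one-combination grid is returned iff it reaches the floor", {
  sites <- rbind(siteRow("m1", 10), siteRow("m1", 30))
  known <- data.frame(molecule_id = "m1", position = c(10L, 30L),
                      mod_symbol = "P", detectable = TRUE)
  g <- GridSpec(0.1, 0.01, 3, 0.05)
  got <- gridSearch(sites, known, g)
  expect_equal(esbTestMin(got$best), 0.1)
  expect_equal(got$bestPoint$recall, 1)
  # unmatched calls only: precision 0, below any floor
  far <- data.frame(molecule_id = "m1", position = c(100L, 130L),
                    mod_symbol = "P", detectable = TRUE)
  expect_warning(got <- gridSearch(sites, far, g), "no threshold")
  expect_null(got$best)
  expect_equal(nrow(got$landscape), 1L)
})

test_that("detection summaries report category and recall percentages", {
  mk <- function(cats, mols = NULL) {
    n <- length(cats)
    data.frame(molecule_id = if (is.null(mols)) sprintf("t%d", seq_len(n))
               else mols,
               position = seq_len(n), mod_symbol = "P",
               detectable = cats != "type_not_detectable",
               category = cats)
  }
  # 198 of 346 tRNA sites identified
  s <- detectionSummary(mk(rep(c("detected", "not_detected"),
                               c(198, 148))))
  expect_equal(s$recall$percent[s$recall$denominator == "overall"], 57.2)

  all <- detectionSummary(mk(rep("detected", 10)))
  expect_equal(all$recall$percent, c(100, 100, 100))
  expect_equal(all$molecules$percent_covered, 100)

  part <- detectionSummary(mk(c(rep("detected", 5),
                                rep("depth_insufficient", 3),
                                rep("type_not_detectable", 2))))
  expect_equal(sum(part$categories$count), 10L)
})
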