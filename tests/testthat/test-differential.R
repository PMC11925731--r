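test_that("delta-ESB follows the per-condition set-to-0 rule", {
  # m6,6A-like site: higher test ESB at the stressed condition
  sa <- siteRow("16S", 1518, esb_test = 0.4, esb_control = 0.02)
  sb <- siteRow("16S", 1518, esb_test = 0.61, esb_control = 0.02)
  d <- computeDeltaEsb(sa, sb, sa[, 1:2], sb[, 1:2])
  expect_equal(d$delta_a, 0.38)
  expect_equal(d$delta_b, 0.59)
  expect_equal(d$change, "increased")

  # called only in condition a: the b-side delta is zeroed
  d <- computeDeltaEsb(sa, sb, sa[, 1:2],
                       data.frame(molecule_id = character(),
                                  position = integer()))
  expect_equal(d$delta_b, 0)
  expect_equal(d$delta_a, 0.38)
  expect_equal(d$change, "decreased")
  expect_true(is.na(d$ratio) || is.finite(d$ratio))
})

test_that("delta-ESB records match a naive row-wise recomputation and are total", {
  set.seed(61)
  for (rep in 1:15) {
    sites <- randomSiteTable(n = 80, nMolecules = 3)
    sa <- sites
    sb <- sites
    sb$esb_test <- pmin(1, sb$esb_test * runif(nrow(sb), 0.5, 1.5))
    ca <- sa[runif(nrow(sa)) < 0.5, c("molecule_id", "position")]
    cb <- sb[runif(nrow(sb)) < 0.5, c("molecule_id", "position")]
    d <- computeDeltaEsb(sa, sb, ca, cb)
    # totality: one record per position in the union of called sets
    u <- unique(rbind(ca, cb))
    expect_equal(nrow(d), nrow(u))
    for (i in seq_len(nrow(d))) {
      inA <- any(ca$molecule_id == d$molecule_id[i] &
                   ca$position == d$position[i])
      ia <- which(sa$molecule_id == d$molecule_id[i] &
                    sa$position == d$position[i])
      wantA <- if (inA) sa$esb_test[ia] - sa$esb_control[ia] else 0
      expect_equal(d$delta_a[i], wantA)
      if (wantA != 0) expect_equal(d$ratio[i], d$delta_b[i] / wantA)
      else expect_true(is.na(d$ratio[i]))
    }
  }
})

test_that("condition comparison labels partition the called union", {
  depthA <- c(m1 = 100, m2 = 12, m3 = 50)
  depthB <- c(m1 = 100, m2 = 80, m3 = 50)
  ca <- data.frame(molecule_id = c("m1", "m3"), position = c(5L, 9L))
  cb <- data.frame(molecule_id = c("m1", "m2", "m3"),
                   position = c(5L, 7L, 20L))
  out <- compareConditions(ca, cb, depthA, depthB)
  st <- setNames(out$status$status,
                 paste(out$status$molecule_id, out$status$position))
  expect_equal(unname(st["m1 5"]), "shared")
  # molecule below 20 reads in exactly one condition
  expect_equal(unname(st["m2 7"]), "modification_in_unique_rna")
  # covered in both conditions but called in only one
  expect_equal(unname(st["m3 9"]), "unique_modification")
  expect_equal(sum(unlist(out$summary[1:3])), nrow(out$status))
  expect_error(compareConditions(ca, cb, depthA[-1], depthB), "missing")
})

test_that("condition comparison matches a brute-force labelling", {
  set.seed(62)
  for (rep in 1:20) {
    ca <- randomCalled()
    cb <- randomCalled()
    mols <- sprintf("mol%d", 1:3)
    depthA <- setNames(sample(c(10, 30, 100), 3, replace = TRUE), mols)
    depthB <- setNames(sample(c(10, 30, 100), 3, replace = TRUE), mols)
    out <- compareConditions(ca, cb, depthA, depthB)
    for (i in seq_len(nrow(out$status))) {
      m <- out$status$molecule_id[i]
      p <- out$status$position[i]
      inA <- any(ca$molecule_id == m & ca$position == p)
      inB <- any(cb$molecule_id == m & cb$position == p)
      want <- if (inA && inB) "shared"
      else if (xor(depthA[[m]] < 20, depthB[[m]] < 20))
        "modification_in_unique_rna"
      else "unique_modification"
      expect_equal(out$status$status[i], want)
    }
  }
})

test_that("MS correlation handles exact, anti-correlated and degenerate input", {
  mkDelta <- function(ratios) {
    do.call(rbind, lapply(seq_along(ratios), function(i) {
      data.frame(molecule_id = "m", position = i * 100 + 1:4,
                 delta_a = 0.2, delta_b = 0.2 * unname(ratios[i]),
                 mod_type = names(ratios)[i])
    }))
  }
  mkMs <- function(ratios) {
    do.call(rbind, lapply(seq_along(ratios), function(i) {
      data.frame(mod_name = names(ratios)[i], condition = c("a", "b"),
                 replicate = 1, abundance = c(1, unname(ratios[i])))
    }))
  }
  r <- c(D = 0.6, Y = 1.0, m6A = 1.4, Gm = 1.1)
  out <- msCorrelation(mkDelta(r), mkMs(r), "a", "b")
  expect_equal(out$rho, 1.0)

  anti <- msCorrelation(mkDelta(c(D = 1, Y = 2, m6A = 3)),
                        mkMs(c(D = 3, Y = 2, m6A = 1)), "a", "b")
  expect_equal(anti$rho, -1.0)

  expect_error(msCorrelation(mkDelta(c(D = 1, Y = 2)),
                             mkMs(c(D = 1, Y = 2)), "a", "b"),
               "at least 3")
  expect_error(msCorrelation(mkDelta(c(D = 1, Y = 1, m6A = 1)),
                             mkMs(c(D = 1, Y = 1, m6A = 1)), "a", "b"),
               "zero variance")
})

test_that("MS correlation is symmetric under swapping conditions (log scale)", {
  set.seed(63)
  ratios <- c(D = 0.6, Y = 0.9, m6A = 1.3, Gm = 1.1, Um = 0.75)
  delta <- do.call(rbind, lapply(seq_along(ratios), function(i) {
    data.frame(molecule_id = "m", position = i * 100 + 1:5,
               delta_a = runif(5, 0.1, 0.4),
               mod_type = names(ratios)[i])
  }))
  delta$delta_b <- delta$delta_a * ratios[delta$mod_type] *
    runif(nrow(delta), 0.95, 1.05)
  ms <- do.call(rbind, lapply(seq_along(ratios), function(i) {
    data.frame(mod_name = names(ratios)[i], condition = c("a", "b"),
               replicate = 1,
               abundance = c(1, unname(ratios[i]) * runif(1, 0.97, 1.03)))
  }))
  fwd <- msCorrelation(delta, ms, "a", "b")
  swapped <- delta
  swapped$delta_a <- delta$delta_b
  swapped$delta_b <- delta$delta_a
  rev <- msCorrelation(swapped, ms, "b", "a")
  expect_equal(cor(log(rev$pairs$seq_ratio), log(rev$pairs$ms_ratio)),
               cor(log(fwd$pairs$seq_ratio), log(fwd$pairs$ms_ratio)),
               tolerance = 1e-12)
})

test_that("detected sites are catalogue positions with sufficient depth", {
  sites <- rbind(siteRow("m1", 5, depth = 100), siteRow("m1", 6, depth = 100),
                 siteRow("m2", 5, depth = 10))
  known <- data.frame(molecule_id = c("m1", "m2"), position = c(5L, 5L),
                      mod_symbol = "P", detectable = TRUE)
  out <- detectedSites(sites, known)
  expect_equal(nrow(out), 1L)
  expect_equal(out$molecule_id, "m1")
  expect_equal(nrow(detectedSites(sites, known, minDepth = 5)), 2L)
})
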