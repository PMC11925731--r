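# Brute-force reference implementations, independent of the package's
# vectorized code paths, plus random-instance builders.

# scan sorted positions molecule by molecule for consecutive runs
naiveMerge <- function(called) {
  out <- data.frame(molecule_id = character(), start = integer(),
                    end = integer())
  for (m in sort(unique(called$molecule_id))) {
    pos <- sort(unique(called$position[called$molecule_id == m]))
    if (!length(pos)) next
    s <- pos[1]
    for (i in seq_along(pos)) {
      last <- i == length(pos)
      if (last || pos[i + 1] != pos[i] + 1) {
        out <- rbind(out, data.frame(molecule_id = m, start = s,
                                     end = pos[i]))
        if (!last) s <- pos[i + 1]
      }
    }
  }
  out
}

naivePR <- function(called, known, tolerance = 10) {
  regions <- naiveMerge(called)
  nTrue <- 0L
  for (i in seq_len(nrow(regions))) {
    k <- known[known$molecule_id == regions$molecule_id[i], ]
    hit <- FALSE
    for (p in k$position) {
      if (p >= regions$start[i] - tolerance &&
          p <= regions$end[i] + tolerance) hit <- TRUE
    }
    if (hit) nTrue <- nTrue + 1L
  }
  det <- 0L
  for (i in seq_len(nrow(known))) {
    if (any(called$molecule_id == known$molecule_id[i] &
            called$position == known$position[i])) det <- det + 1L
  }
  list(true_regions = nTrue, false_regions = nrow(regions) - nTrue,
       known_detected = det, known_total = nrow(known),
       precision = if (nrow(regions)) nTrue / nrow(regions) else NA_real_,
       recall = if (nrow(known)) det / nrow(known) else NA_real_)
}

naiveApply <- function(sites, esbTest, esbControl, oddr, padj) {
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    keep[i] <- sites$esb_test[i] >= esbTest &&
      sites$esb_control[i] <= esbControl &&
      sites$odds_ratio[i] >= oddr && sites$p_adj[i] <= padj
  }
  sites[keep, , drop = FALSE]
}

naiveClassify <- function(called, known, depth, minDepth = 20,
                          offsetWindow = 10) {
  cat_out <- character(nrow(known))
  off_out <- rep(NA_integer_, nrow(known))
  for (i in seq_len(nrow(known))) {
    if (!is.na(known$detectable[i]) && !known$detectable[i]) {
      cat_out[i] <- "type_not_detectable"
      next
    }
    if (depth[[known$molecule_id[i]]] < minDepth) {
      cat_out[i] <- "depth_insufficient"
      next
    }
    pos <- called$position[called$molecule_id == known$molecule_id[i]]
    if (known$position[i] %in% pos) {
      cat_out[i] <- "detected"
    } else {
      d <- pos - known$position[i]
      d <- d[abs(d) <= offsetWindow]
      if (length(d)) {
        cat_out[i] <- "detected_with_offset"
        d <- sort(d)  # upstream (more negative) first
        off_out[i] <- d[order(abs(d), d)][1]
      } else {
        cat_out[i] <- "not_detected"
      }
    }
  }
  list(category = cat_out, offset_nt = off_out)
}

# exhaustive grid evaluation with the stated tie-break, recomputed from
# scratch (no landscape lookup)
naiveGridSearch <- function(sites, known, grid, floor = 0.85,
                            tolerance = 10) {
  evalCombo <- function(et, ec, or, pa) {
    naivePR(naiveApply(sites, et, ec, or, pa), known, tolerance)
  }
  rows <- list()
  for (et in grid@esbTestValues) for (ec in grid@esbControlValues)
    for (or in grid@oddrValues) for (pa in grid@padjValues) {
      pr <- evalCombo(et, ec, or, pa)
      rows <- c(rows, list(c(et = et, ec = ec, or = or, pa = pa,
                             precision = pr$precision, recall = pr$recall)))
    }
  land <- as.data.frame(do.call(rbind, rows))
  feas <- land[!is.na(land$precision) & land$precision >= floor, ]
  if (!nrow(feas)) return(NULL)
  feas <- feas[feas$recall == max(feas$recall), ]
  feas <- feas[order(-feas$et, feas$ec, -feas$or, feas$pa), ]
  cur <- feas[1, ]
  for (par in c("pa", "ec", "or", "et")) {
    vals <- switch(par, pa = grid@padjValues, ec = grid@esbControlValues,
                   or = grid@oddrValues, et = grid@esbTestValues)
    vals <- if (par %in% c("pa", "ec")) sort(vals, decreasing = TRUE)
    else sort(vals)
    for (v in vals) {
      trial <- cur
      trial[[par]] <- v
      pr <- evalCombo(trial$et, trial$ec, trial$or, trial$pa)
      if (!is.na(pr$precision) && pr$precision == cur$precision &&
          pr$recall == cur$recall) {
        cur <- trial
        break
      }
    }
  }
  cur
}

# random small site table with a handful of signal positions
randomSiteTable <- function(n = 50, nMolecules = 3, maxPos = 60) {
  mol <- sprintf("mol%d", sample(nMolecules, n, replace = TRUE))
  pos <- sample(maxPos, n, replace = TRUE)
  keep <- !duplicated(paste(mol, pos))
  mol <- mol[keep]; pos <- pos[keep]; n <- length(mol)
  data.frame(molecule_id = mol, position = pos,
             ref_base = sample(c("A", "C", "G", "U"), n, replace = TRUE),
             esb_test = runif(n), esb_control = runif(n, 0, 0.2),
             odds_ratio = runif(n, 0, 12), p_adj = runif(n),
             depth = sample(100, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

randomCalled <- function(nMolecules = 3, maxPos = 50, density = 0.3) {
  rows <- list()
  for (m in seq_len(nMolecules)) {
    pos <- which(runif(maxPos) < density)
    if (length(pos)) {
      rows <- c(rows, list(data.frame(molecule_id = sprintf("mol%d", m),
                                      position = pos)))
    }
  }
  if (!length(rows)) {
    return(data.frame(molecule_id = character(), position = integer()))
  }
  do.call(rbind, rows)
}

randomKnown <- function(nMolecules = 3, maxPos = 50, nSites = 5) {
  mol <- sprintf("mol%d", sample(nMolecules, nSites, replace = TRUE))
  pos <- sample(maxPos, nSites, replace = TRUE)
  keep <- !duplicated(paste(mol, pos))
  data.frame(molecule_id = mol[keep], position = pos[keep],
             mod_symbol = "P",
             detectable = sample(c(TRUE, TRUE, TRUE, FALSE), sum(keep),
                                 replace = TRUE),
             stringsAsFactors = FALSE)
}

# minimal valid site-table row(s)
siteRow <- function(molecule = "m1", position = 1, esb_test = 0.5,
                    esb_control = 0.001, odds_ratio = 10, p_adj = 1e-6,
                    depth = 100, ref_base = "A") {
  data.frame(molecule_id = molecule, position = position,
             ref_base = ref_base, esb_test = esb_test,
             esb_control = esb_control, odds_ratio = odds_ratio,
             p_adj = p_adj, depth = depth, stringsAsFactors = FALSE)
}

# CT table for one assay yielding a target ddct (noise-free)
ctForDdct <- function(assay, ddct, refType = "IVT", nrep = 2) {
  rbind(
    data.frame(assay_id = assay, sample_type = "WT", replicate = seq_len(nrep),
               ct_target = 20 + ddct, ct_control_a = 20),
    data.frame(assay_id = assay, sample_type = refType,
               replicate = seq_len(nrep), ct_target = 20, ct_control_a = 20))
}

# small-but-structured simulation profile for fast tests
smallSimConfig <- function(seed = 1L, ...) {
  simConfig(seed = seed,
            nMolecules = c(tRNA = 8, rRNA = 2, mRNA = 10, ncRNA = 3),
            plantedMean = c(tRNA = 5, rRNA = 10, mRNA = 1.2, ncRNA = 0.5),
            ...)
}
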