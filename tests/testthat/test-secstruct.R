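test_that("amide hydrogens are placed anti-parallel to the preceding carbonyl", {
  ## previous carbonyl along +x: C at origin-side, O displaced -x, so the
  ## formula puts H one Angstrom along +x from N
  res1 <- list(N = c(0, 0, -3), CA = c(0, 0.9, -2.2), C = c(0, 0, -1.3),
               O = c(-1.23, 0, -1.3))
  res2 <- list(N = c(0, 0, 0), CA = c(0, 0.9, 0.8), C = c(0, 0, 1.7),
               O = c(1.23, 0, 1.7))
  s <- structureFromResidues(list(res1, res2), aa = c("A", "V"))
  h <- placeAmideHydrogens(s)
  H <- residueAtoms(h, "A", 2L)$H
  expect_equal(H, c(1, 0, 0), tolerance = 1e-12)
  ## the chain-first residue has no preceding carbonyl
  expect_null(residueAtoms(h, "A", 1L)$H)
})

test_that("prolines receive no amide hydrogen and never donate", {
  res <- buildStrand(4)
  s <- structureFromResidues(res, aa = c("A", "P", "A", "A"))
  h <- placeAmideHydrogens(s)
  expect_null(residueAtoms(h, "A", 2L)$H)
  expect_false(is.null(residueAtoms(h, "A", 3L)$H))
})

test_that("placed N-H bond lengths are exactly 1 Angstrom on generator output", {
  b <- cachedSandwich(seed = 3L)
  h <- placeAmideHydrogens(b$structure)
  a <- h@atoms
  hs <- a[a$elety == "H", ]
  ns <- a[a$elety == "N", ]
  d <- sqrt(rowSums((as.matrix(hs[, c("x", "y", "z")]) -
    as.matrix(ns[match(hs$resno, ns$resno), c("x", "y", "z")]))^2))
  expect_true(all(abs(d - 1) < 1e-9))
})

test_that("the Kabsch-Sander energy matches its electrostatic formula", {
  don <- list(N = c(0, 0, 0), H = c(1, 0, 0))
  acc <- list(C = c(4.13, 0, 0), O = c(2.9, 0, 0))
  ## independent arithmetic on the four pair distances
  expected <- 0.084 * 332 * (1 / 2.9 + 1 / 3.13 - 1 / 1.9 - 1 / 4.13)
  expect_equal(ksEnergy(don, acc), expected, tolerance = 1e-12)
  ## distant pair: all 1/r terms cancel to numerical zero
  far <- list(C = c(1000, 0, 0), O = c(998.77, 0, 0))
  expect_lt(abs(ksEnergy(don, far)), 1e-3)
  ## clash sentinel
  expect_true(is.na(ksEnergy(don, list(C = c(0.2, 0, 0), O = c(0.3, 0, 0)))))
})

test_that("an ideal helix is dominated by i -> i-4 bonds and has no strands", {
  h <- helixChain(30L)
  g <- buildHBondGraph(h)
  expect_gt(nrow(g@bonds), 15)
  expect_true(all(g@bonds$donor - g@bonds$acceptor == 4L))
  tp <- assignStrands(g, h)
  expect_equal(nrow(tp@strands), 0L)
  ss <- secondaryStructureString(h, "A")
  expect_gt(mean(strsplit(ss, "")[[1]] == "H"), 0.8)
})

test_that("an antiparallel hairpin shows reciprocal inter-strand bonds", {
  b <- cachedSandwich(seed = 4L, nStrands = 2L, noiseSigma = 0)
  g <- buildHBondGraph(b$structure)
  bb <- g@bonds
  st <- b$truth$strands
  s1 <- st$first[1]:st$last[1]; s2 <- st$first[2]:st$last[2]
  inter <- bb[bb$donor %in% s1 & bb$acceptor %in% s2 |
              bb$donor %in% s2 & bb$acceptor %in% s1, ]
  expect_gt(nrow(inter), 4)
  ## reciprocal pairs: donor->acceptor and acceptor->donor at registered rows
  key <- paste(inter$donor, inter$acceptor)
  rev <- paste(inter$acceptor, inter$donor)
  expect_gt(sum(rev %in% key), 2)
  tp <- assignStrands(g, b$structure)
  expect_equal(nrow(tp@strands), 2L)
  expect_equal(tp@pairings$orientation, "antiparallel")
})

test_that("a single residue yields an empty graph", {
  s <- structureFromResidues(buildStrand(2)[1], aa = "A")
  expect_equal(nrow(buildHBondGraph(s)@bonds), 0L)
})

test_that("strand assignment recovers the generated sandwich", {
  for (off in 0:1) {
    b <- cachedSandwich(seed = 5L, connectivity = off)
    tp <- assignStrands(buildHBondGraph(b$structure), b$structure)
    tr <- b$truth$strands
    expect_equal(nrow(tp@strands), 8L)
    expect_true(all(abs(tp@strands$first - tr$first) <= 1))
    expect_true(all(abs(tp@strands$last - tr$last) <= 1))
    expect_equal(sort(vapply(tp@sheets, length, integer(1))), c(4L, 4L))
    ## pairing graph equals the construction template
    obs <- tp@pairings[order(tp@pairings$i, tp@pairings$j), c("i", "j")]
    tpl <- topologyTemplate(off)
    expect_equal(unname(as.matrix(obs)),
                 unname(as.matrix(tpl[order(tpl$i, tpl$j), ])))
  }
})

test_that("a one-residue bulge is merged into a single strand", {
  ## strand A: 8 ideal residues; strand B antiparallel with one extra
  ## (bulged) residue inserted mid-strand, displaced off the lattice but
  ## with its carbonyl still on the hydrogen-bond axis (a classic beta
  ## bulge keeps the flanking bond pattern)
  tail0 <- list(list(N = c(0, -0.4, -4.3), CA = c(0, -0.94, -3.3),
                     C = c(0, 0, -2.05), O = c(-1.23, 0, -2.05)))
  a <- buildStrand(8, origin = c(0, 0, 0), direction = c(0, 0, 1),
                   parityPhase = 0L)
  bTop <- buildStrand(8, origin = c(4.13, 0, 3.3 * 7), direction = c(0, 0, -1),
                      parityPhase = 0L)
  bulge <- list(N = c(5.6, 1.4, 3.3 * 4 + 0.7), CA = c(5.3, 1.1, 3.3 * 4 + 0.1),
                C = c(4.13, 0.3, 3.3 * 4 - 0.3), O = c(2.93, 0.15, 3.3 * 4 - 0.45))
  loop <- lapply(1:4, function(k) {
    z <- 3.3 * 7 + 2.5 * k
    list(N = c(1 + k, -2, z - 1), CA = c(1 + k, -2.5, z), C = c(1 + k, -2, z + 1),
         O = c(1 + k, -0.9, z + 1))
  })
  resList <- c(tail0, a, loop, bTop[1:4], list(bulge), bTop[5:8])
  s <- structureFromResidues(resList, aa = "V", id = "bulged-hairpin")
  tp <- assignStrands(buildHBondGraph(s), s)
  bStrands <- tp@strands[tp@strands$first > 13, , drop = FALSE]
  expect_equal(nrow(bStrands), 1L)
  ## the merged strand spans the bulge residue (18)
  expect_true(bStrands$first <= 17 && bStrands$last >= 19)
})

test_that("a chain break splits a strand run", {
  b <- cachedSandwich(seed = 6L, noiseSigma = 0)
  tr <- b$truth$strands
  s <- b$structure
  ## delete a mid-strand residue of strand 3: the neighbours are left 6.6 A
  ## apart, beyond the 4.5 A chain-break threshold
  mid <- tr$first[3] + 4L
  s@atoms <- s@atoms[s@atoms$resno != mid, ]
  tp <- assignStrands(buildHBondGraph(s), s)
  pieces <- tp@strands[tp@strands$first >= tr$first[3] - 1 &
                       tp@strands$last <= tr$last[3] + 1, ]
  expect_gte(nrow(pieces), 1L)
  expect_false(any(pieces$first < mid & pieces$last > mid))
})

test_that("raising the cutoff magnitude never adds bonds", {
  for (seed in 1:3) {
    b <- cachedSandwich(seed = seed)
    loose <- buildHBondGraph(b$structure, cutoff = -0.5)@bonds
    tight <- buildHBondGraph(b$structure, cutoff = -1.5)@bonds
    kLoose <- paste(loose$donor, loose$acceptor)
    kTight <- paste(tight$donor, tight$acceptor)
    expect_true(all(kTight %in% kLoose))
    expect_lte(nrow(tight), nrow(loose))
  }
})
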