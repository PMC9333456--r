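test_that("composition counts residues exactly", {
  expect_equal(unname(residueComposition("PPPP", "P")$fraction), 1)
  cmp <- residueComposition("PGDEAPLERK", c("P", "G", "E"))
  expect_equal(unname(cmp$fraction), c(2, 1, 2) / 10)
  expect_equal(cmp$length, 10L)
  ## seeded random sequence with independently tallied counts
  set.seed(7)
  v <- sample(c("A", "P", "G", "K", "D"), 200, replace = TRUE)
  cmp2 <- residueComposition(paste(v, collapse = ""), c("P", "K"))
  expect_equal(unname(cmp2$fraction), c(sum(v == "P"), sum(v == "K")) / 200)
  expect_equal(sum(residueComposition("ACDEFGHIKLMNPQRSTVWY")$fraction), 1)
  expect_error(residueComposition(""), class = "c2UsageError")
  expect_warning(residueComposition("AXXA", "A"), "non-standard")
})

test_that("pI matches the independent ProtParam oracle on the FerI rows", {
  ## frozen oracle values (Biopython ProtParam on the gap-stripped rows;
  ## reliable above its bisection floor of pH 4.05)
  oracle <- c(Dysferlin = 4.2084, Otoferlin = 4.3945, Fer1L4 = 6.7537,
              Fer1L6 = 5.0557)
  t1 <- ferlinFerITable()
  for (nm in names(oracle)) {
    seq <- t1$sequence[t1$ferlin == nm]
    expect_equal(isoelectricPoint(sequenceSegment(seq)), oracle[[nm]],
                 tolerance = 2e-3)
  }
  ## below that floor the zero-charge property pins the value instead
  for (nm in c("Myoferlin", "Fer1L5")) {
    seg <- sequenceSegment(t1$sequence[t1$ferlin == nm])
    pi <- isoelectricPoint(seg)
    expect_lt(pi, 4.05)
    expect_lt(abs(netCharge(seg, pi)), 1e-3)
  }
})

test_that("pI of single glycine equals the two-group closed form", {
  ## only the termini ionize: pI = (pKa_Nterm + pKa_Cterm) / 2
  expect_equal(isoelectricPoint("G"), (7.5 + 3.55) / 2, tolerance = 1e-3)
})

test_that("pI is monotone in charged-residue content", {
  expect_gt(isoelectricPoint("KKKKKKKK"), isoelectricPoint("DDDDDDDD"))
  base <- "ALSTGVNQ"
  for (extra in c("D", "E")) {
    expect_lte(isoelectricPoint(paste0(base, extra)), isoelectricPoint(base))
  }
  for (extra in c("K", "R")) {
    expect_gte(isoelectricPoint(paste0(base, extra)), isoelectricPoint(base))
  }
})

test_that("pI bisection converges with near-zero net charge on random peptides", {
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      sample(5:500, 1), replace = TRUE), collapse = "")
    pi <- isoelectricPoint(s)
    expect_true(pi > 0 && pi < 14)
    expect_lt(abs(netCharge(s, pi)), 1e-3)
  }
})

test_that("extinction coefficients follow the composition formula", {
  expect_equal(extinctionCoefficient("GASL"), 0)
  expect_equal(extinctionCoefficient("W"), 5500)
  expect_equal(extinctionCoefficient("WWYC"), 2 * 5500 + 1490)
  expect_equal(extinctionCoefficient("WWYCC", "all-cystine"),
               2 * 5500 + 1490 + 125)
  expect_equal(extinctionCoefficient("WWYCC", "all-reduced"), 2 * 5500 + 1490)
  ## additivity over concatenation in reduced mode
  a <- "WYCAT"; b <- "CWWG"
  expect_equal(extinctionCoefficient(paste0(a, b), "all-reduced"),
               extinctionCoefficient(a, "all-reduced") +
                 extinctionCoefficient(b, "all-reduced"))
})

test_that("identity and similarity match hand counts", {
  expect_equal(identitySimilarity(c("ACDE", "ACDE"))$identity, 1)
  expect_equal(identitySimilarity(c("AC", "GT"))$identity, 0)
  ## 3-row toy alignment, hand-counted:
  ## r1 A C D - K ; r2 A C E - K ; r3 A - D E K
  ## pair 1-2: 5 occupied columns in common frame -> 4 comparable, 3 identical,
  ##           D/E similar -> id 3/4, sim 4/4 over 4 occupied columns
  out <- identitySimilarity(c("ACD-K", "ACE-K", "A-DEK"))
  p12 <- out$pairs[out$pairs$i == 1 & out$pairs$j == 2, ]
  expect_equal(p12$identity, 3 / 4)
  expect_equal(p12$similarity, 4 / 4)
  p13 <- out$pairs[out$pairs$i == 1 & out$pairs$j == 3, ]
  ## columns with >= 1 residue: 1,2,3,4,5 -> 5; identical: A,D,K -> 3
  expect_equal(p13$identity, 3 / 5)
  expect_error(identitySimilarity("ACDE"), class = "c2UsageError")
  expect_error(identitySimilarity(c("AC", "ACG")), class = "c2UsageError")
})

test_that("TM arithmetic uses inclusive spans and exclusive extracellular counts", {
  tm <- ferlinTmTable()
  dys <- tm[tm$ferlin == "Dysferlin", ]
  out <- tmAnalytics("Dysferlin", c(dys$tm_first, dys$tm_last),
                     c(dys$extra_first, dys$extra_last))
  expect_equal(out$length, 23L)
  expect_equal(out$extracellular_count, 12L)
  expect_equal(tmAnalytics("x", c(5L, 5L))$length, 1L)
  ## conserved proline search window tolerates a hinge inside the span:
  ## a Pro four residues before the span end is still found
  seqIn <- paste0(strrep("A", 90), "P", strrep("A", 20))  # Pro at 91
  expect_equal(tmAnalytics("oto-like", c(73L, 95L), sequence = seqIn)$conserved_pro, 91L)
  ## and one just past the span end is found for the common case
  seqOut <- paste0(strrep("A", 95), "P", strrep("A", 20))  # Pro at 96
  expect_equal(tmAnalytics("dys-like", c(73L, 95L), sequence = seqOut)$conserved_pro, 96L)
})

test_that("hydropathy scan flags hydrophobic runs only", {
  polyI <- strrep("I", 40)
  out <- hydropathyScan(polyI, window = 9L)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$first, out$last), c(1L, 40L))
  expect_equal(nrow(hydropathyScan(strrep("D", 40), window = 9L)), 0L)
  ## one 23-residue I-run inside an alternating I/D background
  bg <- paste(rep(c("I", "D"), 20), collapse = "")
  s <- paste0(bg, strrep("I", 23), bg)
  out2 <- hydropathyScan(s, window = 9L)
  expect_equal(nrow(out2), 1L)
  run <- (nchar(bg) + 1):(nchar(bg) + 23)
  expect_true(out2$first <= min(run) + 2 && out2$last >= max(run) - 2)
  expect_error(hydropathyScan("IIII", window = 9L), class = "c2UsageError")
  expect_error(hydropathyScan(polyI, window = 8L), class = "c2UsageError")
})

test_that("the pocket census counts acidic reference slots", {
  ref <- cachedReference()
  refIn <- list(structure = ref$structure, annotation = ref$annotation,
                truth = ref$truth)
  ## the reference against itself: all six slots acidic
  self <- pocketCensus(refIn, refIn)
  expect_equal(self$acidic_count, 6L)
  expect_equal(self$call, "binding-likely")
  ## a pocket-free replica: same fold, proline loops, no acidic slots
  b <- cachedSandwich(seed = 22L, pocketAcidic = FALSE)
  cand <- list(structure = b$structure,
               annotation = annotateC2(b$structure)[[1]])
  none <- pocketCensus(cand, refIn)
  expect_equal(none$acidic_count, 0L)
  expect_equal(none$call, "binding-unlikely")
  ## a single aspartate at one slot: census of one, still binding-unlikely
  b2 <- buildSandwich(sandwichSpec(seed = 23L, pocketAcidic = FALSE))
  s2 <- b2$structure
  slot <- b2$truth$pocketPositions[1]
  s2@atoms$aa[s2@atoms$resno == slot] <- "D"
  cand2 <- list(structure = s2, annotation = annotateC2(s2)[[1]])
  one <- pocketCensus(cand2, refIn)
  expect_equal(one$acidic_count, 1L)
  expect_equal(one$call, "binding-unlikely")
})

test_that("cation proximity recovers reference pocket residues", {
  b <- cachedSandwich(seed = 24L, noiseSigma = 0)
  s <- b$structure
  ## drop a cation 2.5 A from the CA of a known pocket residue
  slot <- b$truth$pocketPositions[3]
  ca <- caCoords(s, "A", slot)
  s@hetero <- data.frame(chain = "A", resno = 900L, ins = "", aa = "X",
                         elety = "CA", x = ca[1] + 2.5, y = ca[2], z = ca[3],
                         occ = 1)
  hits <- referencePocketPositions(s, "A", cutoff = 4.0)
  expect_true(slot %in% hits)
  expect_true(all(abs(hits - slot) <= 2))
  sNo <- b$structure
  expect_error(referencePocketPositions(sNo, "A"), class = "c2UsageError")
})
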