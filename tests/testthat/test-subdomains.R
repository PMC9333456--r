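test_that("Kabsch superposition handles exact, rigid and degenerate inputs", {
  set.seed(1)
  a <- matrix(rnorm(30), 10)
  expect_equal(superposeKabsch(a, a)$rmsd, 0, tolerance = 1e-12)
  R <- randomRotation()
  b <- a %*% R + matrix(rep(c(3, -2, 7), each = 10), 10)
  f <- superposeKabsch(a, b)
  expect_lt(f$rmsd, 1e-6)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  ## the returned transform really maps b onto a
  expect_lt(max(abs(b %*% f$rotation +
                    matrix(f$translation, 10, 3, byrow = TRUE) - a)), 1e-6)
  expect_error(superposeKabsch(a[1:2, ], b[1:2, ]), class = "c2DegeneracyError")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superposeKabsch(line, line + 1), class = "c2DegeneracyError")
})

test_that("SVD superposition agrees with the quaternion method", {
  set.seed(2)
  devs <- replicate(50, {
    a <- matrix(rnorm(30), 10)
    b <- matrix(rnorm(30), 10)
    abs(superposeKabsch(a, b)$rmsd - quaternionRmsd(a, b))
  })
  expect_lt(max(devs), 1e-9)
})

test_that("self-alignment is the identity correspondence with zero RMSD", {
  x <- cachedAnnotated(seed = 7L)
  al <- alignStructures(x, x)
  expect_equal(al$rmsd, 0, tolerance = 1e-9)
  expect_identical(al$pairs$seq_a, al$pairs$seq_b)
})

test_that("alignment refuses mismatched topologies", {
  t1 <- cachedAnnotated(seed = 11L, connectivity = 0L)
  t2 <- cachedAnnotated(seed = 11L, connectivity = 1L)
  expect_error(alignStructures(t1, t2), class = "c2TopologyMismatch")
})

test_that("a loop insertion leaves strand residues paired and itself unpaired", {
  ref <- cachedReference()
  b <- cachedSandwich(seed = 17L,
                      insertions = list("b6-7" = list(length = 30L,
                                                      ssClass = "helix-rich")))
  cand <- list(structure = b$structure,
               annotation = annotateC2(b$structure)[[1]])
  al <- alignStructures(cand, ref)
  sp <- al$pairs[grepl("^strand", al$pairs$region), ]
  expect_gte(nrow(sp), 8 * 6)
  ## unpaired candidate residues = the inserted segment
  rnC <- cand$annotation@boundaries[1]:cand$annotation@boundaries[2]
  unpaired <- setdiff(rnC, al$pairs$seq_a)
  tri <- b$truth$insertions[[1]]
  expect_gte(length(intersect(unpaired, tri$first:tri$last)), tri$length - 4L)
})

test_that("insertion lengths are loop-length differences against the reference", {
  ref <- cachedReference()
  expect_equal(nrow(detectInsertions(ref, ref)), 0L)
  for (spec in list(c(30L, 1L), c(60L, 2L))) {
    b <- cachedSandwich(seed = 18L + spec[2],
                        insertions = list("b6-7" = list(length = spec[1],
                                                        ssClass = "helix-rich")))
    cand <- list(structure = b$structure,
                 annotation = annotateC2(b$structure)[[1]])
    ins <- detectInsertions(cand, ref)
    ## edge-strand fraying can register as a 1-residue difference at other
    ## loops; the true insertion must be recovered exactly
    real <- ins[ins$length > 2L, , drop = FALSE]
    expect_equal(nrow(real), 1L)
    expect_equal(real$host_loop, "b6-7")
    expect_equal(real$length, spec[1])
    expect_true(all(ins$length[ins$length <= 2L] <= 2L))
    ## antisymmetry: the reference has no insertion relative to the candidate
    rev <- detectInsertions(ref, cand)
    expect_false("b6-7" %in% rev$host_loop)
  }
})

test_that("the subdomain rule enforces >20 residues and >=2 agreeing paralogs", {
  ssHelix <- paste(rep("H", 200), collapse = "")
  mkIns <- function(len) data.frame(host_loop = "b6-7", length = len,
                                    first = 100L, last = 100L + len - 1L)
  ## length 20 in every paralog: no call (strict inequality)
  expect_equal(nrow(callSubdomains(list(p1 = mkIns(20L), p2 = mkIns(20L)),
                                   c(p1 = ssHelix, p2 = ssHelix))), 0L)
  ## length 21 qualifies
  out <- callSubdomains(list(p1 = mkIns(21L), p2 = mkIns(21L)),
                        c(p1 = ssHelix, p2 = ssHelix))
  expect_equal(nrow(out), 1L)
  expect_true(out$confirmed)
  ## a single paralog with a long insertion: no conserved call
  none <- mkIns(0L)[0, ]
  expect_equal(nrow(callSubdomains(
    list(p1 = mkIns(40L), p2 = none, p3 = none),
    c(p1 = ssHelix, p2 = ssHelix, p3 = ssHelix))), 0L)
  ## single-paralog input: candidate returned but unconfirmed
  solo <- callSubdomains(list(p1 = mkIns(40L)), c(p1 = ssHelix))
  expect_equal(nrow(solo), 1L)
  expect_false(solo$confirmed)
  ## disagreeing secondary-structure classes do not count together
  ssCoil <- paste(rep("-", 200), collapse = "")
  expect_equal(nrow(callSubdomains(list(p1 = mkIns(30L), p2 = mkIns(30L)),
                                   c(p1 = ssHelix, p2 = ssCoil))), 0L)
})

test_that("five of six paralogs sharing an insertion yield one conserved call", {
  ref <- cachedReference()
  sets <- list(); sss <- character()
  for (k in 1:6) {
    insk <- if (k <= 5) list("b1-2" = list(length = 25L, ssClass = "helix-rich"))
            else list()
    b <- cachedSandwich(seed = 30L + k, insertions = insk)
    cand <- list(structure = b$structure,
                 annotation = annotateC2(b$structure)[[1]])
    nm <- paste0("paralog", k)
    sets[[nm]] <- detectInsertions(cand, ref)
    sss[nm] <- secondaryStructureString(b$structure, "A")
  }
  out <- callSubdomains(sets, sss)
  expect_equal(nrow(out), 1L)
  expect_equal(out$host_loop, "b1-2")
  expect_equal(out$ss_class, "helix-rich")
  expect_equal(out$n_paralogs, 5L)
  ## calls are invariant to paralog input order
  perm <- rev(names(sets))
  out2 <- callSubdomains(sets[perm], sss[perm])
  expect_equal(out2, out)
})

test_that("fragment stitching reproduces the parent chain", {
  b <- cachedSandwich(seed = 21L)
  s <- b$structure
  for (cuts in list(60L, c(45L, 90L))) {
    fr <- splitWithOverlap(s, cuts, overlap = 20L, rigid = TRUE, seed = 5L)
    expect_length(fr, length(cuts) + 1L)
    st <- stitchFragments(fr)
    expect_identical(residueNumbers(st$structure, "A"), residueNumbers(s, "A"))
    dev <- max(abs(as.matrix(st$structure@atoms[, c("x", "y", "z")]) -
                   as.matrix(s@atoms[, c("x", "y", "z")])))
    expect_lt(dev, 1e-6)
    expect_true(all(st$junctions$rmsd < 1e-6))
    expect_true(all(st$junctions$overlap == 20L))
  }
})

test_that("disjoint fragments refuse to stitch", {
  b <- cachedSandwich(seed = 21L)
  f1 <- extractRegion(b$structure, "A", 1L, 50L)
  f2 <- extractRegion(b$structure, "A", 80L, 130L)
  expect_error(stitchFragments(list(f1, f2)), class = "c2StitchError")
})

test_that("overlay RMSD is zero for identical domains and equals the pair fit", {
  x <- cachedAnnotated(seed = 7L)
  ov <- overlayRmsd(list(a = x, b = x, c = x))
  expect_lt(max(ov$matrix), 1e-9)
  expect_equal(ov$mean, 0, tolerance = 1e-9)
  y <- cachedAnnotated(seed = 16L)
  two <- overlayRmsd(list(a = x, b = y))
  expect_equal(two$mean, alignStructures(x, y)$rmsd)
  expect_error(overlayRmsd(list(a = x)), class = "c2UsageError")
})

test_that("overlay of noisy replicas matches the closed-form noise RMSD", {
  ## six replicas of one geometry at 0.5 A per-residue noise, compared over
  ## ground-truth register: E[RMSD] for isotropic Gaussian displacement is
  ## sqrt(6) sigma, less the 6 rigid degrees of freedom the fit absorbs
  sigma <- 0.5
  ds <- lapply(41:46, function(sd) {
    b <- buildSandwich(sandwichSpec(seed = sd, noiseSigma = sigma))
    list(structure = b$structure, annotation = truthAnnotation(b))
  })
  names(ds) <- paste0("r", 1:6)
  ov <- overlayRmsd(ds)
  expected <- sqrt(6 * sigma^2) * sqrt(1 - 6 / (3 * 64))
  expect_equal(ov$mean, expected, tolerance = 0.15)
})
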