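test_that("a generated sandwich yields exactly one candidate with all 8 strands", {
  b <- cachedSandwich(seed = 7L)
  tp <- assignStrands(buildHBondGraph(b$structure), b$structure)
  cands <- detectC2Domains(tp, b$structure)
  expect_length(cands, 1L)
  expect_equal(sort(cands[[1]]), 1:8)
})

test_that("a seven-strand sheet produces no candidate", {
  b <- cachedSandwich(seed = 8L, nStrands = 7L)
  tp <- assignStrands(buildHBondGraph(b$structure), b$structure)
  expect_length(detectC2Domains(tp, b$structure), 0L)
})

test_that("two sandwiches on one chain give two candidates in order", {
  b1 <- cachedSandwich(seed = 9L)
  b2 <- cachedSandwich(seed = 10L, connectivity = 0L)
  a2 <- b2$structure@atoms
  shift <- max(b1$structure@atoms$resno) + 20L
  a2$resno <- a2$resno + shift
  a2$x <- a2$x + 80
  s <- b1$structure
  s@atoms <- rbind(s@atoms, a2)
  tp <- assignStrands(buildHBondGraph(s), s)
  cands <- detectC2Domains(tp, s)
  expect_length(cands, 2L)
  st <- tp@strands
  expect_lt(max(st$last[st$index %in% cands[[1]]]), shift)
  expect_gt(min(st$first[st$index %in% cands[[2]]]), shift)
  ## and they classify independently
  expect_equal(classifyTopology(cands[[1]], tp), "Type-II")
  expect_equal(classifyTopology(cands[[2]], tp), "Type-I")
})

test_that("topology classification matches the construction offset", {
  for (seed in 11:13) for (off in 0:1) {
    ann <- cachedAnnotated(seed = seed, connectivity = off)$annotation
    expect_equal(ann@topology, c("Type-I", "Type-II")[off + 1L])
  }
})

test_that("classification flips under a single-step circular permutation", {
  ## template-level check, independent of geometry: feed the classifier a
  ## pairing graph built from each template and from unrelated pairings
  for (off in 0:1) {
    tpl <- topologyTemplate(off)
    tp <- new("SheetTopology",
              strands = data.frame(chain = "A", first = seq(1, 148, by = 20),
                                   last = seq(8, 155, by = 20), index = 1:8),
              pairings = cbind(tpl, orientation = "antiparallel"),
              sheets = list(1:8))
    expect_equal(classifyTopology(1:8, tp), c("Type-I", "Type-II")[off + 1L])
  }
  ## a graph matching both templates equally is ambiguous
  amb <- data.frame(i = 1:4, j = 5:8)
  tpAmb <- new("SheetTopology",
               strands = data.frame(chain = "A", first = seq(1, 148, by = 20),
                                    last = seq(8, 155, by = 20), index = 1:8),
               pairings = cbind(amb, orientation = "antiparallel"),
               sheets = list(1:8))
  expect_equal(classifyTopology(1:8, tpAmb), "ambiguous")
})

test_that("boundaries follow the hydrogen-bond rule exactly", {
  for (off in 0:1) {
    x <- cachedAnnotated(seed = 14L, connectivity = off)
    expect_equal(x$annotation@boundaries, x$truth$boundaries)
  }
})

test_that("a frayed terminal residue is excluded from the boundary", {
  b <- buildSandwich(sandwichSpec(seed = 15L, noiseSigma = 0))
  s <- b$structure
  lastRes <- b$truth$strands$last[8]
  ## displace the backbone of strand 8's terminal residue: the C-alpha keeps
  ## roughly strand-like geometry but every hydrogen bond is broken
  sel <- s@atoms$resno == lastRes & s@atoms$elety %in% c("N", "C", "O", "H")
  s@atoms$y[sel] <- s@atoms$y[sel] + 6
  ann <- annotateC2(s)
  expect_length(ann, 1L)
  expect_equal(ann[[1]]@boundaries[2], lastRes - 1L)
  expect_equal(ann[[1]]@boundaries[1], b$truth$boundaries[1])
})

test_that("loop naming matches ground truth and loop1 sits on b1-2 for Type-II", {
  x <- cachedAnnotated(seed = 7L)
  ann <- x$annotation
  expect_equal(ann@apexLoops, x$truth$apexLoops)
  expect_equal(ann@apexLoops[1], "b1-2")
  expect_equal(loopInterval(ann, "loop1"), loopInterval(ann, "b1-2"))
  ## loops are the exact complement of the strands inside the boundaries
  covered <- sort(c(
    unlist(mapply(seq, ann@strands$first, ann@strands$last)),
    unlist(lapply(ann@loops, function(iv) if (iv[1] <= iv[2]) iv[1]:iv[2]))))
  expect_equal(unname(covered), ann@boundaries[1]:ann@boundaries[2])
})

test_that("abutting strands produce an empty loop interval", {
  x <- cachedAnnotated(seed = 7L)
  tp <- assignStrands(buildHBondGraph(x$structure), x$structure)
  st <- tp@strands
  ## force strand 2 to abut strand 1 (interval arithmetic check)
  st$first[2] <- st$last[1] + 1L
  tp2 <- new("SheetTopology", strands = st, pairings = tp@pairings,
             sheets = tp@sheets)
  ll <- labelLoops(1:8, tp2, x$structure)
  iv <- ll$loops[["b1-2"]]
  expect_equal(iv[2] - iv[1] + 1L, 0L)
})

test_that("annotation is invariant under rigid rotation of the model", {
  x <- cachedAnnotated(seed = 16L)
  set.seed(99)
  rot <- rotateStructure(x$structure)
  ann <- annotateC2(rot)
  expect_length(ann, 1L)
  expect_equal(ann[[1]]@boundaries, x$annotation@boundaries)
  expect_equal(ann[[1]]@topology, x$annotation@topology)
  expect_equal(ann[[1]]@loops, x$annotation@loops)
  expect_equal(ann[[1]]@apexLoops, x$annotation@apexLoops)
})

test_that("domain span sits at the canonical C2 scale", {
  x <- cachedAnnotated(seed = 7L)
  span <- diff(x$annotation@boundaries) + 1L
  expect_gte(span, 110L)
  expect_lte(span, 150L)
})
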