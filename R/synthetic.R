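## Synthetic beta-sandwich generator.
##
## Geometry is an idealized flat beta-lattice: strands run along +-z with a
## rise of 3.3 A per residue, C-alpha pleat +-0.94 A out of the H-bond plane
## (consecutive CA-CA = 3.8 A), carbonyls and amides alternating along the
## +-x H-bond axis, strand spacing 4.13 A within a sheet and 10.5 A between
## the two sheets of a sandwich. With the Kabsch-Sander model this lattice
## yields inter-strand N-H...O=C energies near -2.9 kcal/mol, comfortably
## below the -0.5 kcal/mol assignment cutoff, so every pipeline stage can be
## exercised against known ground truth without any external model.

.RISE <- 3.3        # A per residue along the strand axis
.PLEAT <- 0.94      # CA out-of-plane displacement; gives CA-CA 3.8 A
.ZOFF <- 1.25       # N/C offset from CA along the strand axis
.ODISP <- 1.23      # carbonyl O displacement along the H-bond axis
.WSTRAND <- 4.13    # strand spacing within a sheet (gives r_ON = 2.90 A)
.WSHEET <- 10.5     # spacing between the two sheets of the sandwich
.CACA <- 3.8        # target CA-CA spacing in loops

## Canonical C2 slot arrangement (Type-I): spatial order of sequence strands
## across the two four-stranded sheets. The Type-II arrangement is the
## single-step circular permutation of this table. Encoded as data so the
## topology templates used by the classifier derive from the same source.
.C2_SHEET_A <- c(4L, 1L, 8L, 5L)
.C2_SHEET_B <- c(3L, 2L, 7L, 6L)

#' Topology template for an 8-strand C2 sandwich
#'
#' Returns the strand-pairing adjacency (unordered pairs of sequence-ordered
#' strand indices) for the canonical C2 arrangement at a given circular
#' permutation offset: 0 is Type-I, 1 is Type-II.
#'
#' @param offset integer, 0 or 1.
#' @return data.frame with columns \code{i}, \code{j} (i < j).
#' @export
topologyTemplate <- function(offset = 0L) {
  stopifnot(offset %in% c(0L, 1L))
  perm <- function(q) ((q - 1L - offset) %% 8L) + 1L  # slot of TypeI strand q holds this sequence strand
  prs <- list()
  for (sheet in list(.C2_SHEET_A, .C2_SHEET_B))
    for (k in seq_len(length(sheet) - 1L))
      prs[[length(prs) + 1L]] <- sort(c(perm(sheet[k]), perm(sheet[k + 1L])))
  out <- unique(do.call(rbind, prs))
  data.frame(i = out[, 1L], j = out[, 2L])
}

## Run expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic beta-sandwich
#'
#' Defaults emulate a canonical ferlin-like C2 domain: eight 8-residue
#' strands around the Greek-key slot arrangement with Type-II connectivity,
#' nine-residue inter-strand loops (giving a ~127-residue domain span) and
#' 0.1 A isotropic coordinate noise.
#'
#' @param nStrands number of strands; 8 builds a C2 sandwich, other values a
#'   single-sheet ribbon (used for hairpin and negative-control fixtures).
#' @param strandLen residues per strand.
#' @param connectivity circular-permutation offset: 0 = Type-I, 1 = Type-II.
#' @param loopLengths named integer vector overriding per-loop lengths
#'   (names "b1-2" ... "b7-8"); unnamed scalar sets all loops.
#' @param insertions named list, per loop name a
#'   \code{list(length =, ssClass = "helix-rich"|"coil")} insertion.
#' @param noiseSigma Gaussian coordinate noise, Angstrom.
#' @param seed integer seed fixing all randomness.
#' @param nTail unstructured residues before strand 1 and after the last strand.
#' @param pocketAcidic place Asp at the six pocket reference slots.
#' @return a \linkS4class{SandwichSpec}.
#' @export
sandwichSpec <- function(nStrands = 8L, strandLen = 8L, connectivity = 1L,
                         loopLengths = 9L, insertions = list(),
                         noiseSigma = 0.1, seed = 1L, nTail = 3L,
                         pocketAcidic = TRUE) {
  nStrands <- as.integer(nStrands)
  loopNames <- if (nStrands > 1L)
    sprintf("b%d-%d", seq_len(nStrands - 1L), seq_len(nStrands - 1L) + 1L)
  else character()
  ll <- setNames(rep(as.integer(loopLengths)[1L], length(loopNames)), loopNames)
  if (!is.null(names(loopLengths))) {
    bad <- setdiff(names(loopLengths), loopNames)
    if (length(bad)) .c2Stop("c2SpecError", paste("unknown loop:", bad[1L]))
    ll[names(loopLengths)] <- as.integer(loopLengths)
  }
  if (length(insertions)) {
    bad <- setdiff(names(insertions), loopNames)
    if (length(bad)) .c2Stop("c2SpecError", paste("unknown insertion loop:", bad[1L]))
  }
  new("SandwichSpec", nStrands = nStrands, strandLen = as.integer(strandLen),
      connectivity = as.integer(connectivity), loopLengths = ll,
      insertions = insertions, noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed), nTail = as.integer(nTail),
      pocketAcidic = isTRUE(pocketAcidic))
}

## One lattice residue. x0/y0 position the strand, t is the global lattice
## index (z = 3.3 t), dirSign the chain direction along z, d = +-1 the side
## the amide/carbonyl of this residue points to along x.
.latticeResidue <- function(x0, y0, t, dirSign, d) {
  z <- .RISE * t
  list(N = c(x0, y0, z - .ZOFF * dirSign),
       CA = c(x0, y0 + .PLEAT * d, z),
       C = c(x0, y0, z + .ZOFF * dirSign),
       O = c(x0 + .ODISP * d, y0, z + .ZOFF * dirSign))
}

#' Ideal extended beta-strand backbone
#'
#' Builds an n-residue extended strand with the generator's lattice geometry:
#' rise 3.3 A per residue, alternating pleat (consecutive CA-CA of 3.8 A) and
#' alternating amide/carbonyl orientation.
#'
#' @param n residues (>= 2).
#' @param origin 3-vector, position of the first residue's lattice point.
#' @param direction 3-vector, strand axis (normalized internally).
#' @param side 3-vector, the H-bond axis (defaults to a vector orthogonal to
#'   \code{direction}).
#' @param parityPhase 0 or 1, flips which residues point along +side.
#' @return list of per-residue lists with named 3-vectors N, CA, C, O.
#' @export
buildStrand <- function(n, origin = c(0, 0, 0), direction = c(0, 0, 1),
                        side = NULL, parityPhase = 0L) {
  stopifnot(n >= 2L)
  zhat <- .vunit(direction)
  if (is.null(side)) {
    ref <- if (abs(zhat[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    side <- .vunit(ref - sum(ref * zhat) * zhat)
  }
  xhat <- .vunit(side - sum(side * zhat) * zhat)
  yhat <- c(zhat[2L] * xhat[3L] - zhat[3L] * xhat[2L],
            zhat[3L] * xhat[1L] - zhat[1L] * xhat[3L],
            zhat[1L] * xhat[2L] - zhat[2L] * xhat[1L])
  lapply(seq_len(n) - 1L, function(k) {
    d <- (-1)^((k + parityPhase) %% 2L)
    z <- .RISE * k
    list(N = origin + zhat * (z - .ZOFF) + 0 * xhat,
         CA = origin + zhat * z + yhat * (.PLEAT * d),
         C = origin + zhat * (z + .ZOFF),
         O = origin + zhat * (z + .ZOFF) + xhat * (.ODISP * d))
  })
}

## Cubic Bezier with outward bulge scaled so the arc length fits n interior
## residues at 3.8 A spacing; returns the n interior CA positions.
.loopArc <- function(E0, E1, out, n, lateral = NULL) {
  need <- (n + 1) * .CACA
  chord <- .vnorm(E1 - E0)
  if (chord > need)
    .c2Stop("c2SpecError", sprintf(
      "infeasible loop: %d residues cannot span %.1f A", n, chord))
  if (is.null(lateral)) lateral <- c(0, 0, 0)
  bez <- function(h) {
    P0 <- E0; P3 <- E1
    P1 <- E0 + out * h + (E1 - E0) * 0.25 + lateral * (h * 0.35)
    P2 <- E1 + out * h - (E1 - E0) * 0.25 - lateral * (h * 0.35)
    tt <- seq(0, 1, length.out = 400L)
    b <- outer((1 - tt)^3, P0) + outer(3 * (1 - tt)^2 * tt, P1) +
         outer(3 * (1 - tt) * tt^2, P2) + outer(tt^3, P3)
    b
  }
  arclen <- function(b) sum(sqrt(rowSums(diff(b)^2)))
  lo <- 0; hi <- need
  bhi <- bez(hi)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (arclen(bez(mid)) < need) lo <- mid else hi <- mid
  }
  b <- bez((lo + hi) / 2)
  cs <- c(0, cumsum(sqrt(rowSums(diff(b)^2))))
  total <- cs[length(cs)]
  want <- total * seq_len(n) / (n + 1)
  idx <- findInterval(want, cs, all.inside = TRUE)
  frac <- (want - cs[idx]) / pmax(cs[idx + 1L] - cs[idx], 1e-12)
  b[idx, , drop = FALSE] + (b[idx + 1L, , drop = FALSE] - b[idx, , drop = FALSE]) * frac
}

## Backbone atoms for coil CA traces: N/C along the local tangent. The
## carbonyl direction is randomized (seeded, around the local tangent) the
## way irregular coil dihedrals scatter carbonyls in real chains; regular
## parallel carbonyls at 3.8 A spacing would mimic beta-strand geometry and
## let two nearby coils form spurious ladders. The two residues at each end
## of a coil segment (the strand junctions) keep a deterministic outward
## carbonyl so they cannot act as stray acceptors for the sheet edge.
.coilAtoms <- function(ca, out) {
  n <- nrow(ca)
  res <- vector("list", n)
  ang <- stats::runif(n, 0, 2 * pi)
  ang[c(1L, 2L, n - 1L, n)[c(1L, 2L, n - 1L, n) >= 1L]] <- 0
  for (i in seq_len(n)) {
    p <- ca[max(1L, i - 1L), ]; q <- ca[min(n, i + 1L), ]
    th <- q - p
    th <- if (.vnorm(th) < 1e-8) .vunit(c(out[3L], 0, -out[1L]) + 1e-3) else .vunit(th)
    u <- .vunit(out) - sum(.vunit(out) * th) * th
    u <- if (.vnorm(u) < 1e-6) .vunit(c(th[3L], 0, -th[1L])) else .vunit(u)
    v <- c(th[2L] * u[3L] - th[3L] * u[2L],
           th[3L] * u[1L] - th[1L] * u[3L],
           th[1L] * u[2L] - th[2L] * u[1L])
    odir <- cos(ang[i]) * u + sin(ang[i]) * v
    res[[i]] <- list(N = ca[i, ] - th * .ZOFF, CA = ca[i, ],
                     C = ca[i, ] + th * .ZOFF,
                     O = ca[i, ] + th * .ZOFF + odir * .ODISP)
  }
  res
}

## Ideal alpha-helix: CA on a 2.3 A radius, 1.5 A rise, 100 deg/residue.
## Carbonyls point at the (virtual) amide nitrogen four residues on, which
## reproduces the i -> i+4 hydrogen-bond pattern under the Kabsch-Sander
## model with the package's amide-hydrogen placement rule.
.helixAtoms <- function(k, start, axis, uhat) {
  axis <- .vunit(axis)
  uhat <- .vunit(uhat - sum(uhat * axis) * axis)
  vhat <- c(axis[2L] * uhat[3L] - axis[3L] * uhat[2L],
            axis[3L] * uhat[1L] - axis[1L] * uhat[3L],
            axis[1L] * uhat[2L] - axis[2L] * uhat[1L])
  caAt <- function(i) start + axis * (1.5 * i) +
    uhat * (2.3 * cos(i * 100 * pi / 180)) + vhat * (2.3 * sin(i * 100 * pi / 180))
  nAt <- function(i) caAt(i) + 0.33 * (caAt(i - 1) - caAt(i))
  res <- vector("list", k)
  for (i in seq_len(k) - 1L) {
    CA <- caAt(i)
    N <- nAt(i)
    C <- CA + 0.33 * (caAt(i + 1) - CA)
    O <- C + .ODISP * .vunit(nAt(i + 4) - C)
    res[[i + 1L]] <- list(N = N, CA = CA, C = C, O = O)
  }
  res
}

## Slot table for the sandwich (n == 8) or single-sheet ribbon (other n).
.slotTable <- function(nStrands, connectivity) {
  if (nStrands == 8L) {
    slots <- rbind(
      data.frame(typeI = .C2_SHEET_A, sheet = "A", xi = seq_along(.C2_SHEET_A) - 1L,
                 y0 = 0, dir = c(1, -1, 1, -1)),
      data.frame(typeI = .C2_SHEET_B, sheet = "B", xi = seq_along(.C2_SHEET_B) - 1L,
                 y0 = .WSHEET, dir = c(-1, 1, -1, 1)))
    ## sequence strand p occupies the slot of Type-I strand ((p-1+offset) %% 8)+1
    slots$strand <- ((slots$typeI - 1L - connectivity) %% 8L) + 1L
    slots
  } else {
    data.frame(typeI = seq_len(nStrands), sheet = "A", xi = seq_len(nStrands) - 1L,
               y0 = 0, dir = rep_len(c(1, -1), nStrands), strand = seq_len(nStrands))
  }
}

.STRAND_ALPHA <- c("V", "I", "L", "F", "Y", "T", "S", "A", "E", "K", "R", "Q")
.HELIX_ALPHA <- c("A", "L", "E", "K", "Q", "R", "M", "I")

#' Build a synthetic beta-sandwich with ground truth
#'
#' Assembles the structure described by a \linkS4class{SandwichSpec} and
#' returns it together with the construction ground truth (strand intervals,
#' pairings, sheets, topology type, boundary interval, loop intervals,
#' insertion records, pocket slots and the full sequence). Randomness
#' (sequence sampling, coordinate noise) is fully determined by the spec seed.
#'
#' @param spec a \linkS4class{SandwichSpec}.
#' @return list with elements \code{structure} (ProteinStructure) and
#'   \code{truth} (list).
#' @export
buildSandwich <- function(spec) {
  stopifnot(is(spec, "SandwichSpec"))
  validObject(spec)
  ns <- spec@nStrands; L <- spec@strandLen
  slots <- .slotTable(ns, spec@connectivity)
  slots <- slots[order(slots$strand), , drop = FALSE]
  loopNames <- names(spec@loopLengths)

  ## per-strand lattice geometry
  strandGeom <- function(p) {
    s <- slots[slots$strand == p, , drop = FALSE]
    x0 <- .WSTRAND * s$xi; y0 <- s$y0; dir <- s$dir
    tIdx <- if (dir > 0) seq_len(L) - 1L else rev(seq_len(L) - 1L)
    lapply(seq_len(L), function(k) {
      t <- tIdx[k]
      d <- (-1)^((s$xi + t) %% 2L)
      .latticeResidue(x0, y0, t, dir, d)
    })
  }
  lastCA <- function(p) strandGeom(p)[[L]]$CA
  firstCA <- function(p) strandGeom(p)[[1L]]$CA
  outDir <- function(p) {        # outward normal at the loop after strand p
    s <- slots[slots$strand == p, , drop = FALSE]
    if (s$dir > 0) c(0, 0, 1) else c(0, 0, -1)
  }

  .withSeed(spec@seed, {
    resAtoms <- list(); resAA <- character(); segments <- list()
    addResidues <- function(atomList, aa, segName) {
      start <- length(resAtoms) + 1L
      for (i in seq_along(atomList)) resAtoms[[length(resAtoms) + 1L]] <<- atomList[[i]]
      resAA <<- c(resAA, aa)
      segments[[length(segments) + 1L]] <<- list(name = segName,
        first = start, last = length(resAtoms))
    }
    sampleAA <- function(n, alpha) sample(alpha, n, replace = TRUE)

    ## N-tail: coil walking away from the start of strand 1, angled off the
    ## strand axis and away from the sandwich so it cannot extend the sheet
    awayY <- function(p) if (slots$y0[slots$strand == p] > .WSHEET / 2) 1 else -1
    awayX <- function(p) {
      xs <- .WSTRAND * slots$xi[slots$strand == p]
      if (xs >= .WSTRAND * 1.5) 1 else -1
    }
    if (spec@nTail > 0L) {
      u <- .vunit(-outDir(1L) * 0.4 + c(0.35 * awayX(1L), 1.6 * awayY(1L), 0))
      ca <- t(vapply(seq_len(spec@nTail), function(k)
        firstCA(1L) + (.CACA * k) * u, numeric(3)))
      ca <- ca[rev(seq_len(nrow(ca))), , drop = FALSE]  # N-term first
      addResidues(.coilAtoms(ca, c(0.3, -1, 0)), rep("P", spec@nTail), "tailN")
    }

    insRecords <- list()
    for (p in seq_len(ns)) {
      addResidues(strandGeom(p), sampleAA(L, .STRAND_ALPHA), sprintf("strand%d", p))
      if (p < ns) {
        ln <- sprintf("b%d-%d", p, p + 1L)
        nBase <- spec@loopLengths[[ln]]
        E0 <- lastCA(p); E1 <- firstCA(p + 1L)
        ## per-loop tilt of the bulge plane: every loop lifts off the sheet
        ## plane with its own out-of-plane angle (alternating side, growing
        ## magnitude), so loops on the same face of the sandwich arc through
        ## distinct planes and stay clear of the strand lattice near their
        ## anchors
        out <- .vunit(outDir(p) + c(0, (0.45 + 0.1 * p) * (-1)^p, 0))
        ## distinct lateral excursion per loop so neighbouring arcs on the
        ## same face of the sandwich stay apart
        lat <- .vunit(c(0.9 * cos(1.9 * p), if (E0[2L] > .WSHEET / 2) 1 else -1, 0))
        ins <- spec@insertions[[ln]]
        if (is.null(ins)) {
          ca <- .loopArc(E0, E1, out, nBase, lateral = lat)
          ## coil residues are proline: never hydrogen-bond donors, mirroring
          ## the proline-rich character of real inter-domain linkers and
          ## guaranteeing that coils cannot complete beta-bridge patterns
          addResidues(.coilAtoms(ca, out), rep("P", nBase), ln)
        } else {
          nIns <- as.integer(ins$length)
          ssClass <- if (is.null(ins$ssClass)) "helix-rich" else ins$ssClass
          if (identical(ssClass, "coil")) {
            ca <- .loopArc(E0, E1, out, nBase + nIns, lateral = lat)
            atoms <- .coilAtoms(ca, out)
            aa <- rep("P", nBase + nIns)
            start <- length(resAtoms) + 1L
            addResidues(atoms, aa, ln)
            insFirst <- start + ceiling(nBase / 2)
            insRecords[[length(insRecords) + 1L]] <- list(loop = ln, length = nIns,
              ssClass = "coil", first = insFirst, last = insFirst + nIns - 1L)
          } else {
            pad <- max(2L, ceiling(nIns / 6))
            kHel <- nIns - 2L * pad
            if (kHel < 5L) { pad <- max(0L, (nIns - 5L) %/% 2L); kHel <- nIns - 2L * pad }
            m1 <- ceiling(nBase / 2); m2 <- nBase - m1
            mid <- (E0 + E1) / 2
            axis <- .vunit(c(1, 0, 0) + lat * 0.2)
            hStart <- mid + out * 9 - axis * (1.5 * kHel / 2)
            hel <- .helixAtoms(kHel, hStart, axis, out)
            helFirstCA <- hel[[1L]]$CA; helLastCA <- hel[[kHel]]$CA
            ca1 <- .loopArc(E0, helFirstCA, out, m1 + pad, lateral = lat)
            ca2 <- .loopArc(helLastCA, E1, out, m2 + pad, lateral = -lat)
            atoms <- c(.coilAtoms(ca1, out), hel, .coilAtoms(ca2, out))
            aa <- c(rep("P", m1 + pad), sampleAA(kHel, .HELIX_ALPHA),
                    rep("P", m2 + pad))
            start <- length(resAtoms) + 1L
            addResidues(atoms, aa, ln)
            insFirst <- start + m1
            insRecords[[length(insRecords) + 1L]] <- list(loop = ln, length = nIns,
              ssClass = "helix-rich", first = insFirst, last = insFirst + nIns - 1L)
          }
        }
      }
    }

    ## C-tail
    if (spec@nTail > 0L) {
      u <- .vunit(outDir(ns) * 0.4 + c(0.35 * awayX(ns), 1.6 * awayY(ns), 0))
      ca <- t(vapply(seq_len(spec@nTail), function(k)
        lastCA(ns) + (.CACA * k) * u, numeric(3)))
      addResidues(.coilAtoms(ca, c(-0.3, -1, 0)), rep("P", spec@nTail), "tailC")
    }

    segName <- vapply(segments, `[[`, character(1), "name")
    segFirst <- vapply(segments, `[[`, integer(1), "first")
    segLast <- vapply(segments, `[[`, integer(1), "last")
    seg <- function(nm) c(segFirst[segName == nm], segLast[segName == nm])

    ## strand-first residues carry an explicit amide hydrogen on the lattice
    ## H-bond axis: hydrogen placement from the preceding (coil) carbonyl
    ## would point their N-H away from the partner strand, which no real
    ## sheet edge does; explicitly placed hydrogens are retained by
    ## placeAmideHydrogens
    for (p in seq_len(ns)) {
      f <- seg(sprintf("strand%d", p))[1L]
      sl <- slots[slots$strand == p, , drop = FALSE]
      tStart <- if (sl$dir > 0) 0L else L - 1L
      d <- (-1)^((sl$xi + tStart) %% 2L)
      r1 <- resAtoms[[f]]
      r1$H <- r1$N + c(d, 0, 0)
      resAtoms[[f]] <- r1
    }

    ## pocket slots: two central residues of each of the three apex loops
    pocket <- integer()
    if (ns == 8L) {
      for (ln in c("b1-2", "b3-4", "b5-6")) {
        iv <- seg(ln)
        m <- floor(mean(iv))
        pocket <- c(pocket, m, m + 1L)
      }
      if (spec@pocketAcidic) resAA[pocket] <- "D"
    }

    ## assemble atom table (+ seeded noise)
    rows <- vector("list", length(resAtoms))
    for (i in seq_along(resAtoms)) {
      at <- resAtoms[[i]]
      rows[[i]] <- data.frame(chain = "A", resno = i, ins = "", aa = resAA[i],
        elety = names(at),
        x = vapply(at, `[[`, numeric(1), 1L),
        y = vapply(at, `[[`, numeric(1), 2L),
        z = vapply(at, `[[`, numeric(1), 3L),
        occ = 1, stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    rownames(atoms) <- NULL
    ## Coordinate noise is a smooth per-residue rigid displacement field:
    ## each residue moves as a unit and neighbouring residues move together
    ## (moving average of iid Gaussians over a 5-residue window, scaled so
    ## the marginal per-residue std equals noiseSigma). This emulates model
    ## error in predicted structures, which is correlated at and below the
    ## residue scale; independent atomic noise would corrupt covalent
    ## geometry (C=O bond lengths, CA-CA distances) in a way no model does.
    if (spec@noiseSigma > 0) {
      k <- 5L; nres <- length(resAtoms)
      e <- matrix(stats::rnorm(3L * (nres + k - 1L),
                               sd = spec@noiseSigma * sqrt(k)), ncol = 3L)
      shift <- apply(e, 2L, function(v)
        as.numeric(stats::filter(v, rep(1 / k, k), sides = 1L))[k:(nres + k - 1L)])
      atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
        shift[atoms$resno, ]
    }

    strandsDf <- do.call(rbind, lapply(seq_len(ns), function(p) {
      iv <- seg(sprintf("strand%d", p))
      data.frame(chain = "A", first = iv[1L], last = iv[2L], index = p)
    }))
    loopsTruth <- setNames(lapply(loopNames, seg), loopNames)
    pairTpl <- if (ns == 8L) topologyTemplate(spec@connectivity) else {
      if (ns >= 2L) data.frame(i = seq_len(ns - 1L), j = seq_len(ns - 1L) + 1L)
      else data.frame(i = integer(), j = integer())
    }
    truth <- list(
      strands = strandsDf,
      pairings = cbind(pairTpl, orientation = "antiparallel"),
      sheets = if (ns == 8L) {
        perm <- function(q) ((q - 1L - spec@connectivity) %% 8L) + 1L
        list(sort(perm(.C2_SHEET_A)), sort(perm(.C2_SHEET_B)))
      } else list(seq_len(ns)),
      topology = if (ns == 8L) c("Type-I", "Type-II")[spec@connectivity + 1L] else NA_character_,
      boundaries = c(strandsDf$first[1L], strandsDf$last[ns]),
      loops = loopsTruth,
      apexLoops = if (ns == 8L) c("b1-2", "b3-4", "b5-6") else character(),
      insertions = insRecords,
      pocketPositions = pocket,
      sequence = paste(resAA, collapse = ""))
    list(structure = new("ProteinStructure",
                         id = sprintf("sandwich-seed%d", spec@seed), atoms = atoms,
                         hetero = data.frame()),
         truth = truth)
  })
}

#' Canonical reference C2 domain (synthetic)
#'
#' A generator-built canonical Type-II C2 model used as the default reference
#' for insertion detection and the calcium-pocket census. It is synthetic:
#' an idealized, noise-free sandwich with the canonical loop lengths and
#' aspartates at the six pocket slots, standing in for an experimental
#' reference structure.
#'
#' @return list with \code{structure}, \code{truth} and \code{annotation}.
#'   The annotation carries the construction register (strand and loop
#'   intervals from the ground truth): a reference is a calibrated object,
#'   so its own register is known exactly rather than re-detected, keeping
#'   edge-strand fraying out of every loop-length comparison made against
#'   it.
#' @export
referenceC2 <- function() {
  built <- buildSandwich(sandwichSpec(seed = 20L, noiseSigma = 0))
  list(structure = built$structure, truth = built$truth,
       annotation = truthAnnotation(built))
}

#' Split a chain into overlapping fragments
#'
#' Emulates the overlapping-fragment modelling regime: the chain is cut at
#' the given residue numbers and consecutive fragments share exactly
#' \code{overlap} residues. Each fragment after the first can be re-posed by
#' a random (seeded) rigid motion, which \code{stitchFragments} must undo.
#'
#' @param x a ProteinStructure (single chain).
#' @param cutPoints interior residue numbers where fragments start.
#' @param overlap shared residues between consecutive fragments (>= 1).
#' @param rigid re-pose fragments by random rigid motions.
#' @param seed integer seed for the rigid motions.
#' @return list of ProteinStructure fragments.
#' @export
splitWithOverlap <- function(x, cutPoints, overlap, rigid = TRUE, seed = 1L) {
  ch <- chains(x)[1L]
  rn <- residueNumbers(x, ch)
  overlap <- as.integer(overlap)
  if (overlap < 1L) .c2Stop("c2SpecError", "overlap must be >= 1")
  cutPoints <- sort(as.integer(cutPoints))
  if (any(cutPoints <= min(rn)) || any(cutPoints >= max(rn)))
    .c2Stop("c2SpecError", "cut points must be interior residue numbers")
  starts <- c(min(rn), cutPoints)
  ends <- c(cutPoints + overlap - 1L, max(rn))
  if (any(ends - starts + 1L <= overlap))
    .c2Stop("c2SpecError", "overlap must be smaller than every fragment")
  frags <- .withSeed(seed, lapply(seq_along(starts), function(i) {
    f <- extractRegion(x, ch, starts[i], ends[i])
    f@id <- sprintf("%s-frag%d", x@id, i)
    if (rigid && i > 1L) {
      R <- .randomRotation()
      tr <- stats::runif(3L, -20, 20)
      m <- as.matrix(f@atoms[, c("x", "y", "z")])
      m <- m %*% t(R)
      f@atoms$x <- m[, 1L] + tr[1L]
      f@atoms$y <- m[, 2L] + tr[2L]
      f@atoms$z <- m[, 3L] + tr[3L]
    }
    f
  }))
  frags
}

## Uniform random rotation matrix (via QR of a Gaussian matrix).
.randomRotation <- function() {
  q <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

#' Ideal all-helix chain
#'
#' A single ideal alpha-helix (rise 1.5 A, 100 degrees per residue) with a
#' seeded sequence; used as a strand-free negative control.
#'
#' @param n residues.
#' @param seed integer seed for the sequence.
#' @return a ProteinStructure.
#' @export
helixChain <- function(n = 30L, seed = 1L) {
  atomsList <- .helixAtoms(n, c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  aa <- .withSeed(seed, sample(.HELIX_ALPHA, n, replace = TRUE))
  rows <- lapply(seq_len(n), function(i) {
    at <- atomsList[[i]]
    data.frame(chain = "A", resno = i, ins = "", aa = aa[i], elety = names(at),
               x = vapply(at, `[[`, numeric(1), 1L),
               y = vapply(at, `[[`, numeric(1), 2L),
               z = vapply(at, `[[`, numeric(1), 3L), occ = 1,
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  new("ProteinStructure", id = "helix", atoms = atoms, hetero = data.frame())
}

#' C2Annotation from generator ground truth
#'
#' Converts the construction ground truth of \code{\link{buildSandwich}} into
#' a \linkS4class{C2Annotation}, bypassing detection. Used to validate the
#' comparison operators against known register independent of the detection
#' stages.
#'
#' @param built list returned by \code{buildSandwich} (8-strand spec).
#' @return a \linkS4class{C2Annotation}.
#' @export
truthAnnotation <- function(built) {
  tr <- built$truth
  stopifnot(nrow(tr$strands) == 8L)
  st <- tr$strands[, c("first", "last", "index")]
  new("C2Annotation", chain = tr$strands$chain[1L], strands = st,
      boundaries = as.integer(tr$boundaries), topology = tr$topology,
      loops = lapply(tr$loops, as.integer), apexLoops = tr$apexLoops,
      subdomains = data.frame(), pocket = list())
}
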