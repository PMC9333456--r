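## Backbone hydrogen-bond assignment (Kabsch-Sander electrostatic model) and
## beta-bridge/ladder/strand logic. Only what C2 recognition needs is
## assigned: strands ('E'), a minimal 4-turn helix ('H') used to classify
## insertion secondary structure, and coil ('-').

.KS_CONST <- 0.084 * 332  # q1*q2*f, kcal/mol * A
.HBOND_CUTOFF <- -0.5     # kcal/mol, DSSP convention
.MIN_STRAND_LEN <- 3L
.BULGE_GAP <- 1L
.CHAIN_BREAK <- 4.5       # A between consecutive CA

#' Place amide hydrogens on backbone nitrogens
#'
#' Each non-proline residue with a preceding peptide bond gains an H atom at
#' \code{N + unit(C_prev - O_prev) * 1.0} Angstrom, i.e. the N-H bond is
#' placed anti-parallel to the preceding carbonyl (the standard preprocessing
#' for Kabsch-Sander energies on structures without experimental hydrogens).
#' Existing amide hydrogens are kept. Residues with incomplete backbones are
#' skipped with a message.
#'
#' @param x a ProteinStructure.
#' @return a ProteinStructure with H atoms added.
#' @export
placeAmideHydrogens <- function(x) {
  out <- list()
  for (ch in chains(x)) {
    a <- x@atoms[x@atoms$chain == ch, , drop = FALSE]
    rn <- unique(a$resno)
    hasH <- rn[rn %in% a$resno[a$elety == "H"]]
    skipped <- 0L
    newRows <- list()
    for (k in seq_along(rn)[-1L]) {
      i <- rn[k]; p <- rn[k - 1L]
      ri <- a[a$resno == i, , drop = FALSE]
      aaI <- ri$aa[1L]
      if (aaI == "P" || i %in% hasH) next
      N <- ri[ri$elety == "N", c("x", "y", "z")]
      Cp <- a[a$resno == p & a$elety == "C", c("x", "y", "z")]
      Op <- a[a$resno == p & a$elety == "O", c("x", "y", "z")]
      if (nrow(N) != 1L || nrow(Cp) != 1L || nrow(Op) != 1L) { skipped <- skipped + 1L; next }
      h <- as.numeric(N) + .vunit(as.numeric(Cp) - as.numeric(Op))
      newRows[[length(newRows) + 1L]] <- data.frame(chain = ch, resno = i,
        ins = ri$ins[1L], aa = aaI, elety = "H", x = h[1L], y = h[2L], z = h[3L],
        occ = 1, stringsAsFactors = FALSE)
    }
    if (skipped > 0L)
      message(sprintf("chain %s: %d residue(s) with incomplete backbone skipped", ch, skipped))
    out[[ch]] <- if (length(newRows)) do.call(rbind, newRows) else NULL
  }
  add <- do.call(rbind, out)
  if (is.null(add) || nrow(add) == 0L) return(x)
  atoms <- rbind(x@atoms, add)
  ## restore residue order (atoms within a residue may appear in any order)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  atoms <- atoms[order(match(key, unique(paste(x@atoms$chain, x@atoms$resno,
                                               x@atoms$ins, sep = "\r")))), , drop = FALSE]
  rownames(atoms) <- NULL
  initialize(x, atoms = atoms)
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a putative backbone N-H...O=C bond,
#' \deqn{E = 0.084 \cdot 332 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' with distances in Angstrom and E in kcal/mol. Any inter-atom distance
#' below 0.5 A is treated as a clash and returns \code{NA} (no bond).
#'
#' @param donor named list of 3-vectors with at least \code{N} and \code{H}.
#' @param acceptor named list of 3-vectors with at least \code{C} and \code{O}.
#' @return energy in kcal/mol, or NA on clash / missing atoms.
#' @export
ksEnergy <- function(donor, acceptor) {
  if (is.null(donor$N) || is.null(donor$H) || is.null(acceptor$C) || is.null(acceptor$O))
    return(NA_real_)
  rON <- .vnorm(acceptor$O - donor$N)
  rCH <- .vnorm(acceptor$C - donor$H)
  rOH <- .vnorm(acceptor$O - donor$H)
  rCN <- .vnorm(acceptor$C - donor$N)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(NA_real_)
  .KS_CONST * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

#' Backbone atoms of one residue
#'
#' @param x a ProteinStructure.
#' @param chain chain id.
#' @param resno residue number.
#' @return named list of 3-vectors (one per atom present).
#' @export
residueAtoms <- function(x, chain, resno) {
  chain <- .firstChain(x, chain)
  a <- x@atoms[x@atoms$chain == chain & x@atoms$resno == resno, , drop = FALSE]
  setNames(lapply(seq_len(nrow(a)), function(i) as.numeric(a[i, c("x", "y", "z")])),
           a$elety)
}

## Internal: per-chain residue-level backbone coordinate matrices.
.backboneTables <- function(x) {
  lapply(setNames(nm = chains(x)), function(ch) {
    a <- x@atoms[x@atoms$chain == ch, , drop = FALSE]
    rn <- unique(a$resno)
    get1 <- function(el) {
      m <- matrix(NA_real_, length(rn), 3L)
      sel <- a[a$elety == el, , drop = FALSE]
      m[match(sel$resno, rn), ] <- as.matrix(sel[, c("x", "y", "z")])
      m
    }
    list(resno = rn, aa = a$aa[!duplicated(a$resno)],
         N = get1("N"), H = get1("H"), C = get1("C"), O = get1("O"), CA = get1("CA"))
  })
}

#' Build the backbone hydrogen-bond graph
#'
#' Scores every donor-acceptor pair with the Kabsch-Sander model and keeps
#' bonds with energy below the cutoff, excluding self pairs and sequence
#' neighbours (|i - j| < 2 within a chain). Per donor only the best two
#' acceptors are retained (the DSSP convention). The chain-first residue and
#' prolines are never donors (they carry no placed amide hydrogen); if the
#' structure has no hydrogens at all they are placed first.
#'
#' @param x a ProteinStructure.
#' @param cutoff assignment threshold in kcal/mol (default -0.5).
#' @return an \linkS4class{HBondGraph}.
#' @export
buildHBondGraph <- function(x, cutoff = .HBOND_CUTOFF) {
  x <- placeAmideHydrogens(x)  # idempotent: existing hydrogens are kept
  tabs <- .backboneTables(x)
  don <- list(); acc <- list()
  for (ch in names(tabs)) {
    tb <- tabs[[ch]]
    dOK <- !is.na(tb$N[, 1L]) & !is.na(tb$H[, 1L]) & tb$aa != "P"
    dOK[1L] <- FALSE  # the chain-first residue is never a donor
    aOK <- !is.na(tb$C[, 1L]) & !is.na(tb$O[, 1L])
    if (!any(dOK) || !any(aOK)) next
    don[[ch]] <- data.frame(chain = ch, resno = tb$resno[dOK],
      Nx = tb$N[dOK, 1L], Ny = tb$N[dOK, 2L], Nz = tb$N[dOK, 3L],
      Hx = tb$H[dOK, 1L], Hy = tb$H[dOK, 2L], Hz = tb$H[dOK, 3L])
    acc[[ch]] <- data.frame(chain = ch, resno = tb$resno[aOK],
      Cx = tb$C[aOK, 1L], Cy = tb$C[aOK, 2L], Cz = tb$C[aOK, 3L],
      Ox = tb$O[aOK, 1L], Oy = tb$O[aOK, 2L], Oz = tb$O[aOK, 3L])
  }
  D <- do.call(rbind, don); A <- do.call(rbind, acc)
  empty <- new("HBondGraph", cutoff = cutoff)
  if (is.null(D) || nrow(D) == 0L || is.null(A) || nrow(A) == 0L) return(empty)
  rON <- .crossDist(as.matrix(D[, c("Nx", "Ny", "Nz")]), as.matrix(A[, c("Ox", "Oy", "Oz")]))
  rCH <- .crossDist(as.matrix(D[, c("Hx", "Hy", "Hz")]), as.matrix(A[, c("Cx", "Cy", "Cz")]))
  rOH <- .crossDist(as.matrix(D[, c("Hx", "Hy", "Hz")]), as.matrix(A[, c("Ox", "Oy", "Oz")]))
  rCN <- .crossDist(as.matrix(D[, c("Nx", "Ny", "Nz")]), as.matrix(A[, c("Cx", "Cy", "Cz")]))
  E <- .KS_CONST * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[pmin(rON, rCH, rOH, rCN) < 0.5] <- NA  # clash -> no bond
  sameChain <- outer(D$chain, A$chain, "==")
  dSeq <- abs(outer(D$resno, A$resno, "-"))
  E[sameChain & dSeq < 2L] <- NA
  keep <- which(!is.na(E) & E < cutoff, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(empty)
  bonds <- data.frame(chain_d = D$chain[keep[, 1L]], donor = D$resno[keep[, 1L]],
                      chain_a = A$chain[keep[, 2L]], acceptor = A$resno[keep[, 2L]],
                      energy = E[keep])
  ## best two acceptors per donor
  bonds <- bonds[order(bonds$chain_d, bonds$donor, bonds$energy), , drop = FALSE]
  dkey <- paste(bonds$chain_d, bonds$donor)
  rank <- stats::ave(bonds$energy, dkey, FUN = seq_along)
  bonds <- bonds[rank <= 2, , drop = FALSE]
  rownames(bonds) <- NULL
  new("HBondGraph", bonds = bonds, cutoff = cutoff)
}

setMethod("show", "HBondGraph", function(object) {
  cat(sprintf("HBondGraph: %d bonds (cutoff %.2f kcal/mol)\n",
              nrow(object@bonds), object@cutoff))
})

#' Assign beta-strands, pairings and sheets
#'
#' Detects DSSP-style beta-bridges (parallel and antiparallel patterns) from
#' the hydrogen-bond graph, chains them into ladders, merges ladders across
#' single-residue beta-bulges, and reports runs of at least
#' \code{minStrandLen} residues as strands. Strand pairings carry the
#' majority bridge orientation and sheets are the connected components of
#' the pairing graph. Ladders are split at chain breaks
#' (consecutive CA-CA > 4.5 A).
#'
#' @param g an HBondGraph.
#' @param x the ProteinStructure the graph was built from.
#' @param minStrandLen minimum strand length in residues.
#' @param bulgeGap maximum bulge gap (residues on one strand) merged across.
#' @return a \linkS4class{SheetTopology}.
#' @export
assignStrands <- function(g, x, minStrandLen = .MIN_STRAND_LEN, bulgeGap = .BULGE_GAP) {
  emptyT <- new("SheetTopology")
  if (nrow(g@bonds) == 0L) return(emptyT)
  strandsAll <- list(); pairRows <- list(); idxBase <- 0L
  for (ch in chains(x)) {
    rn <- residueNumbers(x, ch)
    n <- length(rn)
    if (n < 3L) next
    pos <- match(seq(min(rn), max(rn)), rn)  # resno -> position lookup below
    b <- g@bonds[g@bonds$chain_d == ch & g@bonds$chain_a == ch, , drop = FALSE]
    if (nrow(b) == 0L) next
    hb <- matrix(FALSE, n, n)  # hb[a, d]: CO(a) ... HN(d)
    ai <- match(b$acceptor, rn); di <- match(b$donor, rn)
    hb[cbind(ai, di)] <- TRUE
    ## chain breaks between consecutive residues
    ca <- caCoords(x, ch)
    caM <- ca[match(rn, as.integer(rownames(ca))), , drop = FALSE]
    brk <- c(FALSE, sqrt(rowSums((caM[-1L, , drop = FALSE] -
                                  caM[-n, , drop = FALSE])^2)) > .CHAIN_BREAK)
    HB <- function(i, j) i >= 1L && j >= 1L && i <= n && j <= n && hb[i, j]
    linked <- function(i, j) abs(i - j) == 1L && !brk[max(i, j)]
    bridges <- list()
    ## candidate pairs: any (i, j) with a bond among {i-1,i,i+1} x {j-1,j,j+1}
    ## (the second antiparallel/parallel patterns involve only neighbours)
    cand <- which(hb | t(hb), arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    offs <- expand.grid(da = -1L:1L, db = -1L:1L)
    candPairs <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
      cbind(cand[, 1L] + offs$da[r], cand[, 2L] + offs$db[r])))
    candPairs <- candPairs[candPairs[, 1L] >= 1L & candPairs[, 2L] >= 1L &
                           candPairs[, 1L] <= n & candPairs[, 2L] <= n, , drop = FALSE]
    candPairs <- unique(cbind(pmin(candPairs[, 1L], candPairs[, 2L]),
                              pmax(candPairs[, 1L], candPairs[, 2L])))
    for (r in seq_len(nrow(candPairs))) {
      i <- candPairs[r, 1L]; j <- candPairs[r, 2L]
      if (j - i < 3L) next
      anti <- (HB(i, j) && HB(j, i)) ||
              (i > 1L && j < n && linked(i - 1L, i) && linked(j, j + 1L) &&
               HB(i - 1L, j + 1L) && HB(j - 1L, i + 1L) &&
               linked(j - 1L, j) && linked(i, i + 1L))
      para <- (i > 1L && linked(i - 1L, i) && linked(i, i + 1L) && i < n &&
               HB(i - 1L, j) && HB(j, i + 1L)) ||
              (j > 1L && linked(j - 1L, j) && j < n && linked(j, j + 1L) &&
               HB(j - 1L, i) && HB(i, j + 1L))
      if (anti || para)
        bridges[[length(bridges) + 1L]] <- c(i, j, if (anti) 1L else 2L)
    }
    if (length(bridges) == 0L) next
    bm <- do.call(rbind, bridges)
    inBridge <- sort(unique(c(bm[, 1L], bm[, 2L])))
    ## initial runs: consecutive positions, split at chain breaks
    runs <- list(); cur <- inBridge[1L]
    for (k in seq_along(inBridge)[-1L]) {
      i <- inBridge[k]
      if (i - cur[length(cur)] == 1L && !brk[i]) cur <- c(cur, i)
      else { runs[[length(runs) + 1L]] <- cur; cur <- i }
    }
    runs[[length(runs) + 1L]] <- cur
    partnersOf <- function(run) {
      sel <- bm[, 1L] %in% run | bm[, 2L] %in% run
      setdiff(c(bm[sel, 1L], bm[sel, 2L]), run)
    }
    ## merge across bulges: adjacent runs with a small sequence gap whose
    ## bridge partners are contiguous on the same partner strand
    repeat {
      merged <- FALSE
      if (length(runs) > 1L) {
        for (k in seq_len(length(runs) - 1L)) {
          a <- runs[[k]]; b2 <- runs[[k + 1L]]
          gap <- b2[1L] - a[length(a)] - 1L
          if (gap >= 1L && gap <= bulgeGap &&
              !any(brk[seq(a[length(a)] + 1L, b2[1L])]) &&
              length(pa <- partnersOf(a)) && length(pb <- partnersOf(b2)) &&
              min(abs(outer(pa, pb, "-"))) <= 2L) {
            runs[[k]] <- c(a, seq(a[length(a)] + 1L, b2[1L] - 1L), b2)
            runs[[k + 1L]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
    runs <- Filter(function(r) length(r) >= minStrandLen, runs)
    if (length(runs) == 0L) next
    runId <- integer(n)
    for (k in seq_along(runs)) runId[runs[[k]]] <- k
    sdf <- data.frame(chain = ch,
      first = rn[vapply(runs, min, integer(1))],
      last = rn[vapply(runs, max, integer(1))],
      index = idxBase + seq_along(runs))
    strandsAll[[length(strandsAll) + 1L]] <- sdf
    ## pairings: majority bridge orientation between runs
    ri <- runId[bm[, 1L]]; rj <- runId[bm[, 2L]]
    ok <- ri > 0L & rj > 0L & ri != rj
    if (any(ok)) {
      pr <- data.frame(i = idxBase + pmin(ri[ok], rj[ok]),
                       j = idxBase + pmax(ri[ok], rj[ok]),
                       anti = bm[ok, 3L] == 1L)
      agg <- stats::aggregate(anti ~ i + j, pr, function(v) mean(v) >= 0.5)
      pairRows[[length(pairRows) + 1L]] <- data.frame(i = agg$i, j = agg$j,
        orientation = ifelse(agg$anti, "antiparallel", "parallel"))
    }
    idxBase <- idxBase + length(runs)
  }
  if (length(strandsAll) == 0L) return(emptyT)
  strands <- do.call(rbind, strandsAll)
  pairings <- if (length(pairRows)) do.call(rbind, pairRows)
    else data.frame(i = integer(), j = integer(), orientation = character())
  ## sheets: connected components of the pairing graph
  parent <- seq_len(nrow(strands))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairings))) {
    a <- find(pairings$i[r]); b <- find(pairings$j[r])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(nrow(strands)), find, integer(1))
  sheets <- unname(lapply(split(strands$index, comp), sort))
  new("SheetTopology", strands = strands, pairings = pairings, sheets = sheets)
}

setMethod("show", "SheetTopology", function(object) {
  cat(sprintf("SheetTopology: %d strands, %d pairings, %d sheet(s)\n",
              nrow(object@strands), nrow(object@pairings), length(object@sheets)))
  if (nrow(object@strands)) {
    s <- object@strands
    cat(paste(sprintf("  strand %d: %s %d-%d", s$index, s$chain, s$first, s$last),
              collapse = "\n"), "\n")
  }
})

#' @describeIn strands strand table of a SheetTopology
#' @export
setMethod("strands", "SheetTopology", function(x) x@strands)

#' Per-residue secondary-structure string
#'
#' Minimal three-state assignment aligned to the chain sequence: 'E' for
#' residues inside assigned strands, 'H' for residues in runs of overlapping
#' i -> i+4 turns, '-' otherwise. Intended for debugging output and for the
#' secondary-structure class of loop insertions.
#'
#' @param x a ProteinStructure.
#' @param chain chain id (default first).
#' @param topology optional precomputed SheetTopology.
#' @param graph optional precomputed HBondGraph.
#' @return single character string.
#' @export
secondaryStructureString <- function(x, chain, topology = NULL, graph = NULL) {
  chain <- .firstChain(x, chain)
  if (is.null(graph)) graph <- buildHBondGraph(x)
  if (is.null(topology)) topology <- assignStrands(graph, x)
  rn <- residueNumbers(x, chain)
  ss <- rep("-", length(rn))
  b <- graph@bonds[graph@bonds$chain_d == chain & graph@bonds$chain_a == chain, , drop = FALSE]
  turn <- b$donor - b$acceptor == 4L          # CO(i) ... HN(i+4)
  turnAt <- sort(unique(b$acceptor[turn]))
  helixStart <- turnAt[(turnAt - 1L) %in% turnAt]  # consecutive turns -> helix
  for (i in helixStart) {
    idx <- match(i, rn)
    if (!is.na(idx)) ss[pmin(idx + 0L:3L, length(rn))] <- "H"
  }
  s <- topology@strands[topology@strands$chain == chain, , drop = FALSE]
  for (r in seq_len(nrow(s)))
    ss[rn >= s$first[r] & rn <= s$last[r]] <- "E"
  paste(ss, collapse = "")
}
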