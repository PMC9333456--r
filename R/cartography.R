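## C2 beta-sandwich recognition and annotation: candidate detection from the
## sheet topology, Type-I/Type-II classification against the canonical
## templates, boundary extraction from the hydrogen-bond pattern of strands
## 1 and 8, and loop naming with the pocket-apex test.

.SANDWICH_DIST <- 11   # A, mean facing CA distance between the two sheets

#' Detect candidate C2 beta-sandwiches
#'
#' A candidate is a set of eight strands forming two four-stranded sheets
#' that pack face to face: the mean nearest C-alpha distance between the two
#' sheets must fall below \code{sandwichDist}. Candidates are reported in
#' sequence order; overlapping candidates are resolved greedily by earlier
#' start.
#'
#' @param topology a SheetTopology.
#' @param x the ProteinStructure.
#' @param sandwichDist packing threshold in Angstrom.
#' @return list of integer vectors, each the 8 strand indices of one
#'   candidate in sequence order (possibly empty).
#' @export
detectC2Domains <- function(topology, x, sandwichDist = .SANDWICH_DIST) {
  sh <- topology@sheets
  four <- Filter(function(s) length(s) == 4L, sh)
  if (length(four) < 2L) return(list())
  st <- topology@strands
  caOf <- function(idx) {
    do.call(rbind, lapply(idx, function(i) {
      r <- st[st$index == i, , drop = FALSE]
      ca <- caCoords(x, r$chain)
      ca[as.integer(rownames(ca)) >= r$first & as.integer(rownames(ca)) <= r$last, ,
         drop = FALSE]
    }))
  }
  packDist <- function(a, b) {
    d <- .crossDist(a, b)
    (mean(apply(d, 1L, min)) + mean(apply(d, 2L, min))) / 2
  }
  cand <- list()
  for (i in seq_len(length(four) - 1L)) for (j in (i + 1L):length(four)) {
    ## sheets must live on one chain to form a domain
    chs <- unique(st$chain[st$index %in% c(four[[i]], four[[j]])])
    if (length(chs) != 1L) next
    if (packDist(caOf(four[[i]]), caOf(four[[j]])) < sandwichDist)
      cand[[length(cand) + 1L]] <- sort(c(four[[i]], four[[j]]))
  }
  if (length(cand) == 0L) return(list())
  starts <- vapply(cand, function(idx) min(st$first[st$index %in% idx]), integer(1))
  cand <- cand[order(starts)]
  ## greedy overlap resolution: earlier start wins
  taken <- integer(); keep <- list()
  for (cc in cand) {
    if (!any(cc %in% taken)) { keep[[length(keep) + 1L]] <- cc; taken <- c(taken, cc) }
  }
  keep
}

#' Classify the strand topology of a C2 candidate
#'
#' Renumbers the candidate's strands 1..8 in sequence order and matches the
#' observed pairing graph against the canonical C2 adjacency templates at
#' circular-permutation offsets 0 (Type-I) and 1 (Type-II). The unique best
#' match wins; equal scores give "ambiguous".
#'
#' @param candidate integer vector of 8 strand indices.
#' @param topology the SheetTopology.
#' @return "Type-I", "Type-II" or "ambiguous".
#' @export
classifyTopology <- function(candidate, topology) {
  stopifnot(length(candidate) == 8L)
  ord <- candidate[order(topology@strands$first[match(candidate, topology@strands$index)])]
  p <- topology@pairings
  p <- p[p$i %in% candidate & p$j %in% candidate, , drop = FALSE]
  obs <- unique(t(apply(cbind(match(p$i, ord), match(p$j, ord)), 1L, sort)))
  score <- vapply(0:1, function(off) {
    tpl <- topologyTemplate(off)
    sum(apply(obs, 1L, function(r) any(tpl$i == r[1L] & tpl$j == r[2L])))
  }, numeric(1))
  if (score[1L] == score[2L]) "ambiguous" else c("Type-I", "Type-II")[which.max(score)]
}

#' Extract C2 domain boundaries from the hydrogen-bond pattern
#'
#' The domain starts at the first residue of strand 1 that takes part (as
#' donor or acceptor) in a backbone hydrogen bond to one of strand 1's
#' paired strands, and ends at the last such residue of strand 8.
#'
#' @param candidate integer vector of 8 strand indices (sequence order
#'   resolved internally).
#' @param topology the SheetTopology.
#' @param graph the HBondGraph.
#' @return integer(2) closed interval.
#' @export
extractBoundaries <- function(candidate, topology, graph) {
  st <- topology@strands
  ord <- candidate[order(st$first[match(candidate, st$index)])]
  bondResidues <- function(strandIdx) {
    r <- st[st$index == strandIdx, , drop = FALSE]
    partners <- topology@pairings
    partners <- unique(c(partners$j[partners$i == strandIdx],
                         partners$i[partners$j == strandIdx]))
    partners <- intersect(partners, candidate)
    if (length(partners) == 0L)
      .c2Stop("c2AnnotationError",
              sprintf("strand %d has no partner strand", strandIdx))
    inRange <- function(res, row) res >= row$first & res <= row$last
    b <- graph@bonds[graph@bonds$chain_d == r$chain & graph@bonds$chain_a == r$chain, ,
                     drop = FALSE]
    hits <- integer()
    for (pIdx in partners) {
      pr <- st[st$index == pIdx, , drop = FALSE]
      sel <- (inRange(b$donor, r) & inRange(b$acceptor, pr)) |
             (inRange(b$acceptor, r) & inRange(b$donor, pr))
      hits <- c(hits, b$donor[sel & inRange(b$donor, r)],
                b$acceptor[sel & inRange(b$acceptor, r)])
    }
    if (length(hits) == 0L)
      .c2Stop("c2AnnotationError",
              sprintf("strand %d contributes no qualifying hydrogen bond", strandIdx))
    hits
  }
  c(min(bondResidues(ord[1L])), max(bondResidues(ord[8L])))
}

#' Name the inter-strand loops and the pocket apex loops
#'
#' Inter-strand segments are named b1-2 ... b7-8 (zero-length segments get
#' empty intervals). The pocket face is identified geometrically: the
#' sandwich mid-plane is taken orthogonal to the mean strand axis through
#' the candidate centroid, and a loop belongs to the apex when its midpoint
#' C-alpha falls on the same side as loop b1-2. The first three apex loops
#' in sequence order are additionally named loop1, loop2 and loop3; for a
#' Type-II domain loop1 coincides with b1-2 by construction.
#'
#' @param candidate integer vector of 8 strand indices.
#' @param topology the SheetTopology.
#' @param x the ProteinStructure.
#' @return list with \code{loops} (named list of integer(2)) and
#'   \code{apex} (character vector of the b-names of loop1..loop3).
#' @export
labelLoops <- function(candidate, topology, x) {
  st <- topology@strands
  ord <- candidate[order(st$first[match(candidate, st$index)])]
  rows <- st[match(ord, st$index), , drop = FALSE]
  ch <- rows$chain[1L]
  loops <- list()
  for (k in seq_len(7L)) {
    f <- rows$last[k] + 1L; l <- rows$first[k + 1L] - 1L
    loops[[sprintf("b%d-%d", k, k + 1L)]] <- c(f, min(l, f - 1L) + max(0L, l - f + 1L))
  }
  ## apex test: side of the mid-plane orthogonal to the mean strand axis
  ca <- caCoords(x, ch)
  rn <- as.integer(rownames(ca))
  axes <- t(vapply(seq_len(8L), function(k) {
    m <- ca[rn >= rows$first[k] & rn <= rows$last[k], , drop = FALSE]
    v <- m[nrow(m), ] - m[1L, ]
    v / max(.vnorm(v), 1e-9)
  }, numeric(3)))
  ## align axes (antiparallel strands) before averaging
  for (k in 2:8) if (sum(axes[k, ] * axes[1L, ]) < 0) axes[k, ] <- -axes[k, ]
  axis <- .vunit(colMeans(axes))
  strandCa <- ca[rn >= rows$first[1L] & rn <= rows$last[8L], , drop = FALSE]
  centre <- colMeans(strandCa)
  sideOf <- function(iv) {
    if (.intervalLength(iv) == 0L) return(NA_real_)
    m <- ca[rn >= iv[1L] & rn <= iv[2L], , drop = FALSE]
    if (nrow(m) == 0L) return(NA_real_)
    mid <- m[ceiling(nrow(m) / 2), ]
    sum((mid - centre) * axis)
  }
  sides <- vapply(loops, sideOf, numeric(1))
  apex <- character()
  if (!is.na(sides[["b1-2"]])) {
    same <- names(sides)[!is.na(sides) & sign(sides) == sign(sides[["b1-2"]])]
    apex <- head(same, 3L)
  } else {
    message("apex test degenerate (empty b1-2 loop); loops keep b-names only")
  }
  list(loops = loops, apex = apex)
}

#' Annotate all C2 domains of a structure
#'
#' Runs the full recognition pipeline: hydrogen placement, Kabsch-Sander
#' bond assignment, strand/sheet topology, sandwich detection, topology
#' classification, boundary extraction and loop naming. The calcium-pocket
#' census is filled in when a reference is supplied (see
#' \code{\link{pocketCensus}}).
#'
#' @param x a ProteinStructure.
#' @param sandwichDist packing threshold in Angstrom.
#' @param cutoff hydrogen-bond cutoff in kcal/mol.
#' @return list of \linkS4class{C2Annotation} objects (possibly empty).
#' @export
annotateC2 <- function(x, sandwichDist = .SANDWICH_DIST, cutoff = .HBOND_CUTOFF) {
  g <- buildHBondGraph(x, cutoff = cutoff)
  tp <- assignStrands(g, x)
  cands <- detectC2Domains(tp, x, sandwichDist = sandwichDist)
  lapply(cands, function(cc) {
    st <- tp@strands
    ord <- cc[order(st$first[match(cc, st$index)])]
    rows <- st[match(ord, st$index), , drop = FALSE]
    rows$index <- seq_len(8L)
    ll <- labelLoops(cc, tp, x)
    new("C2Annotation", chain = rows$chain[1L],
        strands = rows[, c("first", "last", "index")],
        boundaries = as.integer(extractBoundaries(cc, tp, g)),
        topology = classifyTopology(cc, tp),
        loops = ll$loops, apexLoops = ll$apex,
        subdomains = data.frame(), pocket = list())
  })
}

setMethod("show", "C2Annotation", function(object) {
  cat(sprintf("C2Annotation: chain %s, %s, boundaries %d-%d\n",
              object@chain, object@topology,
              object@boundaries[1L], object@boundaries[2L]))
  ap <- object@apexLoops
  if (length(ap))
    cat(sprintf("  pocket loops: %s\n",
                paste(sprintf("loop%d=%s", seq_along(ap), ap), collapse = ", ")))
})

#' @describeIn strands strand table of a C2Annotation
#' @export
setMethod("strands", "C2Annotation", function(x) x@strands)

#' @describeIn boundaries boundary interval of an annotation
#' @export
setMethod("boundaries", "C2Annotation", function(x) x@boundaries)

#' @describeIn topologyType topology label
#' @export
setMethod("topologyType", "C2Annotation", function(x) x@topology)

#' @describeIn loops named loop intervals
#' @export
setMethod("loops", "C2Annotation", function(x) x@loops)

#' Loop interval of one named loop
#' @param ann a C2Annotation.
#' @param name loop name ("b1-2" ... or "loop1".."loop3").
#' @return integer(2) closed interval (possibly zero-length).
#' @export
loopInterval <- function(ann, name) {
  if (grepl("^loop[123]$", name)) {
    k <- as.integer(sub("loop", "", name))
    if (k > length(ann@apexLoops)) .c2Stop("c2KeyError", paste("no apex loop", name))
    name <- ann@apexLoops[k]
  }
  if (!name %in% names(ann@loops)) .c2Stop("c2KeyError", paste("no loop", name))
  ann@loops[[name]]
}
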