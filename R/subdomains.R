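## Structure-guided comparison against a reference C2 domain: rigid Kabsch
## superposition, strand-anchored residue correspondence, loop-insertion
## detection, the conserved-subdomain rule, overlapping-fragment stitching
## and multi-domain overlay RMSD.

.MIN_OVERLAP <- 10L   # residues shared between stitched fragments
.STITCH_TOL <- 2.0    # A, junction RMSD warning threshold
.SUBDOMAIN_MIN <- 20L # insertion length must be strictly greater
.CONSERVATION_MIN <- 2L

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of two paired coordinate sets by
#' singular value decomposition of the cross-covariance matrix, constrained
#' to a proper rotation (det = +1). Returns the transform mapping \code{b}
#' onto \code{a} (\code{b %*% R + t}) and the post-fit RMSD.
#'
#' @param a,b numeric matrices (n x 3) of paired coordinates, n >= 3.
#' @return list with \code{rotation} (3x3), \code{translation} (length 3)
#'   and \code{rmsd} (Angstrom).
#' @export
superposeKabsch <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L)
    .c2Stop("c2DegeneracyError", "paired n x 3 coordinate sets required")
  n <- nrow(a)
  if (n < 3L) .c2Stop("c2DegeneracyError", "at least 3 paired points required")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2L, ca); B <- sweep(b, 2L, cb)
  H <- crossprod(B, A)
  sv <- svd(H)
  ## collinear (or coincident) point sets leave the rotation underdetermined
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    .c2Stop("c2DegeneracyError", "degenerate (collinear) coordinate set")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  R <- t(R)  # so that b %*% R maps into a's frame
  t0 <- ca - cb %*% R
  fit <- B %*% R
  rmsd <- sqrt(sum((A - fit)^2) / n)
  list(rotation = R, translation = as.numeric(t0), rmsd = rmsd)
}

## Apply a superposition result to raw coordinates.
.applyFit <- function(m, fit) sweep(as.matrix(m) %*% fit$rotation, 2L,
                                    -fit$translation, "-")

#' Strand-anchored correspondence between two annotated C2 domains
#'
#' Strands are matched by index (1..8); within each matched strand residues
#' are paired by register (equal-length strands pair one to one; for
#' unequal lengths the centred window of the shorter is used). Loops are
#' paired from both ends up to the shorter loop length, leaving the middle
#' of the longer loop unpaired. The returned RMSD is computed over the
#' strand-paired C-alpha after Kabsch superposition on those pairs.
#'
#' @param a,b lists with elements \code{structure} (ProteinStructure) and
#'   \code{annotation} (C2Annotation), as returned by the annotation
#'   pipeline.
#' @return list with \code{pairs} (data.frame seq_a, seq_b, region),
#'   \code{rmsd} and \code{fit} (the Kabsch result mapping b onto a).
#' @export
alignStructures <- function(a, b) {
  annA <- a$annotation; annB <- b$annotation
  if (annA@topology != annB@topology || annA@topology == "ambiguous")
    .c2Stop("c2TopologyMismatch",
            sprintf("cannot align %s domain to %s domain",
                    annA@topology, annB@topology))
  caAllA <- caCoords(a$structure, annA@chain)
  caAllB <- caCoords(b$structure, annB@chain)
  caRange <- function(ca, first, last) {
    rn <- as.integer(rownames(ca))
    ca[rn >= first & rn <= last, , drop = FALSE]
  }
  ## coarse rigid fit on the eight strand centroids fixes the frame in which
  ## the per-strand register is read off
  centA <- t(vapply(1:8, function(k)
    colMeans(caRange(caAllA, annA@strands$first[k], annA@strands$last[k])), numeric(3)))
  centB <- t(vapply(1:8, function(k)
    colMeans(caRange(caAllB, annB@strands$first[k], annB@strands$last[k])), numeric(3)))
  coarse <- superposeKabsch(centA, centB)
  pairStrand <- function(k) {
    ra <- annA@strands[k, ]; rb <- annB@strands[k, ]
    sa <- ra$first:ra$last; sb <- rb$first:rb$last
    mA <- caRange(caAllA, ra$first, ra$last)
    mB <- .applyFit(caRange(caAllB, rb$first, rb$last), coarse)
    best <- NULL; bestScore <- Inf
    span <- 2L + abs(length(sa) - length(sb))
    for (shift in -span:span) {
      ia <- seq(max(1L, 1L - shift), min(length(sa), length(sb) - shift))
      if (length(ia) < 3L) next
      sc <- mean(rowSums((mA[ia, , drop = FALSE] -
                          mB[ia + shift, , drop = FALSE])^2))
      if (sc < bestScore) { bestScore <- sc; best <- shift }
    }
    ia <- seq(max(1L, 1L - best), min(length(sa), length(sb) - best))
    data.frame(seq_a = sa[ia], seq_b = sb[ia + best],
               region = sprintf("strand%d", k))
  }
  pairLoop <- function(nm) {
    ia <- annA@loops[[nm]]; ib <- annB@loops[[nm]]
    la <- .intervalLength(ia); lb <- .intervalLength(ib)
    nn <- min(la, lb)
    if (nn == 0L) return(NULL)
    nHead <- ceiling(nn / 2); nTail <- nn - nHead
    sa <- ia[1L]:ia[2L]; sb <- ib[1L]:ib[2L]
    data.frame(
      seq_a = c(sa[seq_len(nHead)], if (nTail) sa[la - nTail + seq_len(nTail)]),
      seq_b = c(sb[seq_len(nHead)], if (nTail) sb[lb - nTail + seq_len(nTail)]),
      region = nm)
  }
  pairs <- do.call(rbind, c(lapply(1:8, pairStrand),
                            Filter(Negate(is.null), lapply(names(annA@loops), pairLoop))))
  strandPairs <- pairs[grepl("^strand", pairs$region), , drop = FALSE]
  caA <- caCoords(a$structure, annA@chain, strandPairs$seq_a)
  caB <- caCoords(b$structure, annB@chain, strandPairs$seq_b)
  caA <- caA[match(strandPairs$seq_a, rownames(caA)), , drop = FALSE]
  caB <- caB[match(strandPairs$seq_b, rownames(caB)), , drop = FALSE]
  fit <- superposeKabsch(caA, caB)
  list(pairs = pairs, rmsd = fit$rmsd, fit = fit)
}

#' Detect loop insertions relative to a reference domain
#'
#' Per inter-strand loop the insertion length is
#' \code{max(0, candidate loop length - reference loop length)}; the
#' interval covers the unpaired middle residues of the candidate loop.
#'
#' @param candidate,reference lists with \code{structure} and
#'   \code{annotation} elements.
#' @return data.frame with columns \code{host_loop}, \code{length},
#'   \code{first}, \code{last} (zero rows when nothing is inserted).
#' @export
detectInsertions <- function(candidate, reference) {
  annC <- candidate$annotation; annR <- reference$annotation
  out <- list()
  for (nm in names(annC@loops)) {
    lc <- .intervalLength(annC@loops[[nm]])
    lr <- .intervalLength(annR@loops[[nm]])
    ins <- max(0L, lc - lr)
    if (ins > 0L) {
      iv <- annC@loops[[nm]]
      nHead <- ceiling(min(lc, lr) / 2)
      first <- iv[1L] + nHead
      out[[length(out) + 1L]] <- data.frame(host_loop = nm, length = ins,
        first = first, last = first + ins - 1L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(host_loop = character(), length = integer(),
                      first = integer(), last = integer()))
  do.call(rbind, out)
}

## Secondary-structure class of an insertion interval: helix-rich when >40%
## of its residues are helical, sheet-rich when >40% are strand, else coil.
.ssClass <- function(ss, first, last) {
  seg <- strsplit(substr(ss, first, last), "")[[1L]]
  if (length(seg) == 0L) return("coil")
  if (mean(seg == "H") > 0.4) "helix-rich"
  else if (mean(seg == "E") > 0.4) "sheet-rich"
  else "coil"
}

#' Call conserved subdomains across paralogs
#'
#' A subdomain is called at a loop when at least \code{conservationMin}
#' paralogs carry an insertion strictly longer than \code{minLength}
#' residues there (21 qualifies, 20 does not) with agreeing
#' secondary-structure class. With a single paralog conservation cannot be
#' evaluated: candidates are returned flagged unconfirmed.
#'
#' @param insertionSets named list (one element per paralog) of insertion
#'   data.frames from \code{\link{detectInsertions}}.
#' @param ssStrings named character vector of per-residue secondary
#'   structure strings (indexable by residue number), one per paralog.
#' @param minLength insertion length threshold (strict inequality).
#' @param conservationMin minimum number of agreeing paralogs.
#' @return data.frame with columns \code{host_loop}, \code{ss_class},
#'   \code{conserved_in} (comma-separated paralogs), \code{n_paralogs},
#'   \code{confirmed}.
#' @export
callSubdomains <- function(insertionSets, ssStrings,
                           minLength = .SUBDOMAIN_MIN,
                           conservationMin = .CONSERVATION_MIN) {
  stopifnot(length(insertionSets) >= 1L)
  paralogs <- sort(names(insertionSets))
  recs <- list()
  for (pg in paralogs) {
    df <- insertionSets[[pg]]
    for (r in seq_len(nrow(df))) {
      if (df$length[r] > minLength) {
        cls <- .ssClass(ssStrings[[pg]], df$first[r], df$last[r])
        recs[[length(recs) + 1L]] <- data.frame(paralog = pg,
          host_loop = df$host_loop[r], ss_class = cls)
      }
    }
  }
  empty <- data.frame(host_loop = character(), ss_class = character(),
                      conserved_in = character(), n_paralogs = integer(),
                      confirmed = logical())
  if (length(recs) == 0L) return(empty)
  recs <- do.call(rbind, recs)
  single <- length(insertionSets) == 1L
  out <- list()
  for (lp in sort(unique(recs$host_loop))) {
    sub <- recs[recs$host_loop == lp, , drop = FALSE]
    tab <- sort(table(sub$ss_class), decreasing = TRUE)
    cls <- names(tab)[1L]
    members <- sort(sub$paralog[sub$ss_class == cls])
    if (single) {
      out[[length(out) + 1L]] <- data.frame(host_loop = lp, ss_class = cls,
        conserved_in = paste(members, collapse = ","),
        n_paralogs = length(members), confirmed = FALSE)
    } else if (length(members) >= conservationMin) {
      out[[length(out) + 1L]] <- data.frame(host_loop = lp, ss_class = cls,
        conserved_in = paste(members, collapse = ","),
        n_paralogs = length(members), confirmed = TRUE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Stitch overlapping fragment models into one structure
#'
#' Fragments are ordered by their first residue number; each subsequent
#' fragment is rigidly superposed onto the growing assembly over the shared
#' C-alpha positions (at least \code{minOverlap} residues). Coordinates in
#' the overlap are taken from the earlier fragment, numbering stays the
#' author numbering, and the per-junction overlap RMSD is reported. A
#' junction RMSD above \code{stitchTol} produces a warning but still
#' stitches.
#'
#' @param fragments list of ProteinStructure fragments (single chain each).
#' @param minOverlap minimum shared residues per junction.
#' @param stitchTol junction RMSD warning threshold, Angstrom.
#' @return list with \code{structure} (the assembly) and \code{junctions}
#'   (data.frame with overlap size and RMSD per junction).
#' @export
stitchFragments <- function(fragments, minOverlap = .MIN_OVERLAP,
                            stitchTol = .STITCH_TOL) {
  stopifnot(length(fragments) >= 1L)
  ord <- order(vapply(fragments, function(f)
    min(residueNumbers(f, chains(f)[1L])), integer(1)))
  fragments <- fragments[ord]
  asm <- fragments[[1L]]
  ch <- chains(asm)[1L]
  junctions <- list()
  for (k in seq_along(fragments)[-1L]) {
    frag <- fragments[[k]]
    fch <- chains(frag)[1L]
    shared <- intersect(residueNumbers(asm, ch), residueNumbers(frag, fch))
    if (length(shared) < minOverlap)
      .c2Stop("c2StitchError", sprintf(
        "junction %d: %d shared residues (< %d required)",
        k - 1L, length(shared), minOverlap))
    caA <- caCoords(asm, ch, shared); caF <- caCoords(frag, fch, shared)
    caA <- caA[match(shared, rownames(caA)), , drop = FALSE]
    caF <- caF[match(shared, rownames(caF)), , drop = FALSE]
    fit <- superposeKabsch(caA, caF)
    if (fit$rmsd > stitchTol)
      warning(sprintf("junction %d overlap RMSD %.2f A exceeds %.2f A",
                      k - 1L, fit$rmsd, stitchTol))
    m <- .applyFit(as.matrix(frag@atoms[, c("x", "y", "z")]), fit)
    frag@atoms$x <- m[, 1L]; frag@atoms$y <- m[, 2L]; frag@atoms$z <- m[, 3L]
    newPart <- frag@atoms[!(frag@atoms$resno %in% shared), , drop = FALSE]
    newPart$chain <- ch
    asmAtoms <- rbind(asm@atoms, newPart)
    asmAtoms <- asmAtoms[order(asmAtoms$resno), , drop = FALSE]
    rownames(asmAtoms) <- NULL
    asm <- initialize(asm, atoms = asmAtoms)
    junctions[[length(junctions) + 1L]] <- data.frame(junction = k - 1L,
      overlap = length(shared), rmsd = fit$rmsd)
  }
  list(structure = asm,
       junctions = if (length(junctions)) do.call(rbind, junctions)
                   else data.frame(junction = integer(), overlap = integer(),
                                   rmsd = numeric()))
}

#' Pairwise and mean overlay RMSD of annotated C2 domains
#'
#' All distinct pairs are aligned with \code{\link{alignStructures}} and the
#' strand-anchored C-alpha RMSD is collected into a symmetric matrix
#' together with the mean over distinct pairs.
#'
#' @param domains named list of lists with \code{structure} and
#'   \code{annotation}.
#' @return list with \code{matrix} and \code{mean}.
#' @export
overlayRmsd <- function(domains) {
  n <- length(domains)
  if (n < 2L) .c2Stop("c2UsageError", "at least two domains required")
  nms <- names(domains)
  if (is.null(nms)) nms <- sprintf("domain%d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- alignStructures(domains[[i]], domains[[j]])$rmsd
    m[i, j] <- m[j, i] <- r
  }
  list(matrix = m, mean = mean(m[upper.tri(m)]))
}
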