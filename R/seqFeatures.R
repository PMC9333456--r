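## Sequence-level analytics: composition, isoelectric point (Bjellqvist /
## ProtParam pKa set with bisection), molar extinction coefficient at
## 280 nm, alignment identity/similarity, calcium-pocket census and
## transmembrane-span arithmetic.

#' Construct a SequenceSegment
#'
#' @param sequence one-letter string; gap characters '-' are stripped.
#' @param name segment label.
#' @param protein parent protein identifier.
#' @param interval optional integer(2) closed interval in parent numbering.
#' @return a \linkS4class{SequenceSegment}.
#' @export
sequenceSegment <- function(sequence, name = NA_character_,
                            protein = NA_character_, interval = c(NA, NA)) {
  new("SequenceSegment", name = as.character(name), protein = as.character(protein),
      interval = as.integer(interval),
      sequence = gsub("-", "", toupper(sequence), fixed = TRUE))
}

setMethod("show", "SequenceSegment", function(object) {
  cat(sprintf("SequenceSegment '%s' (%s): %d aa\n", object@name, object@protein,
              nchar(object@sequence)))
})

## Accept either a SequenceSegment or a plain string; return the clean
## residue vector (standard letters only; others dropped with a warning).
.residueVector <- function(x, context = "analysis") {
  s <- if (is(x, "SequenceSegment")) x@sequence else gsub("-", "", toupper(x), fixed = TRUE)
  if (!nzchar(s)) .c2Stop("c2UsageError", "empty sequence")
  v <- strsplit(s, "")[[1L]]
  bad <- !(v %in% .standardAA)
  if (any(bad)) {
    warning(sprintf("%d non-standard residue(s) excluded from %s",
                    sum(bad), context))
    v <- v[!bad]
  }
  if (length(v) == 0L) .c2Stop("c2UsageError", "no standard residues in sequence")
  v
}

#' Residue composition of a segment
#'
#' @param x a SequenceSegment or one-letter string.
#' @param letters optional subset of residues to report (default: all 20).
#' @return list with \code{length} (standard residues) and \code{fraction}
#'   (named numeric, count/length per requested letter).
#' @export
residueComposition <- function(x, letters = NULL) {
  v <- .residueVector(x, "composition")
  if (is.null(letters)) letters <- .standardAA
  counts <- vapply(letters, function(l) sum(v == l), numeric(1))
  list(length = length(v), fraction = counts / length(v))
}

## Bjellqvist pKa values as used by the ProtParam tool: side chains plus
## residue-specific terminal corrections.
.PK_POS <- c(K = 10.0, R = 12.0, H = 5.98)
.PK_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
.PK_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
.PK_NTERM_DEFAULT <- 7.5
.PK_CTERM <- c(D = 4.55, E = 4.75)
.PK_CTERM_DEFAULT <- 3.55

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the ionizable side chains
#' (D, E, C, Y, H, K, R) with the Bjellqvist/ProtParam pKa set.
#'
#' @param x a SequenceSegment or one-letter string.
#' @param pH pH value.
#' @return net charge (elementary charges).
#' @export
netCharge <- function(x, pH) {
  v <- .residueVector(x, "charge calculation")
  nt <- v[1L]; ct <- v[length(v)]
  pkN <- if (nt %in% names(.PK_NTERM)) .PK_NTERM[[nt]] else .PK_NTERM_DEFAULT
  pkC <- if (ct %in% names(.PK_CTERM)) .PK_CTERM[[ct]] else .PK_CTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - pkN)) +
    sum(vapply(names(.PK_POS), function(a)
      sum(v == a) / (1 + 10^(pH - .PK_POS[[a]])), numeric(1)))
  neg <- 1 / (1 + 10^(pkC - pH)) +
    sum(vapply(names(.PK_NEG), function(a)
      sum(v == a) / (1 + 10^(.PK_NEG[[a]] - pH)), numeric(1)))
  pos - neg
}

#' Isoelectric point
#'
#' The pH at which the net charge crosses zero, found by bisection on
#' pH 0..14 to |charge| < 1e-4 with the Bjellqvist/ProtParam pKa set (the
#' charge is monotone decreasing in pH, so the root is unique).
#'
#' @param x a SequenceSegment or one-letter string (gaps stripped).
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(x) {
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- netCharge(x, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill-von Hippel composition estimate:
#' \code{5500 nTrp + 1490 nTyr + 125 nCystine}. In "all-cystine" mode the
#' number of cystines is \code{floor(nCys / 2)}; in "all-reduced" mode it
#' is zero.
#'
#' @param x a SequenceSegment or one-letter string.
#' @param cystineMode "all-cystine" or "all-reduced".
#' @return extinction coefficient in M^-1 cm^-1.
#' @export
extinctionCoefficient <- function(x, cystineMode = c("all-cystine", "all-reduced")) {
  cystineMode <- match.arg(cystineMode)
  v <- .residueVector(x, "extinction coefficient")
  pairs <- if (cystineMode == "all-cystine") sum(v == "C") %/% 2L else 0L
  5500 * sum(v == "W") + 1490 * sum(v == "Y") + 125 * pairs
}

## Residue classes treated as similar for the similarity fraction (one
## common choice of physico-chemical groups).
.SIM_CLASSES <- c("ILVM", "FWY", "KRH", "DE", "ST", "NQ", "AG", "C", "P")

#' Mean identity and similarity of a gapped alignment
#'
#' Pairwise identity is the number of identical non-double-gap columns over
#' the columns where at least one of the two rows has a residue; similarity
#' uses membership of the same physico-chemical class. Means are taken over
#' all distinct row pairs.
#'
#' @param alignment character vector (>= 2 equal-length gapped rows).
#' @return list with \code{identity}, \code{similarity} (mean fractions) and
#'   \code{pairs} (per-pair data.frame).
#' @export
identitySimilarity <- function(alignment) {
  if (length(alignment) < 2L) .c2Stop("c2UsageError", "need at least 2 rows")
  if (length(unique(nchar(alignment))) != 1L)
    .c2Stop("c2UsageError", "alignment rows must have equal length")
  rows <- lapply(alignment, function(s) strsplit(toupper(s), "")[[1L]])
  classOf <- function(a) {
    hit <- which(vapply(.SIM_CLASSES, function(cl)
      grepl(a, cl, fixed = TRUE), logical(1)))
    if (length(hit)) hit[1L] else NA_integer_
  }
  n <- length(rows)
  recs <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- rows[[i]]; b <- rows[[j]]
    occ <- a != "-" | b != "-"
    both <- a != "-" & b != "-"
    id <- sum(both & a == b) / sum(occ)
    sim <- sum(both & (a == b |
      (vapply(a, classOf, integer(1)) == vapply(b, classOf, integer(1)))),
      na.rm = TRUE) / sum(occ)
    recs[[length(recs) + 1L]] <- data.frame(i = i, j = j, identity = id,
                                            similarity = sim)
  }
  pairs <- do.call(rbind, recs)
  list(identity = mean(pairs$identity), similarity = mean(pairs$similarity),
       pairs = pairs)
}

#' Pocket residues near bound cations
#'
#' Residues of the polymer with any atom within \code{cutoff} of a bound
#' divalent cation (HETATM records named CA, ZN, MG or MN). Used to derive
#' the reference coordinating positions from a cation-bound reference
#' structure.
#'
#' @param x a ProteinStructure whose \code{hetero} slot carries the cations.
#' @param chain polymer chain to scan (default first).
#' @param cutoff distance cutoff in Angstrom.
#' @param ions HETATM atom names treated as cations.
#' @return sorted integer vector of residue numbers.
#' @export
referencePocketPositions <- function(x, chain, cutoff = 4.0,
                                     ions = c("CA", "ZN", "MG", "MN")) {
  chain <- .firstChain(x, chain)
  het <- x@hetero[x@hetero$elety %in% ions, , drop = FALSE]
  if (nrow(het) == 0L)
    .c2Stop("c2UsageError", "no bound cations in the hetero records")
  a <- x@atoms[x@atoms$chain == chain, , drop = FALSE]
  d <- .crossDist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(het[, c("x", "y", "z")]))
  sort(unique(a$resno[apply(d, 1L, min) <= cutoff]))
}

#' Calcium-pocket census of an annotated C2 domain
#'
#' Maps the reference coordinating positions onto the candidate through the
#' strand-anchored correspondence and counts how many aligned candidate
#' residues are acidic (Asp or Glu). The domain is called binding-likely
#' when at least \code{threshold} slots are acidic.
#'
#' @param candidate,reference lists with \code{structure} and
#'   \code{annotation}.
#' @param referencePositions residue numbers of the coordinating slots in
#'   the reference; default: the six pocket slots of the packaged synthetic
#'   reference.
#' @param threshold acidic slots required for a binding-likely call.
#' @return list with \code{positions} (mapped candidate residues, NA when a
#'   slot is unmatched), \code{residues}, \code{acidic_count} and
#'   \code{call}.
#' @export
pocketCensus <- function(candidate, reference, referencePositions = NULL,
                         threshold = 4L) {
  if (is.null(referencePositions)) {
    ref <- reference
    if (is.null(ref$truth$pocketPositions))
      .c2Stop("c2UsageError", "referencePositions required for this reference")
    referencePositions <- ref$truth$pocketPositions
  }
  al <- alignStructures(candidate, reference)
  mapped <- al$pairs$seq_a[match(referencePositions, al$pairs$seq_b)]
  ch <- candidate$annotation@chain
  rn <- residueNumbers(candidate$structure, ch)
  aa <- strsplit(chainSequence(candidate$structure, ch), "")[[1L]]
  res <- aa[match(mapped, rn)]
  acidic <- sum(res %in% c("D", "E"), na.rm = TRUE)
  list(positions = mapped, residues = res, acidic_count = acidic,
       call = if (acidic >= threshold) "binding-likely" else "binding-unlikely")
}

#' Transmembrane-span arithmetic
#'
#' Span length is inclusive (\code{last - first + 1}); the extracellular
#' count uses the exclusive end-minus-start convention
#' (\code{last - first}). The conserved proline is the first Pro found in
#' the window from four residues inside the span end to three residues past
#' it, accommodating spans whose hinge proline falls inside the predicted
#' helix.
#'
#' @param protein protein identifier (carried through).
#' @param span integer(2) closed TM interval.
#' @param extracellular optional integer(2) closed extracellular interval.
#' @param sequence optional full-length protein sequence (1-based) used to
#'   locate the conserved proline.
#' @return list with \code{protein}, \code{span}, \code{length},
#'   \code{conserved_pro} (NA when not found / no sequence),
#'   \code{extracellular} and \code{extracellular_count}.
#' @export
tmAnalytics <- function(protein, span, extracellular = NULL, sequence = NULL) {
  span <- as.integer(span)
  stopifnot(length(span) == 2L, span[1L] <= span[2L])
  len <- span[2L] - span[1L] + 1L
  pro <- NA_integer_
  if (!is.null(sequence)) {
    v <- strsplit(gsub("-", "", toupper(sequence), fixed = TRUE), "")[[1L]]
    win <- seq(max(1L, span[2L] - 4L), min(length(v), span[2L] + 3L))
    hit <- win[v[win] == "P"]
    if (length(hit)) pro <- hit[1L]
    else message(sprintf("%s: no conserved Pro near span end %d", protein, span[2L]))
  }
  extraCount <- NA_integer_
  if (!is.null(extracellular)) {
    extracellular <- as.integer(extracellular)
    extraCount <- extracellular[2L] - extracellular[1L]
  }
  list(protein = protein, span = span, length = len, conserved_pro = pro,
       extracellular = extracellular, extracellular_count = extraCount)
}

## Kyte-Doolittle hydropathy values.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Sliding-window hydropathy scan
#'
#' Kyte-Doolittle window means; maximal runs of window centres above the
#' threshold are reported as candidate membrane spans (expanded by half a
#' window on both sides, clipped to the chain).
#'
#' @param sequence one-letter string.
#' @param window odd window size >= 7.
#' @param threshold mean hydropathy threshold for a candidate.
#' @return data.frame with columns \code{first}, \code{last}, \code{peak}.
#' @export
hydropathyScan <- function(sequence, window = 19L, threshold = 1.6) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 7L)
    .c2Stop("c2UsageError", "window must be odd and >= 7")
  v <- .residueVector(sequence, "hydropathy scan")
  if (length(v) < window)
    .c2Stop("c2UsageError", "sequence shorter than the window")
  kd <- .KD[v]
  means <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 2L))
  centre <- which(!is.na(means) & means > threshold)
  if (length(centre) == 0L)
    return(data.frame(first = integer(), last = integer(), peak = numeric()))
  grp <- cumsum(c(1L, diff(centre) != 1L))
  half <- window %/% 2L
  do.call(rbind, lapply(split(centre, grp), function(cc) {
    data.frame(first = max(1L, min(cc) - half),
               last = min(length(v), max(cc) + half),
               peak = max(means[cc]))
  }))
}
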