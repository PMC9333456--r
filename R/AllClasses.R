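#' @import methods
#' @importFrom stats setNames
NULL

## Atom table columns shared by all ProteinStructure objects. Coordinates in
## Angstrom, author (1-based) residue numbering, one-letter amino-acid codes
## with 'X' for anything outside the 20 standard residues.
.atomCols <- c("chain", "resno", "ins", "aa", "elety", "x", "y", "z", "occ")

#' ProteinStructure: ordered chains of residues with backbone atoms
#'
#' A lightweight coordinate container for polymer chains. Atoms are stored as
#' a single data.frame (one row per atom) in chain order, with strictly
#' increasing \code{(resno, ins)} within each chain. HETATM records are not
#' part of the polymer and live in the \code{hetero} slot so that ligand
#' geometry (for example bound divalent cations) remains available.
#'
#' @slot id single character identifier.
#' @slot atoms data.frame with columns \code{chain}, \code{resno}, \code{ins},
#'   \code{aa}, \code{elety}, \code{x}, \code{y}, \code{z}, \code{occ}.
#' @slot hetero data.frame with the same columns for non-polymer atoms.
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(id = "character", atoms = "data.frame", hetero = "data.frame"),
  prototype(id = NA_character_,
            atoms = data.frame(), hetero = data.frame()))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return(TRUE)
  if (!all(.atomCols %in% names(a)))
    return(paste("atoms must have columns:", paste(.atomCols, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom coordinates must be finite")
  if (any(!nzchar(a$elety))) return("atom names must be non-empty")
  ok <- vapply(split(a, factor(a$chain, unique(a$chain))), function(ca) {
    key <- paste(ca$resno, ca$ins)
    r <- rle(key)$values
    rn <- as.integer(sub(" .*", "", r))
    all(diff(rn) >= 0) && !anyDuplicated(r)
  }, logical(1))
  if (!all(ok))
    return("residues must be strictly increasing by (resno, ins) within chains")
  TRUE
})

#' HBondGraph: directed backbone donor-to-acceptor hydrogen bonds
#'
#' Records N-H...O=C backbone hydrogen bonds scored with the Kabsch-Sander
#' electrostatic model. Each row is one bond from a donor residue (amide) to
#' an acceptor residue (carbonyl); energies are in kcal/mol and all retained
#' bonds fall below the assignment cutoff. Per donor at most the best two
#' acceptors are kept.
#'
#' @slot bonds data.frame with columns \code{chain_d}, \code{donor},
#'   \code{chain_a}, \code{acceptor}, \code{energy}.
#' @slot cutoff numeric, the assignment threshold in kcal/mol.
#' @exportClass HBondGraph
setClass("HBondGraph",
  representation(bonds = "data.frame", cutoff = "numeric"),
  prototype(bonds = data.frame(chain_d = character(), donor = integer(),
                               chain_a = character(), acceptor = integer(),
                               energy = numeric()),
            cutoff = -0.5))

setValidity("HBondGraph", function(object) {
  b <- object@bonds
  if (nrow(b) == 0L) return(TRUE)
  if (any(b$energy >= object@cutoff)) return("all bond energies must fall below the cutoff")
  same <- b$chain_d == b$chain_a
  if (any(same & abs(b$donor - b$acceptor) < 2L))
    return("self and nearest-neighbour bonds are excluded (|i - j| >= 2)")
  n <- table(paste(b$chain_d, b$donor))
  if (any(n > 2L)) return("at most two acceptors per donor")
  TRUE
})

#' SheetTopology: beta-strands, their pairings and sheet membership
#'
#' The product of ladder/strand assignment: strand intervals in sequence
#' order, the pairing graph between strands (parallel or antiparallel) and
#' its connected components (sheets).
#'
#' @slot strands data.frame with columns \code{chain}, \code{first},
#'   \code{last}, \code{index} (1-based order along the sequence).
#' @slot pairings data.frame with columns \code{i}, \code{j} (strand indices,
#'   i < j) and \code{orientation} ("parallel" or "antiparallel").
#' @slot sheets list of integer vectors, each the strand indices of one sheet.
#' @exportClass SheetTopology
setClass("SheetTopology",
  representation(strands = "data.frame", pairings = "data.frame", sheets = "list"),
  prototype(strands = data.frame(chain = character(), first = integer(),
                                 last = integer(), index = integer()),
            pairings = data.frame(i = integer(), j = integer(),
                                  orientation = character()),
            sheets = list()))

setValidity("SheetTopology", function(object) {
  s <- object@strands; p <- object@pairings
  if (nrow(s) > 0L) {
    if (any(s$first > s$last)) return("strand first must be <= last")
    for (ch in unique(s$chain)) {
      cs <- s[s$chain == ch, , drop = FALSE]
      cs <- cs[order(cs$first), , drop = FALSE]
      if (nrow(cs) > 1L && any(cs$first[-1L] <= cs$last[-nrow(cs)]))
        return("strands of one chain must be non-overlapping")
    }
  }
  if (nrow(p) > 0L) {
    if (!all(c(p$i, p$j) %in% s$index)) return("paired strands must exist")
    if (any(p$i >= p$j)) return("pairings stored with i < j")
  }
  TRUE
})

#' C2Annotation: one detected C2 beta-sandwich domain
#'
#' Boundaries follow the hydrogen-bond rule: the domain runs from the first
#' residue of strand 1 that takes part in an inter-strand backbone hydrogen
#' bond through the last such residue of strand 8. Loops are the inter-strand
#' segments, named b1-2 ... b7-8; the three apex loops additionally carry the
#' pocket names loop1, loop2, loop3.
#'
#' @slot chain chain identifier.
#' @slot strands data.frame of the 8 member strands in sequence order
#'   (columns \code{first}, \code{last}, \code{index} 1..8).
#' @slot boundaries integer(2), closed interval in residue numbering.
#' @slot topology "Type-I", "Type-II" or "ambiguous".
#' @slot loops named list of integer(2) closed intervals (zero-length loops
#'   are stored as \code{c(first, first - 1L)}).
#' @slot apexLoops character, the inter-strand names of loop1..loop3.
#' @slot subdomains data.frame of called subdomains (may be empty).
#' @slot pocket list, census of the calcium-pocket reference slots.
#' @exportClass C2Annotation
setClass("C2Annotation",
  representation(chain = "character", strands = "data.frame",
                 boundaries = "integer", topology = "character",
                 loops = "list", apexLoops = "character",
                 subdomains = "data.frame", pocket = "list"),
  prototype(chain = NA_character_, strands = data.frame(),
            boundaries = c(NA_integer_, NA_integer_), topology = "ambiguous",
            loops = list(), apexLoops = character(),
            subdomains = data.frame(), pocket = list()))

setValidity("C2Annotation", function(object) {
  if (nrow(object@strands) != 8L) return("a C2 annotation has exactly 8 strands")
  b <- object@boundaries
  if (length(b) != 2L) return("boundaries must be a closed interval")
  if (!any(is.na(b)) && b[1L] > b[2L]) return("boundary start must be <= end")
  if (!object@topology %in% c("Type-I", "Type-II", "ambiguous"))
    return("topology must be Type-I, Type-II or ambiguous")
  TRUE
})

#' SequenceSegment: a named residue range with its sequence
#'
#' Gap characters ('-') are stripped from the sequence at construction; the
#' interval keeps the author numbering of the parent protein. Non-standard
#' letters are tolerated in the slot but excluded (with a warning) from
#' composition, pI and extinction-coefficient calculations.
#'
#' @slot name segment label (for example "FerI" or "A-B linker").
#' @slot protein parent protein identifier.
#' @slot interval integer(2) closed interval, NA when unknown.
#' @slot sequence one-letter amino-acid string, gap-free.
#' @exportClass SequenceSegment
setClass("SequenceSegment",
  representation(name = "character", protein = "character",
                 interval = "integer", sequence = "character"),
  prototype(name = NA_character_, protein = NA_character_,
            interval = c(NA_integer_, NA_integer_), sequence = ""))

setValidity("SequenceSegment", function(object) {
  if (grepl("-", object@sequence, fixed = TRUE))
    return("sequence must be gap-free after construction")
  TRUE
})

#' SandwichSpec: parameters of a synthetic C2-like beta-sandwich
#'
#' @slot nStrands integer, number of strands (8 for a C2 domain).
#' @slot strandLen integer, residues per strand.
#' @slot connectivity integer offset, 0 (Type-I) or 1 (Type-II circular
#'   permutant).
#' @slot loopLengths named integer vector, residues per inter-strand loop
#'   (names "b1-2" ... "b7-8").
#' @slot insertions named list: per loop a list(length=, ssClass=) insertion.
#' @slot noiseSigma numeric, isotropic Gaussian coordinate noise (Angstrom).
#' @slot seed integer, fixes all randomness.
#' @slot nTail integer, unstructured residues before strand 1 / after strand 8.
#' @slot pocketAcidic logical, place Asp at the six pocket reference slots.
#' @exportClass SandwichSpec
setClass("SandwichSpec",
  representation(nStrands = "integer", strandLen = "integer",
                 connectivity = "integer", loopLengths = "integer",
                 insertions = "list", noiseSigma = "numeric",
                 seed = "integer", nTail = "integer", pocketAcidic = "logical"))

setValidity("SandwichSpec", function(object) {
  if (object@strandLen < 4L) return("strandLen must be >= 4")
  if (!object@connectivity %in% c(0L, 1L)) return("connectivity offset must be 0 or 1")
  if (any(object@loopLengths < 1L)) return("loop lengths must be >= 1")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})
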