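#' Read a coordinate model into a ProteinStructure
#'
#' Parses a PDB (or mmCIF) file and returns the polymer as an ordered
#' structure. Alternate locations are resolved per atom by keeping the
#' highest-occupancy record (tie broken toward altloc 'A'); HETATM records are
#' excluded from the polymer chains but kept in the \code{hetero} slot so that
#' bound ions remain available to downstream geometry. Residue numbering is
#' the author numbering of the file and is preserved everywhere.
#'
#' @param path file path.
#' @param dialect "pdb" (canonical) or "mmcif".
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' s <- buildSandwich(sandwichSpec(seed = 1L))$structure
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(s, f)
#' identicalish <- readStructure(f)
#' @export
readStructure <- function(path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    .c2Stop("c2IOError", sprintf("file not found: %s", path))
  pdb <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) .c2Stop("c2FormatError",
      sprintf("cannot parse '%s' as %s: %s", path, dialect, conditionMessage(e))))
  at <- pdb$atom
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  at$altloc <- ifelse(is.na(at$alt), "", at$alt)
  poly <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type != "ATOM", , drop = FALSE]
  if (nrow(poly) == 0L)
    .c2Stop("c2EmptyStructureError", sprintf("no polymer (ATOM) records in %s", path))
  poly <- .resolveAltloc(poly)
  mk <- function(d) {
    if (nrow(d) == 0L) return(data.frame())
    data.frame(chain = ifelse(is.na(d$chain), "A", d$chain),
               resno = as.integer(d$resno),
               ins = d$ins, aa = .aaOne(d$resid), elety = d$elety,
               x = d$x, y = d$y, z = d$z, occ = d$occ,
               stringsAsFactors = FALSE)
  }
  new("ProteinStructure",
      id = sub("\\.(pdb|cif|ent)(\\.gz)?$", "", basename(path)),
      atoms = mk(poly), hetero = mk(het))
}

## Keep one record per (chain, resno, ins, elety): highest occupancy, then the
## lexicographically first altloc (so the tie falls to '' or 'A').
.resolveAltloc <- function(at) {
  key <- paste(at$chain, at$resno, at$ins, at$elety, sep = "\r")
  if (!anyDuplicated(key)) return(at)
  ord <- order(key, -at$occ, at$altloc)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at[order(match(paste(at$chain, at$resno, at$ins, sep = "\r"),
                 unique(paste(at$chain, at$resno, at$ins, sep = "\r")))), , drop = FALSE]
}

#' Write a ProteinStructure as a PDB file
#'
#' Emits standard fixed-width ATOM records in residue order with a TER record
#' after each chain and a final END. Coordinates are written to 3 decimals,
#' so \code{readStructure(writeStructure(s))} is the identity on chain ids,
#' numbering, sequence, atom names and coordinates to 1e-3 Angstrom.
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeStructure <- function(x, path) {
  stopifnot(is(x, "ProteinStructure"))
  if (nrow(x@atoms) == 0L)
    .c2Stop("c2EmptyStructureError", "refusing to write an empty structure")
  con <- tryCatch(file(path, "w"),
                  error = function(e) .c2Stop("c2IOError",
                    sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  serial <- 0L
  for (ch in chains(x)) {
    a <- x@atoms[x@atoms$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$elety[i]
      nm <- if (nchar(nm) <= 3L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      res3 <- if (a$aa[i] %in% names(.aa1to3)) .aa1to3[[a$aa[i]]] else "UNK"
      el <- sub("[0-9'*]+$", "", a$elety[i])
      el <- substr(el, 1L, 1L)
      writeLines(sprintf(
        "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm, res3, ch, a$resno[i] %% 10000L,
        ifelse(nzchar(a$ins[i]), a$ins[i], " "),
        a$x[i], a$y[i], a$z[i], a$occ[i], 0, el), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d", serial %% 100000L), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @describeIn chains chains in file order
#' @export
setMethod("chains", "ProteinStructure", function(x) unique(x@atoms$chain))

#' @describeIn residueNumbers residue numbers of one chain
#' @export
setMethod("residueNumbers", "ProteinStructure", function(x, chain) {
  chain <- .firstChain(x, chain)
  a <- x@atoms[x@atoms$chain == chain, , drop = FALSE]
  unique(a$resno)
})

#' @describeIn chainSequence one-letter sequence; unknown residues are 'X'
#' @export
setMethod("chainSequence", "ProteinStructure", function(x, chain) {
  chain <- .firstChain(x, chain)
  a <- x@atoms[x@atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) return("")
  paste(a$aa[!duplicated(paste(a$resno, a$ins))], collapse = "")
})

#' @describeIn extractRegion closed-interval slice in author numbering
#' @export
setMethod("extractRegion", "ProteinStructure", function(x, chain, first, last) {
  chain <- .firstChain(x, chain)
  if (first > last) .c2Stop("c2RangeError", "first must be <= last")
  keep <- x@atoms$chain == chain & x@atoms$resno >= first & x@atoms$resno <= last
  if (!any(keep))
    .c2Stop("c2RangeError",
            sprintf("range %d-%d does not intersect chain %s", first, last, chain))
  new("ProteinStructure", id = x@id, atoms = x@atoms[keep, , drop = FALSE],
      hetero = x@hetero)
})

#' @describeIn caCoords C-alpha coordinates with residue-number rownames
#' @export
setMethod("caCoords", "ProteinStructure", function(x, chain, resno = NULL) {
  chain <- .firstChain(x, chain)
  a <- x@atoms[x@atoms$chain == chain & x@atoms$elety == "CA", , drop = FALSE]
  if (!is.null(resno)) a <- a[a$resno %in% resno, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
})

setMethod("show", "ProteinStructure", function(object) {
  ch <- chains(object)
  nres <- vapply(ch, function(c) length(residueNumbers(object, c)), integer(1))
  cat(sprintf("ProteinStructure '%s': %d chain(s), %d residues, %d atoms\n",
              object@id, length(ch), sum(nres), nrow(object@atoms)))
  for (i in seq_along(ch))
    cat(sprintf("  chain %s: %d residues\n", ch[i], nres[i]))
})

#' Coordinates of one backbone atom type per residue
#'
#' @param x a ProteinStructure.
#' @param chain chain id.
#' @param elety atom name ("N", "CA", "C", "O", "H").
#' @return matrix (n x 3) with rownames = residue numbers (residues lacking
#'   the atom are absent).
#' @export
atomCoords <- function(x, chain, elety) {
  chain <- .firstChain(x, chain)
  a <- x@atoms[x@atoms$chain == chain & x@atoms$elety == elety, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub(" .*", "", names(ss)))
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFastaSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Assemble a ProteinStructure from per-residue atom lists
#'
#' Builds a structure from a list of residues, each a named list of atom
#' 3-vectors (as produced by \code{\link{buildStrand}}). Residues are
#' numbered consecutively from \code{firstResno}.
#'
#' @param residues list of named lists of 3-vectors.
#' @param aa one-letter codes (recycled if length 1).
#' @param id structure identifier.
#' @param chain chain identifier.
#' @param firstResno number of the first residue.
#' @return a \linkS4class{ProteinStructure}.
#' @export
structureFromResidues <- function(residues, aa = "A", id = "model",
                                  chain = "A", firstResno = 1L) {
  aa <- rep_len(aa, length(residues))
  rows <- lapply(seq_along(residues), function(i) {
    at <- residues[[i]]
    data.frame(chain = chain, resno = firstResno + i - 1L, ins = "", aa = aa[i],
               elety = names(at),
               x = vapply(at, `[[`, numeric(1), 1L),
               y = vapply(at, `[[`, numeric(1), 2L),
               z = vapply(at, `[[`, numeric(1), 3L),
               occ = 1, stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  new("ProteinStructure", id = id, atoms = atoms, hetero = data.frame())
}
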