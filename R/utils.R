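## Small shared helpers. Errors carry package-specific condition classes so
## callers (and the CLI wrapper) can react per failure mode.

.c2Stop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "c2Error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))
.standardAA <- unname(.aa3to1)

.aaOne <- function(resid3) {
  out <- unname(.aa3to1[toupper(resid3)])
  out[is.na(out)] <- "X"
  out
}

.firstChain <- function(x, chain) {
  if (missing(chain) || is.null(chain)) {
    ch <- chains(x)
    if (length(ch) == 0L) .c2Stop("c2KeyError", "structure has no chains")
    ch[1L]
  } else {
    if (!chain %in% chains(x))
      .c2Stop("c2KeyError", sprintf("no chain '%s' in structure '%s'", chain, x@id))
    chain
  }
}

## Euclidean norm / unit vector for 3-vectors.
.vnorm <- function(v) sqrt(sum(v * v))
.vunit <- function(v) v / .vnorm(v)

## Pairwise distance matrix between two n x 3 coordinate sets.
.crossDist <- function(a, b) {
  a2 <- rowSums(a * a); b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

## Closed-interval length in author numbering.
.intervalLength <- function(iv) max(0L, iv[2L] - iv[1L] + 1L)
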