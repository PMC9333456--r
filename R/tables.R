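## Packaged fixtures: the two printed reference tables of the ferlin study,
## shipped verbatim as TSV under inst/extdata. The FerI table carries the
## gapped alignment rows (spans, sequences and published pI values); the TM
## table carries the predicted transmembrane span boundaries, conserved
## proline positions and extracellular counts. Two rows are internally
## inconsistent as printed (lengths versus spans); the loaders return the
## cells exactly as published and leave reconciliation to the caller.

.extdata <- function(name)
  system.file("extdata", name, package = "C2Cartographer", mustWork = TRUE)

#' FerI region table (six human ferlins)
#'
#' The published FerI alignment rows: span in the full-length protein,
#' gapped sequence and published isoelectric point. Sequences are returned
#' exactly as printed (use \code{\link{sequenceSegment}} to strip gaps).
#'
#' @return data.frame with columns ferlin, length, span_first, span_last,
#'   sequence, pI.
#' @export
ferlinFerITable <- function() {
  utils::read.delim(.extdata("feri_table.tsv"), stringsAsFactors = FALSE)
}

#' Transmembrane span table (six human ferlins)
#'
#' The published TM span boundaries, printed span lengths, conserved proline
#' positions and extracellular intervals with their printed counts.
#'
#' @return data.frame with columns ferlin, tm_length, tm_first, tm_last,
#'   conserved_pro, extra_first, extra_last, extra_count.
#' @export
ferlinTmTable <- function() {
  utils::read.delim(.extdata("tm_table.tsv"), stringsAsFactors = FALSE)
}

#' Both packaged ferlin tables
#' @return list with elements \code{feri} and \code{tm}.
#' @export
fixtureTables <- function() list(feri = ferlinFerITable(), tm = ferlinTmTable())
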