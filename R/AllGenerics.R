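#' Chains of a structure
#' @param x a ProteinStructure.
#' @return character vector of chain identifiers in file order.
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' Residue numbers of one chain
#' @param x a ProteinStructure.
#' @param chain chain identifier; defaults to the first chain.
#' @return integer vector of author residue numbers in order.
#' @export
setGeneric("residueNumbers", function(x, chain) standardGeneric("residueNumbers"))

#' One-letter sequence of one chain
#' @param x a ProteinStructure.
#' @param chain chain identifier; defaults to the first chain.
#' @return single character string, unknown residues as 'X'.
#' @export
setGeneric("chainSequence", function(x, chain) standardGeneric("chainSequence"))

#' Slice a closed residue interval out of a chain
#' @param x a ProteinStructure.
#' @param chain chain identifier.
#' @param first,last closed interval bounds in author numbering.
#' @return a ProteinStructure containing the residues with
#'   \code{first <= resno <= last}.
#' @export
setGeneric("extractRegion", function(x, chain, first, last) standardGeneric("extractRegion"))

#' C-alpha coordinates
#' @param x a ProteinStructure.
#' @param chain chain identifier; defaults to the first chain.
#' @param resno optional integer vector restricting the residues.
#' @return numeric matrix (n x 3) with rownames = residue numbers.
#' @export
setGeneric("caCoords", function(x, chain, resno = NULL) standardGeneric("caCoords"))

#' Strand table of a topology or annotation
#' @param x a SheetTopology or C2Annotation.
#' @return data.frame of strand intervals.
#' @export
setGeneric("strands", function(x) standardGeneric("strands"))

#' Boundary interval of an annotation
#' @param x a C2Annotation.
#' @return integer(2) closed interval.
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' Topology label of an annotation
#' @param x a C2Annotation.
#' @return "Type-I", "Type-II" or "ambiguous".
#' @export
setGeneric("topologyType", function(x) standardGeneric("topologyType"))

#' Loop intervals of an annotation
#' @param x a C2Annotation.
#' @return named list of integer(2) closed intervals.
#' @export
setGeneric("loops", function(x) standardGeneric("loops"))
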