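#' @include AllClasses.R
NULL

#' @rdname StructureModel-class
#' @param x a `StructureModel`
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname StructureModel-class
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname StructureModel-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname StructureModel-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ProteinSequence-class
#' @param x a `ProteinSequence`
#' @export
setGeneric("seqLetters", function(x) standardGeneric("seqLetters"))

#' @rdname ProteinSequence-class
#' @export
setGeneric("seqNumbering", function(x) standardGeneric("seqNumbering"))
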