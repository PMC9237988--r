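#' @rdname BsAlignments-class
#' @param x a `BsAlignments` object.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname BsAlignments-class
#' @export
setGeneric("samHeader", function(x) standardGeneric("samHeader"))

#' @rdname BsAlignments-class
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' Look up reference bases
#'
#' Returns the uppercase reference sequence of a 0-based half-open interval.
#'
#' @param ref a [FastaReference-class] object.
#' @param contig contig name.
#' @param start0 0-based start.
#' @param end0 0-based exclusive end.
#' @return a character string of `end0 - start0` bases.
#' @export
setGeneric("refBases", function(ref, contig, start0, end0) standardGeneric("refBases"))

#' @rdname DiploidTruth-class
#' @param x a `DiploidTruth` object.
#' @export
setGeneric("truthVariants", function(x) standardGeneric("truthVariants"))

#' @rdname DiploidTruth-class
#' @export
setGeneric("referenceSequences", function(x) standardGeneric("referenceSequences"))

#' @rdname DiploidTruth-class
#' @param hap `"h1"` or `"h2"`.
#' @export
setGeneric("haplotypeSequences", function(x, hap) standardGeneric("haplotypeSequences"))

#' @rdname BenchmarkCurve-class
#' @param x a `BenchmarkCurve` object.
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))
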