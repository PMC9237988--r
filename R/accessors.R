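#' @rdname BsAlignments-class
#' @export
setMethod("records", "BsAlignments", function(x) x@records)

#' @rdname BsAlignments-class
#' @export
setMethod("samHeader", "BsAlignments", function(x) x@header)

#' @rdname BsAlignments-class
#' @export
setMethod("nRecords", "BsAlignments", function(x) nrow(x@records))

setMethod("show", "BsAlignments", function(object) {
  rec <- object@records
  mapped <- if (nrow(rec)) sum(!bitwAnd(rec$flag, 4L)) else 0L
  cat("BsAlignments with", nrow(rec), "records (", mapped, "mapped ) over",
      length(unique(rec$rname[rec$rname != "*"])), "contigs\n")
  if (nrow(rec) > 0) {
    head_n <- min(5L, nrow(rec))
    print(rec[seq_len(head_n), c("qname", "flag", "rname", "pos0", "mapq", "cigar")])
    if (nrow(rec) > head_n) cat("...", nrow(rec) - head_n, "more\n")
  }
})

setMethod("show", "FastaReference", function(object) {
  cat("FastaReference with", length(object@sequences), "contigs:\n")
  w <- Biostrings::width(object@sequences)
  for (i in seq_along(object@sequences))
    cat(" ", names(object@sequences)[i], ":", w[i], "bp\n")
})

#' @rdname refBases
#' @export
setMethod("refBases", "FastaReference", function(ref, contig, start0, end0) {
  if (!contig %in% names(ref@sequences))
    stop("unknown contig: ", contig)
  seq <- ref@sequences[[contig]]
  if (start0 < 0 || end0 > length(seq) || end0 < start0)
    stop("interval out of range for contig ", contig)
  if (end0 == start0) return("")
  as.character(Biostrings::subseq(seq, start = start0 + 1L, end = end0))
})

setMethod("show", "MaskStats", function(object) {
  cat("MaskStats\n")
  cat("  records seen:          ", object@recordsSeen, "\n")
  cat("  records masked:        ", object@recordsMasked,
      sprintf("(CT %d, GA %d)", as.integer(object@ctRecords), as.integer(object@gaRecords)), "\n")
  cat("  records passed through:", object@recordsPassedThrough, "\n")
  cat("  bases replaced:        ", object@basesReplaced, "\n")
  cat("  bases BQ-zeroed:       ", object@basesBqZeroed, "\n")
})

#' Mask statistics accessors
#'
#' @param x a [MaskStats-class] object.
#' @return a single number.
#' @name maskstats-accessors
NULL

#' @rdname maskstats-accessors
#' @export
recordsSeen <- function(x) x@recordsSeen
#' @rdname maskstats-accessors
#' @export
recordsMasked <- function(x) x@recordsMasked
#' @rdname maskstats-accessors
#' @export
recordsPassedThrough <- function(x) x@recordsPassedThrough
#' @rdname maskstats-accessors
#' @export
basesReplaced <- function(x) x@basesReplaced
#' @rdname maskstats-accessors
#' @export
basesBqZeroed <- function(x) x@basesBqZeroed

#' @rdname DiploidTruth-class
#' @export
setMethod("truthVariants", "DiploidTruth", function(x) x@variants)

#' @rdname DiploidTruth-class
#' @export
setMethod("referenceSequences", "DiploidTruth", function(x) x@reference)

#' @rdname DiploidTruth-class
#' @export
setMethod("haplotypeSequences", "DiploidTruth", function(x, hap = c("h1", "h2")) {
  hap <- match.arg(hap)
  x@haplotypes[[hap]]
})

setMethod("show", "DiploidTruth", function(object) {
  v <- object@variants
  cat("DiploidTruth:", length(object@reference), "contigs,",
      sum(Biostrings::width(object@reference)), "bp,",
      nrow(v), "truth SNVs (", sum(v$genotype == "het"), "het /",
      sum(v$genotype == "hom-alt"), "hom-alt ), seed", object@seed, "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %s %dbp @ %gX, conversion %.3g, error %.3g, BQ %d (%s), seed %d\n",
              object@layout, object@readLength, object@depth,
              object@conversionRate, object@errorRate, object@baseQuality,
              object@bqProfile, object@seed))
})

setMethod("show", "PileupColumn", function(object) {
  cat(sprintf("PileupColumn %s:%d ref=%s DP=%d\n", object@contig,
              object@pos0 + 1L, object@refBase, nrow(object@observations)))
  if (nrow(object@observations) > 0)
    print(table(object@observations$base))
})

setMethod("show", "GenotypeCall", function(object) {
  cat(sprintf("GenotypeCall %s:%d %s>%s GT=%s QUAL=%.1f GQ=%.1f DP=%d\n",
              object@contig, object@pos, object@ref,
              if (length(object@alt)) paste(object@alt, collapse = ",") else ".",
              object@genotype, object@qual, object@gq, object@dp))
})

#' @rdname BenchmarkCurve-class
#' @export
setMethod("curveTable", "BenchmarkCurve", function(x) x@table)

setMethod("show", "BenchmarkCurve", function(object) {
  cat("BenchmarkCurve over", toupper(object@scoreField), "with",
      nrow(object@table), "thresholds\n")
  print(utils::head(object@table, 10))
})
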