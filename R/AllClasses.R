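#' @useDynLib bsmask, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.REQUIRED_RECORD_COLS <- c("qname", "flag", "rname", "pos0", "mapq", "cigar",
                           "rnext", "pnext0", "tlen", "seq", "qual", "tags")

#' Container for SAM/BAM alignment records
#'
#' A thin S4 wrapper around a header (the verbatim `@`-lines of a SAM file)
#' and a record table holding one row per alignment. All reference
#' coordinates are stored 0-based (`pos0`, `pnext0`); conversion to the
#' 1-based SAM/VCF convention happens only at file boundaries. Optional
#' fields (tags) are kept as the verbatim tab-joined string so that
#' unrecognised tags round-trip losslessly.
#'
#' @slot header character vector of SAM header lines (each starting with `@`).
#' @slot records data.frame with columns `qname`, `flag`, `rname`, `pos0`,
#'   `mapq`, `cigar`, `rnext`, `pnext0`, `tlen`, `seq`, `qual`, `tags`.
#' @export
setClass("BsAlignments",
         slots = c(header = "character", records = "data.frame"))

setValidity("BsAlignments", function(object) {
  rec <- object@records
  missing_cols <- setdiff(.REQUIRED_RECORD_COLS, names(rec))
  if (length(missing_cols) > 0)
    return(paste("records is missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(rec) == 0) return(TRUE)
  has_seq <- rec$seq != "*"
  has_qual <- rec$qual != "*"
  both <- has_seq & has_qual
  if (any(both) && any(nchar(rec$seq[both]) != nchar(rec$qual[both])))
    return("seq and qual lengths differ for records with stored sequence")
  mapped <- !bitwAnd(rec$flag, 4L)
  if (any(mapped & rec$pos0 < 0))
    return("mapped record with negative position")
  ql <- cigarQueryLength(rec$cigar)
  chk <- mapped & has_seq & !is.na(ql)
  if (any(ql[chk] != nchar(rec$seq[chk])))
    return("CIGAR query length does not match sequence length")
  TRUE
})

#' Reference sequence provider backed by a FASTA-style sequence set
#'
#' Wraps a [Biostrings::DNAStringSet] (uppercased at construction) and serves
#' the `(contig, 0-based half-open interval) -> nucleotide string` lookup
#' contract used throughout the package. The alternative reference source,
#' per-record MD tags, needs no object: functions taking a `reference`
#' argument fall back to MD reconstruction when it is `NULL`.
#'
#' @slot sequences a `DNAStringSet`, one entry per contig.
#' @export
setClass("FastaReference", slots = c(sequences = "DNAStringSet"))

setValidity("FastaReference", function(object) {
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    return("contig names must be present and unique")
  bad <- !grepl("^[ACGTN]*$", as.character(object@sequences))
  if (any(bad))
    return("reference contains characters outside A/C/G/T/N")
  TRUE
})

#' Tallies of the double-masking procedure
#'
#' @slot recordsSeen,recordsMasked,recordsPassedThrough record counts;
#'   every record is either masked (mapped, with sequence, CT or GA context)
#'   or passed through untouched.
#' @slot basesReplaced number of read bases rewritten to the reference base
#'   (aligned ref-C/read-T or ref-G/read-A columns).
#' @slot basesBqZeroed number of read bases whose base quality was set to 0;
#'   always at least `basesReplaced`.
#' @slot ctRecords,gaRecords masked-record counts per conversion context.
#' @export
setClass("MaskStats",
         slots = c(recordsSeen = "numeric", recordsMasked = "numeric",
                   recordsPassedThrough = "numeric", basesReplaced = "numeric",
                   basesBqZeroed = "numeric", ctRecords = "numeric",
                   gaRecords = "numeric"))

setValidity("MaskStats", function(object) {
  if (object@basesReplaced > object@basesBqZeroed)
    return("basesReplaced must not exceed basesBqZeroed")
  if (object@recordsSeen != object@recordsMasked + object@recordsPassedThrough)
    return("recordsSeen must equal recordsMasked + recordsPassedThrough")
  TRUE
})

#' Synthetic diploid genome with known truth variants
#'
#' @slot reference `DNAStringSet` of contig sequences.
#' @slot haplotypes list of two `DNAStringSet`s (`h1`, `h2`), each obtained by
#'   applying the truth variants to the reference.
#' @slot variants data.frame with columns `contig`, `pos0`, `ref`, `alt`,
#'   `genotype` (`"het"` or `"hom-alt"`), `hap` (1 or 2 for heterozygous
#'   variants, 0 for homozygous ones). SNVs only.
#' @slot seed integer seed the genome was generated from.
#' @export
setClass("DiploidTruth",
         slots = c(reference = "DNAStringSet", haplotypes = "list",
                   variants = "data.frame", seed = "integer"))

setValidity("DiploidTruth", function(object) {
  v <- object@variants
  if (nrow(v) > 0) {
    if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L))
      return("variants must be SNVs (single-base ref and alt)")
    for (ctg in unique(v$contig)) {
      p <- v$pos0[v$contig == ctg]
      if (any(diff(p) <= 0))
        return("variant positions must be strictly increasing per contig")
    }
  }
  if (!identical(sort(names(object@haplotypes)), c("h1", "h2")))
    return("haplotypes must be a list with elements h1 and h2")
  for (h in c("h1", "h2")) {
    rebuilt <- .applyVariants(object@reference, v, h)
    if (!identical(as.character(rebuilt), as.character(object@haplotypes[[h]])))
      return(sprintf("haplotype %s is not the reference plus its variants", h))
  }
  TRUE
})

#' Per-cytosine methylation states for a diploid genome
#'
#' Methylation is assigned per haplotype and per strand: for every cytosine
#' of a haplotype strand, its context (CG/CHG/CHH, read 5'->3' along that
#' strand) is determined and a methylated/unmethylated state is drawn from
#' the per-context probability. States are stored as full-length logical
#' vectors in Watson coordinates for O(1) lookup during read simulation
#' (Crick-strand cytosines sit at Watson guanine positions).
#'
#' @slot levels named numeric vector of methylation probabilities for
#'   `CG`, `CHG`, `CHH`.
#' @slot states nested list `states[[contig]][[hap]][[strand]]`, with
#'   `hap` in `h1`/`h2` and `strand` in `watson`/`crick`; each entry is a
#'   logical vector over contig positions (TRUE = methylated; only cytosine
#'   positions of that strand are meaningful).
#' @slot seed integer seed.
#' @export
setClass("MethylationProfile",
         slots = c(levels = "numeric", states = "list", seed = "integer"))

setValidity("MethylationProfile", function(object) {
  if (!all(c("CG", "CHG", "CHH") %in% names(object@levels)))
    return("levels must be named CG, CHG, CHH")
  if (any(object@levels < 0 | object@levels > 1))
    return("methylation levels must be probabilities")
  TRUE
})

#' Simulation configuration for synthetic WGBS libraries
#'
#' @slot depth target mean fold-coverage.
#' @slot readLength read length in bases.
#' @slot fragmentMean,fragmentSd fragment length distribution (PE only).
#' @slot layout `"SE"` or `"PE"`.
#' @slot directional logical; the simulator emits directional libraries
#'   (mate 1 reads the original converted strand).
#' @slot conversionRate probability that an unmethylated cytosine is
#'   bisulfite-converted on any one molecule.
#' @slot errorRate per-base sequencing error probability (uniform over the
#'   three alternative bases).
#' @slot baseQuality phred base quality assigned to simulated bases.
#' @slot bqProfile `"constant"` or `"decay"` (linear 3' fall-off of 20 phred
#'   across the read).
#' @slot seed integer seed.
#' @export
setClass("SimConfig",
         slots = c(depth = "numeric", readLength = "integer",
                   fragmentMean = "numeric", fragmentSd = "numeric",
                   layout = "character", directional = "logical",
                   conversionRate = "numeric", errorRate = "numeric",
                   baseQuality = "integer", bqProfile = "character",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@depth <= 0) return("depth must be positive")
  for (p in c("conversionRate", "errorRate"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      return(paste(p, "must be in [0, 1]"))
  if (!object@layout %in% c("SE", "PE")) return("layout must be SE or PE")
  if (!object@bqProfile %in% c("constant", "decay"))
    return("bqProfile must be constant or decay")
  if (object@layout == "PE" && object@fragmentMean < object@readLength)
    return("infeasible configuration: fragmentMean < readLength")
  TRUE
})

#' One pileup column: the filtered observations at a reference site
#'
#' @slot contig contig name.
#' @slot pos0 0-based reference position.
#' @slot refBase reference base at the site.
#' @slot observations data.frame with columns `base`, `bq`, `mapq`,
#'   `context` (one row per surviving read base).
#' @export
setClass("PileupColumn",
         slots = c(contig = "character", pos0 = "integer",
                   refBase = "character", observations = "data.frame"))

#' A diploid genotype call at one site
#'
#' @slot contig contig name.
#' @slot pos 1-based position (VCF convention).
#' @slot ref reference allele.
#' @slot alt character vector of alternate alleles (may be empty).
#' @slot genotype unphased genotype as a sorted allele pair, e.g. `"C/T"`.
#' @slot qual phred-scaled confidence that the site is non-reference.
#' @slot gq phred-scaled confidence in the assigned genotype.
#' @slot dp filtered observation count.
#' @slot posteriors named numeric vector of the 10 genotype posteriors.
#' @export
setClass("GenotypeCall",
         slots = c(contig = "character", pos = "integer", ref = "character",
                   alt = "character", genotype = "character", qual = "numeric",
                   gq = "numeric", dp = "integer", posteriors = "numeric"))

setValidity("GenotypeCall", function(object) {
  if (abs(sum(object@posteriors) - 1) > 1e-6)
    return("posteriors must sum to 1")
  TRUE
})

#' Precision/sensitivity/F1 as a function of a score threshold
#'
#' @slot scoreField which score was swept: `"qual"`, `"gq"` or `"dp"`.
#' @slot table data.frame with columns `threshold`, `tp`, `fp`, `fn`,
#'   `precision`, `sensitivity`, `f1`.
#' @export
setClass("BenchmarkCurve",
         slots = c(scoreField = "character", table = "data.frame"))

setValidity("BenchmarkCurve", function(object) {
  tab <- object@table
  need <- c("threshold", "tp", "fp", "fn", "precision", "sensitivity", "f1")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tab) > 1 && length(unique(tab$tp + tab$fn)) != 1)
    return("tp + fn must be constant across thresholds")
  TRUE
})
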