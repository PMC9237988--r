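# The double-masking procedure: conversion-context determination from SAM
# flags and the two masking rules (reference-base replacement at aligned
# ref-C/read-T or ref-G/read-A columns, and base-quality zeroing of every
# potentially bisulfite-converted base).

#' Determine the bisulfite conversion context of an alignment
#'
#' A mapped bisulfite alignment can carry either C->T conversion artifacts
#' (mate 1 on the Watson strand, FW+, and mate 2 on the Crick strand, RC-)
#' or G->A artifacts in reference orientation (mate 1 on Crick, FW-, and
#' mate 2 on Watson, RC+). Single-end reads behave like mate 1. The context
#' is a pure function of the first/second-in-pair and reverse flags, so the
#' procedure applies identically to directional and non-directional
#' libraries: it follows whatever strand/mate decision the aligner made.
#'
#' @param paired,secondInPair,reverse,mapped logical flags (vectorised).
#' @return character vector with values `"CT"`, `"GA"` or `"NONE"`.
#' @examples
#' conversionContext(paired = TRUE, secondInPair = FALSE, reverse = FALSE)  # "CT"
#' conversionContext(paired = TRUE, secondInPair = TRUE, reverse = TRUE)    # "CT"
#' conversionContext(paired = FALSE, secondInPair = FALSE, reverse = TRUE)  # "GA"
#' @export
conversionContext <- function(paired, secondInPair, reverse, mapped = TRUE) {
  n <- max(length(paired), length(secondInPair), length(reverse), length(mapped))
  paired <- rep_len(paired, n); secondInPair <- rep_len(secondInPair, n)
  reverse <- rep_len(reverse, n); mapped <- rep_len(mapped, n)
  if (any(secondInPair & !paired))
    stop("inconsistent flags: second-in-pair set on unpaired record")
  mate1 <- !paired | !secondInPair
  # mate1-forward or mate2-reverse -> CT; mate1-reverse or mate2-forward -> GA
  ctx <- ifelse(mate1 != reverse, "CT", "GA")
  ctx[!mapped] <- "NONE"
  ctx
}

#' @rdname conversionContext
#' @param flag integer SAM flag(s).
#' @export
flagContext <- function(flag) {
  conversionContext(paired = flagPaired(flag),
                    secondInPair = flagSecondInPair(flag),
                    reverse = flagReverse(flag),
                    mapped = !flagUnmapped(flag))
}

.maskStats <- function(seen = 0, masked = 0, passed = 0, replaced = 0,
                       zeroed = 0, ct = 0, ga = 0) {
  new("MaskStats", recordsSeen = seen, recordsMasked = masked,
      recordsPassedThrough = passed, basesReplaced = replaced,
      basesBqZeroed = zeroed, ctRecords = ct, gaRecords = ga)
}

#' Double-mask a single alignment record
#'
#' Reference implementation of the two masking rules on one record, built on
#' the per-column view of [alignedColumns()]. In a CT context: (i) every
#' aligned column with reference C and read T has its base set to C and its
#' quality to 0; (ii) every remaining read T (mismatch at a non-C reference,
#' match at a reference T, insertion or soft-clip) keeps its base but has
#' its quality set to 0. The GA context is the mirror image (reference G,
#' read A). Read-base N is never touched. Flags, CIGAR, position and MAPQ
#' are unchanged; MD and NM are recomputed unless `keepTags` is set.
#'
#' @param x a [BsAlignments-class] object.
#' @param i record index.
#' @param reference optional [FastaReference-class]; when `NULL` the MD tag
#'   is used.
#' @param scope `"all-t"` zeroes every convertible read base (the default:
#'   any such base may have arisen from conversion); `"ref-c-only"` zeroes
#'   only the replaced bases.
#' @param keepTags do not recompute MD/NM after base replacement.
#' @return list with `record` (a one-row record data.frame), `context`,
#'   `replaced` and `zeroed` counts.
#' @export
maskRecord <- function(x, i, reference = NULL,
                       scope = c("all-t", "ref-c-only"), keepTags = FALSE) {
  scope <- match.arg(scope)
  rec <- x@records[i, , drop = FALSE]
  ctx <- flagContext(rec$flag)
  if (ctx == "NONE" || rec$seq == "*")
    return(list(record = rec, context = ctx, replaced = 0L, zeroed = 0L))
  cols <- alignedColumns(x, i, reference = reference)
  target <- if (ctx == "CT") "T" else "A"
  reftgt <- if (ctx == "CT") "C" else "G"
  ch <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  bq <- qualToInt(rec$qual)
  isTarget <- cols$readBase == target
  replace <- isTarget & !is.na(cols$refBase) & cols$refBase == reftgt
  zero <- if (scope == "all-t") isTarget else replace
  ch[cols$readIndex0[replace] + 1L] <- reftgt
  bq[cols$readIndex0[zero] + 1L] <- 0L
  rec$seq <- paste(ch, collapse = "")
  rec$qual <- intToQual(bq)
  if (!keepTags) {
    upd <- recomputeMdNm(rec, cols, deletedRefBases(x@records[i, , drop = FALSE],
                                                    reference))
    rec$tags <- setTag(rec$tags, "MD", "Z", upd$md)
    rec$tags <- setTag(rec$tags, "NM", "i", upd$nm)
  }
  list(record = rec, context = ctx,
       replaced = sum(replace), zeroed = sum(zero))
}

# Reference bases consumed by the D operations of a record, in order,
# recovered from the MD tag when present or from FASTA otherwise.
deletedRefBases <- function(rec, reference = NULL) {
  cig <- parseCigar(rec$cigar)
  if (!any(cig$op == "D")) return(character(0))
  md <- getTag(rec$tags, "MD")
  if (!is.na(md)) return(expandMdTag(md, rec$cigar, rec$seq)$deleted)
  if (is.null(reference)) stop("no reference source for deleted bases")
  out <- character(0)
  rp <- rec$pos0
  for (k in seq_len(nrow(cig))) {
    op <- cig$op[k]; len <- cig$len[k]
    if (op %in% c("M", "=", "X", "N")) rp <- rp + len
    else if (op == "D") {
      out <- c(out, strsplit(refBases(reference, rec$rname, rp, rp + len),
                             "", fixed = TRUE)[[1]])
      rp <- rp + len
    }
  }
  out
}

# Rebuild MD/NM from the (post-masking) record using the pre-masking column
# view for reference bases.
recomputeMdNm <- function(rec, cols, deleted = character(0)) {
  cig <- parseCigar(rec$cigar)
  ch <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  refByQ <- rep(NA_character_, length(ch))
  al <- !is.na(cols$refPos0)
  refByQ[cols$readIndex0[al] + 1L] <- cols$refBase[al]
  md <- ""
  run <- 0L
  nm <- 0L
  qi <- 0L
  di <- 0L
  for (k in seq_len(nrow(cig))) {
    op <- cig$op[k]; len <- cig$len[k]
    if (op %in% c("M", "=", "X")) {
      for (j in seq_len(len)) {
        rb <- refByQ[qi + j]
        if (!is.na(rb) && ch[qi + j] == rb) {
          run <- run + 1L
        } else {
          md <- paste0(md, run, if (is.na(rb)) "N" else rb)
          run <- 0L
          nm <- nm + 1L
        }
      }
      qi <- qi + len
    } else if (op == "I") {
      qi <- qi + len
      nm <- nm + len
    } else if (op == "S") {
      qi <- qi + len
    } else if (op == "D") {
      dels <- if (length(deleted) >= di + len) deleted[di + seq_len(len)] else rep("N", len)
      md <- paste0(md, run, "^", paste(dels, collapse = ""))
      run <- 0L
      di <- di + len
      nm <- nm + len
    }
  }
  list(md = paste0(md, run), nm = nm)
}

#' Double-mask a set of alignments
#'
#' Applies [maskRecord()] semantics to every record, in input order, using a
#' compiled batch core. Unmapped and sequence-less records pass through
#' untouched. The header gains a program-group line recording the masking
#' parameters (idempotently: re-masking adds nothing). Record count, order,
#' flags, positions, CIGARs and MAPQs are invariant; only SEQ, QUAL and the
#' MD/NM tags can change.
#'
#' @inheritParams maskRecord
#' @param x a [BsAlignments-class] object.
#' @param reference a [FastaReference-class], or `NULL` to reconstruct
#'   reference bases from per-record MD tags.
#' @param strict with both MD and FASTA available, verify they agree on
#'   every aligned base and fail on conflict.
#' @return list with `alignments` (the masked [BsAlignments-class]) and
#'   `stats` (a [MaskStats-class]).
#' @export
maskAlignments <- function(x, reference = NULL,
                           scope = c("all-t", "ref-c-only"),
                           keepTags = FALSE, strict = FALSE) {
  scope <- match.arg(scope)
  rec <- x@records
  n <- nrow(rec)
  stats <- .maskStats()
  if (n == 0)
    return(list(alignments = BsAlignments(rec, maskPgHeader(x@header, scope)),
                stats = stats))
  ctx <- flagContext(rec$flag)
  maskable <- ctx != "NONE" & rec$seq != "*"
  ctxCode <- ifelse(maskable & ctx == "CT", 1L, ifelse(maskable & ctx == "GA", 2L, 0L))

  refStrings <- character(0)
  refIdx <- rep(NA_integer_, n)
  if (!is.null(reference)) {
    refStrings <- as.character(reference@sequences)
    refIdx <- match(rec$rname, names(reference@sequences))
    if (any(maskable & is.na(refIdx)))
      stop("no reference source: contig ",
           rec$rname[maskable & is.na(refIdx)][1], " absent from FASTA")
  } else {
    # reconstruct a per-record reference chunk from the MD tag
    md <- getTag(rec$tags, "MD")
    if (any(maskable & is.na(md)))
      stop("no reference source: record ", which(maskable & is.na(md))[1],
           " lacks an MD tag and no FASTA was provided")
    refStrings <- rep("", n)
    for (i in which(maskable)) {
      refStrings[i] <- mdRecordRefChunk(rec[i, , drop = FALSE], md[i])
      refIdx[i] <- i
    }
    # the chunk is positioned at the record start, so positions become 0
    res <- cpp_mask_batch(rec$seq, rec$qual, rec$cigar, rep(0L, n),
                          ctxCode, refStrings, refIdx,
                          if (scope == "all-t") 1L else 2L, !keepTags)
    return(finishMask(x, rec, res, ctx, maskable, keepTags, scope))
  }
  if (strict) checkMdAgainstFasta(rec, maskable, reference)
  res <- cpp_mask_batch(rec$seq, rec$qual, rec$cigar, rec$pos0,
                        ctxCode, refStrings, refIdx,
                        if (scope == "all-t") 1L else 2L, !keepTags)
  finishMask(x, rec, res, ctx, maskable, keepTags, scope)
}

# The reference chunk spanned by one record, rebuilt from its MD tag.
mdRecordRefChunk <- function(rec, md) {
  exp <- expandMdTag(md, rec$cigar, rec$seq)
  cig <- parseCigar(rec$cigar)
  out <- character(0)
  ai <- 0L
  di <- 0L
  for (k in seq_len(nrow(cig))) {
    op <- cig$op[k]; len <- cig$len[k]
    if (op %in% c("M", "=", "X")) {
      out <- c(out, exp$aligned[ai + seq_len(len)])
      ai <- ai + len
    } else if (op == "D") {
      out <- c(out, exp$deleted[di + seq_len(len)])
      di <- di + len
    } else if (op == "N") {
      out <- c(out, rep("N", len))
    }
  }
  paste(out, collapse = "")
}

checkMdAgainstFasta <- function(rec, maskable, reference) {
  md <- getTag(rec$tags, "MD")
  for (i in which(maskable & !is.na(md))) {
    exp <- expandMdTag(md[i], rec$cigar[i], rec$seq[i])
    chunk <- mdRecordRefChunk(rec[i, , drop = FALSE], md[i])
    span <- nchar(chunk)
    fasta <- refBases(reference, rec$rname[i], rec$pos0[i], rec$pos0[i] + span)
    if (!identical(chunk, fasta))
      stop("MD/FASTA disagreement at record ", i)
  }
  invisible(TRUE)
}

finishMask <- function(x, rec, res, ctx, maskable, keepTags, scope) {
  rec$seq <- as.character(res$seq)
  rec$qual <- as.character(res$qual)
  if (!keepTags) {
    upd <- maskable & !is.na(res$md)
    if (any(upd)) {
      rec$tags[upd] <- setTag(rec$tags[upd], "MD", "Z", res$md[upd])
      rec$tags[upd] <- setTag(rec$tags[upd], "NM", "i",
                              as.character(res$nm[upd]))
    }
  }
  stats <- .maskStats(
    seen = nrow(rec), masked = sum(maskable), passed = sum(!maskable),
    replaced = sum(res$replaced), zeroed = sum(res$zeroed),
    ct = sum(maskable & ctx == "CT"), ga = sum(maskable & ctx == "GA"))
  list(alignments = BsAlignments(rec, maskPgHeader(x@header, scope)),
       stats = stats)
}

maskPgHeader <- function(header, scope) {
  pg <- paste0("@PG\tID:bsmask\tPN:bsmask\tVN:",
               as.character(utils::packageVersion("bsmask")),
               "\tCL:mask --mask-scope ", scope)
  if (pg %in% header) header else c(header, pg)
}

#' Mask an alignment file end to end
#'
#' Reads a SAM (or BAM, with Rsamtools available) file, double-masks every
#' record and writes the result, preserving record order. A convenience
#' wrapper around [readSam()]/[maskAlignments()]/[writeSam()].
#'
#' @param input,output alignment file paths (`.sam` or `.bam`).
#' @param fasta optional reference FASTA path; when absent, MD tags must be
#'   present.
#' @inheritParams maskAlignments
#' @param statsFile optional path; masking tallies are written there as
#'   one `key<TAB>value` per line.
#' @return the [MaskStats-class], invisibly.
#' @export
maskFile <- function(input, output, fasta = NULL,
                     scope = c("all-t", "ref-c-only"), keepTags = FALSE,
                     strict = FALSE, statsFile = NULL) {
  scope <- match.arg(scope)
  isBam <- function(p) grepl("\\.bam$", p, ignore.case = TRUE)
  x <- if (isBam(input)) readBam(input) else readSam(input)
  reference <- if (!is.null(fasta)) fastaReference(fasta) else NULL
  res <- maskAlignments(x, reference, scope = scope, keepTags = keepTags,
                        strict = strict)
  if (isBam(output)) writeBam(res$alignments, output)
  else writeSam(res$alignments, output)
  if (!is.null(statsFile)) {
    s <- res$stats
    writeLines(paste(c("records_seen", "records_masked",
                       "records_passed_through", "bases_replaced",
                       "bases_bq_zeroed", "ct_records", "ga_records"),
                     c(s@recordsSeen, s@recordsMasked, s@recordsPassedThrough,
                       s@basesReplaced, s@basesBqZeroed, s@ctRecords,
                       s@gaRecords), sep = "\t"),
               statsFile)
  }
  invisible(res$stats)
}
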