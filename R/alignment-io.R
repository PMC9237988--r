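# Alignment and reference I/O: SAM text parsing/writing, BAM via Rsamtools
# conversion, FASTA-backed reference lookup, MD-tag reference reconstruction,
# and the aligned-column view every downstream module consumes.

#' Construct a BsAlignments object
#'
#' @param records a data.frame of alignment records (see
#'   [BsAlignments-class] for the required columns).
#' @param header character vector of SAM header lines.
#' @return a validated [BsAlignments-class] object.
#' @export
BsAlignments <- function(records = emptyRecords(), header = character(0)) {
  rownames(records) <- NULL
  new("BsAlignments", header = header, records = records)
}

#' @rdname BsAlignments
#' @export
emptyRecords <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos0 = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext0 = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), tags = character(0),
             stringsAsFactors = FALSE)
}

#' Read alignments from a SAM file
#'
#' Parses a SAM text file into a [BsAlignments-class] object. Positions are
#' converted to the package-internal 0-based convention; sequences are
#' uppercased; optional fields are retained verbatim.
#'
#' @param path path to a SAM file.
#' @param region optional [GenomicRanges::GRanges] (or a `"contig:start-end"`
#'   string, 1-based inclusive) restricting the result to mapped records whose
#'   reference span overlaps the region.
#' @return a [BsAlignments-class] object.
#' @export
readSam <- function(path, region = NULL) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  header <- lines[is_header]
  body <- lines[!is_header & nzchar(lines)]
  if (length(body) == 0)
    return(BsAlignments(emptyRecords(), header))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop("parse error at record ", which(nf < 11L)[1],
         ": fewer than 11 mandatory fields")
  f <- function(k) vapply(parts, `[[`, character(1), k)
  fi <- function(k) {
    v <- suppressWarnings(as.integer(f(k)))
    if (anyNA(v))
      stop("parse error at record ", which(is.na(v))[1],
           ": non-integer field ", k)
    v
  }
  tags <- vapply(parts, function(p)
    if (length(p) > 11L) paste(p[-seq_len(11L)], collapse = "\t") else "",
    character(1))
  rec <- data.frame(
    qname = f(1), flag = fi(2), rname = f(3), pos0 = fi(4) - 1L,
    mapq = fi(5), cigar = f(6), rnext = f(7), pnext0 = fi(8) - 1L,
    tlen = fi(9), seq = toupper(f(10)), qual = f(11), tags = tags,
    stringsAsFactors = FALSE)
  x <- BsAlignments(rec, header)
  if (!is.null(region)) x <- filterRegion(x, region) else x
}

# Brute region restriction by reference-span overlap (0-based half-open).
filterRegion <- function(x, region) {
  if (is.character(region)) region <- GenomicRanges::GRanges(region)
  rec <- x@records
  if (nrow(rec) == 0) return(x)
  span <- cigarRefSpan(rec$cigar)
  mapped <- !flagUnmapped(rec$flag) & !is.na(span)
  keep <- rep(FALSE, nrow(rec))
  for (i in seq_along(region)) {
    ctg <- as.character(GenomicRanges::seqnames(region)[i])
    s0 <- GenomicRanges::start(region)[i] - 1L
    e0 <- GenomicRanges::end(region)[i]
    keep <- keep | (mapped & rec$rname == ctg &
                      rec$pos0 < e0 & rec$pos0 + span > s0)
  }
  BsAlignments(rec[keep, , drop = FALSE], x@header)
}

#' Write alignments to a SAM file
#'
#' The inverse of [readSam()]: writing then re-reading reproduces every
#' field, tag and record order.
#'
#' @param x a [BsAlignments-class] object.
#' @param path output path.
#' @return invisibly, the number of records written.
#' @export
writeSam <- function(x, path) {
  rec <- x@records
  body <- character(0)
  if (nrow(rec) > 0) {
    body <- paste(rec$qname, rec$flag, rec$rname, rec$pos0 + 1L, rec$mapq,
                  rec$cigar, rec$rnext, rec$pnext0 + 1L, rec$tlen, rec$seq,
                  rec$qual, sep = "\t")
    has_tags <- nzchar(rec$tags)
    body[has_tags] <- paste(body[has_tags], rec$tags[has_tags], sep = "\t")
  }
  writeLines(c(x@header, body), path)
  invisible(nrow(rec))
}

#' @rdname readSam
#' @export
readBam <- function(path, region = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM support needs the Rsamtools package; use SAM input instead")
  dest <- tempfile(fileext = "")
  sam <- Rsamtools::asSam(path, dest)
  on.exit(unlink(sam))
  readSam(sam, region = region)
}

#' @rdname writeSam
#' @export
writeBam <- function(x, path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM support needs the Rsamtools package; use SAM output instead")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  n <- writeSam(x, sam)
  dest <- sub("\\.bam$", "", path)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = FALSE)
  invisible(n)
}

#' Construct a FASTA-backed reference provider
#'
#' Soft-masked (lowercase) bases are uppercased; characters outside
#' A/C/G/T/N are rejected. Contig names are taken up to the first whitespace
#' of the FASTA header.
#'
#' @param x a FASTA file path, a [Biostrings::DNAStringSet], or a named
#'   character vector of contig sequences.
#' @return a [FastaReference-class] object.
#' @export
fastaReference <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (!methods::is(x, "DNAStringSet"))
    stop("x must be a FASTA path, DNAStringSet or named character vector")
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("reference contains characters outside A/C/G/T/N")
  new("FastaReference", sequences = Biostrings::DNAStringSet(seqs))
}

#' Reconstruct aligned reference bases from an MD tag
#'
#' Expands a SAM MD tag against the record's CIGAR and sequence, yielding the
#' reference base under every aligned (M/=/X) query position plus the bases
#' removed by deletions, without consulting a FASTA.
#'
#' @param md the MD tag value.
#' @param cigar the record's CIGAR string.
#' @param seq the record's sequence (reference orientation).
#' @return list with `aligned` (character vector, one uppercase reference
#'   base per aligned query position, in query order) and `deleted`
#'   (reference bases consumed by D operations, in order).
#' @export
expandMdTag <- function(md, cigar, seq) {
  cig <- parseCigar(cigar)
  readCh <- strsplit(seq, "", fixed = TRUE)[[1]]
  alignedIdx <- integer(0)
  qi <- 0L
  nDel <- 0L
  for (k in seq_len(nrow(cig))) {
    op <- cig$op[k]; len <- cig$len[k]
    if (op %in% c("M", "=", "X")) {
      alignedIdx <- c(alignedIdx, qi + seq_len(len))
      qi <- qi + len
    } else if (op %in% c("I", "S")) {
      qi <- qi + len
    } else if (op == "D") {
      nDel <- nDel + len
    }
  }
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  if (sum(nchar(toks)) != nchar(md))
    stop("malformed MD: ", md)
  aligned <- character(length(alignedIdx))
  deleted <- character(0)
  j <- 0L
  for (tok in toks) {
    first <- substr(tok, 1L, 1L)
    if (first >= "0" && first <= "9") {
      n <- as.integer(tok)
      if (n > 0L) {
        if (j + n > length(alignedIdx)) stop("malformed MD: ", md)
        aligned[j + seq_len(n)] <- readCh[alignedIdx[j + seq_len(n)]]
        j <- j + n
      }
    } else if (first == "^") {
      deleted <- c(deleted, strsplit(toupper(substr(tok, 2L, nchar(tok))),
                                     "", fixed = TRUE)[[1]])
    } else {
      if (j + 1L > length(alignedIdx)) stop("malformed MD: ", md)
      j <- j + 1L
      aligned[j] <- toupper(tok)
    }
  }
  if (j != length(alignedIdx) || length(deleted) != nDel)
    stop("malformed MD: ", md, " (covers ", j, " aligned and ",
         length(deleted), " deleted bases; CIGAR ", cigar, " implies ",
         length(alignedIdx), " and ", nDel, ")")
  list(aligned = aligned, deleted = deleted)
}

#' Per-base aligned-column view of one alignment record
#'
#' Walks the CIGAR of record `i` and returns one row per query-consuming
#' position. Aligned (M/=/X) columns carry the 0-based reference position and
#' reference base (from the MD tag, or from `reference` when no MD is
#' available); insertion and soft-clip columns carry the read base and
#' quality only. D/N operations consume reference silently; H/P produce
#' nothing.
#'
#' @param x a [BsAlignments-class] object.
#' @param i record index (scalar).
#' @param reference optional [FastaReference-class].
#' @param source `"auto"` (MD if present, else FASTA), `"md"` or `"fasta"`.
#' @param strict when both MD and FASTA are available, verify that they
#'   agree on every aligned base and fail on conflict.
#' @return data.frame with columns `readIndex0`, `refPos0` (NA off-reference),
#'   `readBase`, `refBase` (NA off-reference), `bq`, `op`.
#' @export
alignedColumns <- function(x, i, reference = NULL,
                           source = c("auto", "md", "fasta"), strict = FALSE) {
  source <- match.arg(source)
  rec <- x@records[i, , drop = FALSE]
  if (flagUnmapped(rec$flag)) stop("record is not mapped")
  if (rec$seq == "*") stop("record has no stored sequence")
  md <- getTag(rec$tags, "MD")
  if (source == "md" && is.na(md)) stop("no reference source: MD tag absent")
  if (source == "fasta" && is.null(reference))
    stop("no reference source: FASTA not provided")
  useMd <- !is.na(md) && source != "fasta"
  useFasta <- !is.null(reference) && (source == "fasta" || !useMd || strict)
  if (!useMd && !useFasta)
    stop("no reference source: record lacks an MD tag and no FASTA was provided")

  cig <- parseCigar(rec$cigar)
  readCh <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  bq <- qualToInt(rec$qual)
  if (length(bq) == 0) bq <- rep(NA_integer_, length(readCh))

  qi <- 0L; rp <- rec$pos0
  readIndex0 <- integer(0); refPos0 <- integer(0); op <- character(0)
  for (k in seq_len(nrow(cig))) {
    o <- cig$op[k]; len <- cig$len[k]
    if (o %in% c("M", "=", "X")) {
      readIndex0 <- c(readIndex0, qi + seq_len(len) - 1L)
      refPos0 <- c(refPos0, rp + seq_len(len) - 1L)
      op <- c(op, rep(o, len))
      qi <- qi + len; rp <- rp + len
    } else if (o %in% c("I", "S")) {
      readIndex0 <- c(readIndex0, qi + seq_len(len) - 1L)
      refPos0 <- c(refPos0, rep(NA_integer_, len))
      op <- c(op, rep(o, len))
      qi <- qi + len
    } else if (o %in% c("D", "N")) {
      rp <- rp + len
    }
  }
  aligned <- !is.na(refPos0)
  refBase <- rep(NA_character_, length(readIndex0))
  if (useMd) {
    exp <- expandMdTag(md, rec$cigar, rec$seq)
    refBase[aligned] <- exp$aligned
  }
  if (useFasta) {
    fb <- vapply(refPos0[aligned], function(p)
      refBases(reference, rec$rname, p, p + 1L), character(1))
    if (useMd && (strict || source == "auto")) {
      if (strict && any(fb != refBase[aligned]))
        stop("MD/FASTA disagreement at record ", i, " (aligned offset ",
             which(fb != refBase[aligned])[1], ")")
    } else {
      refBase[aligned] <- fb
    }
  }
  data.frame(readIndex0 = readIndex0, refPos0 = refPos0,
             readBase = readCh[readIndex0 + 1L], refBase = refBase,
             bq = bq[readIndex0 + 1L], op = op, stringsAsFactors = FALSE)
}
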