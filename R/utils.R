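# Shared low-level helpers: CIGAR arithmetic, tag access, phred encoding.

.CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
.CIGAR_REF_OPS <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR string.
#' @return data.frame with columns `op` (character) and `len` (integer);
#'   zero rows for `"*"`.
#' @keywords internal
parseCigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*")
    return(data.frame(op = character(0), len = integer(0)))
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

# Vectorised query length (sum of M/I/S/=/X); NA for "*".
cigarQueryLength <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    p <- parseCigar(cg)
    sum(p$len[p$op %in% .CIGAR_QUERY_OPS])
  }, integer(1), USE.NAMES = FALSE)
}

# Vectorised reference span (sum of M/D/N/=/X); NA for "*".
cigarRefSpan <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    p <- parseCigar(cg)
    sum(p$len[p$op %in% .CIGAR_REF_OPS])
  }, integer(1), USE.NAMES = FALSE)
}

#' Extract one optional field from a record's tag string
#'
#' @param tags tab-joined SAM optional fields (possibly `""`).
#' @param tag two-letter tag name, e.g. `"MD"`.
#' @return the tag value as character, or `NA` if absent. Vectorised over
#'   `tags`.
#' @export
getTag <- function(tags, tag) {
  pat <- paste0("(?:^|\t)", tag, ":[AifZHB]:([^\t]*)")
  m <- regmatches(tags, regexec(pat, tags))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_,
         character(1))
}

# Replace or append a tag; value "" removes it. Vectorised.
setTag <- function(tags, tag, type, value) {
  pat <- paste0("(^|\t)", tag, ":[AifZHB]:[^\t]*")
  stripped <- gsub(pat, "\\1", tags)
  stripped <- gsub("\t+", "\t", stripped)
  stripped <- sub("^\t", "", sub("\t$", "", stripped))
  add <- !is.na(value)
  out <- stripped
  piece <- paste0(tag, ":", type, ":", value)
  out[add] <- ifelse(nzchar(stripped[add]),
                     paste(stripped[add], piece[add], sep = "\t"),
                     piece[add])
  out
}

# phred+33 QUAL string <-> integer vector
qualToInt <- function(qual) {
  if (is.na(qual) || qual == "*") return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

intToQual <- function(bq) {
  if (length(bq) == 0) return("*")
  rawToChar(as.raw(pmin(bq, 93L) + 33L))
}

# SAM flag bit helpers (vectorised over integer flags)
flagPaired <- function(flag) bitwAnd(flag, 1L) != 0L
flagProperPair <- function(flag) bitwAnd(flag, 2L) != 0L
flagUnmapped <- function(flag) bitwAnd(flag, 4L) != 0L
flagReverse <- function(flag) bitwAnd(flag, 16L) != 0L
flagFirstInPair <- function(flag) bitwAnd(flag, 64L) != 0L
flagSecondInPair <- function(flag) bitwAnd(flag, 128L) != 0L
flagSecondary <- function(flag) bitwAnd(flag, 256L) != 0L
flagQcFail <- function(flag) bitwAnd(flag, 512L) != 0L
flagDuplicate <- function(flag) bitwAnd(flag, 1024L) != 0L
flagSupplementary <- function(flag) bitwAnd(flag, 2048L) != 0L

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Apply the SNVs of a DiploidTruth variant table to the reference, for one
# haplotype ("h1"/"h2"). Used both by the simulator and the class validity.
.applyVariants <- function(reference, variants, hap) {
  hapIdx <- if (hap == "h1") 1L else 2L
  out <- as.character(reference)
  if (nrow(variants) > 0) {
    for (ctg in unique(variants$contig)) {
      v <- variants[variants$contig == ctg, , drop = FALSE]
      use <- v$genotype == "hom-alt" | v$hap == hapIdx
      v <- v[use, , drop = FALSE]
      if (nrow(v) == 0) next
      ch <- strsplit(out[[ctg]], "", fixed = TRUE)[[1]]
      ch[v$pos0 + 1L] <- v$alt
      out[[ctg]] <- paste(ch, collapse = "")
    }
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(reference)
  res
}

# rbind a list of data.frames; NULL when empty, fresh row names otherwise
rbindRows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
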