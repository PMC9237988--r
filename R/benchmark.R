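# SNP benchmarking against a truth set: TP/FP/FN classification requiring
# both the substitution context and the genotype to match, score-threshold
# sweeps, and precision/sensitivity/F1 summaries.

#' Truth variants as a comparable table
#'
#' @param truth a [DiploidTruth-class].
#' @return data.frame with `contig`, `pos` (1-based), `ref`, `alt` and
#'   `genotype` (sorted allele pair, e.g. `"C/T"`).
#' @export
truthTable <- function(truth) {
  v <- truth@variants
  gtAlleles <- ifelse(v$genotype == "het",
                      paste(pmin(v$ref, v$alt), pmax(v$ref, v$alt), sep = "/"),
                      paste(v$alt, v$alt, sep = "/"))
  data.frame(contig = v$contig, pos = v$pos0 + 1L, ref = v$ref, alt = v$alt,
             genotype = gtAlleles, stringsAsFactors = FALSE)
}

#' Read SNVs and genotypes from a VCF file
#'
#' Thin wrapper over `VariantAnnotation::readVcf` returning the flat table
#' the benchmarking functions consume. Genotypes are resolved to allele
#' pairs; non-SNV records are skipped with a warning.
#'
#' @param path a VCF file.
#' @return data.frame with `contig`, `pos`, `ref`, `alt`, `genotype`,
#'   `qual`, `gq`, `dp` (scores NA where the file lacks them).
#' @export
readVcfVariants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altL <- lapply(rr$ALT, as.character)
  gtM <- VariantAnnotation::geno(vcf)$GT
  gt <- if (!is.null(gtM)) gtM[, 1] else rep(NA_character_, length(rr))
  isSnv <- nchar(ref) == 1L &
    vapply(altL, function(a) length(a) >= 0 && all(nchar(a) == 1L), logical(1))
  if (any(!isSnv))
    warning(sum(!isSnv), " non-SNV record(s) skipped")
  genoStr <- vapply(seq_along(ref), function(i) {
    if (is.na(gt[i])) return(NA_character_)
    idx <- as.integer(strsplit(gt[i], "[/|]")[[1]])
    alleles <- c(ref[i], altL[[i]])[idx + 1L]
    paste(sort(alleles), collapse = "/")
  }, character(1))
  gq <- dp <- rep(NA_real_, length(ref))
  g <- VariantAnnotation::geno(vcf)
  if ("GQ" %in% names(g)) gq <- as.numeric(g$GQ[, 1])
  if ("DP" %in% names(g)) dp <- as.numeric(g$DP[, 1])
  qual <- rr$QUAL
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), ref = ref,
    alt = vapply(altL, paste, character(1), collapse = ","),
    genotype = genoStr,
    qual = if (is.null(qual)) NA_real_ else as.numeric(qual),
    gq = gq, dp = dp, stringsAsFactors = FALSE)
  out[isSnv, , drop = FALSE]
}

.asVariantTable <- function(x, role) {
  if (is.character(x) && length(x) == 1L) x <- readVcfVariants(x)
  if (methods::is(x, "DiploidTruth")) x <- truthTable(x)
  need <- c("contig", "pos", "ref", "genotype")
  if (!all(need %in% names(x)))
    stop(role, " table needs columns: ", paste(need, collapse = ", "))
  for (s in c("qual", "gq", "dp"))
    if (!s %in% names(x)) x[[s]] <- NA_real_
  snv <- nchar(x$ref) == 1L &
    !grepl("[^ACGT/]", x$genotype)
  if (any(!snv)) {
    warning(sum(!snv), " non-SNV ", role, " record(s) skipped")
    x <- x[snv, , drop = FALSE]
  }
  x
}

#' Classify calls against a truth set
#'
#' Exact-position SNV matching: a call is a true positive only when it sits
#' at a truth site with the same substitution context (reference allele and
#' position) and the same unphased genotype. A truth site called with the
#' wrong genotype yields one false positive and one false negative; an
#' uncalled truth site yields a false negative; a call off the truth set is
#' a false positive.
#'
#' @param truth truth variants: a [DiploidTruth-class], a VCF path, or a
#'   data.frame with `contig`, `pos`, `ref`, `genotype`.
#' @param calls called variants in the same forms (e.g. the data.frame from
#'   [callVariants()]).
#' @param regions optional [GenomicRanges::GRanges] of confident regions;
#'   both sides are restricted to them.
#' @return data.frame of classified variants: `contig`, `pos`, `ref`,
#'   `truthGenotype`, `callGenotype`, `class` (TP/FP/FN) and the call's
#'   `qual`, `gq`, `dp` scores (NA on FN rows).
#' @export
classifyVariants <- function(truth, calls, regions = NULL) {
  tt <- .asVariantTable(truth, "truth")
  ct <- .asVariantTable(calls, "calls")
  if (!is.null(regions)) {
    inReg <- function(d) {
      gr <- GenomicRanges::GRanges(d$contig,
                                   IRanges::IRanges(d$pos, width = 1L))
      GenomicRanges::countOverlaps(gr, regions) > 0L
    }
    tt <- tt[inReg(tt), , drop = FALSE]
    ct <- ct[inReg(ct), , drop = FALSE]
  }
  tKey <- paste(tt$contig, tt$pos)
  cKey <- paste(ct$contig, ct$pos)
  hit <- match(cKey, tKey)
  isTp <- !is.na(hit) & ct$ref == tt$ref[hit] & ct$genotype == tt$genotype[hit]
  rows <- list()
  if (any(isTp))
    rows$tp <- data.frame(contig = ct$contig[isTp], pos = ct$pos[isTp],
                          ref = ct$ref[isTp],
                          truthGenotype = tt$genotype[hit[isTp]],
                          callGenotype = ct$genotype[isTp], class = "TP",
                          qual = ct$qual[isTp], gq = ct$gq[isTp],
                          dp = ct$dp[isTp], stringsAsFactors = FALSE)
  if (any(!isTp))
    rows$fp <- data.frame(contig = ct$contig[!isTp], pos = ct$pos[!isTp],
                          ref = ct$ref[!isTp],
                          truthGenotype = NA_character_,
                          callGenotype = ct$genotype[!isTp], class = "FP",
                          qual = ct$qual[!isTp], gq = ct$gq[!isTp],
                          dp = ct$dp[!isTp], stringsAsFactors = FALSE)
  matched <- tKey %in% cKey[isTp]
  if (any(!matched))
    rows$fn <- data.frame(contig = tt$contig[!matched], pos = tt$pos[!matched],
                          ref = tt$ref[!matched],
                          truthGenotype = tt$genotype[!matched],
                          callGenotype = NA_character_, class = "FN",
                          qual = NA_real_, gq = NA_real_, dp = NA_real_,
                          stringsAsFactors = FALSE)
  out <- rbindRows(rows)
  if (is.null(out))
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), truthGenotype = character(0),
                      callGenotype = character(0), class = character(0),
                      qual = numeric(0), gq = numeric(0), dp = numeric(0))
  out[order(out$contig, out$pos, out$class), , drop = FALSE]
}

#' Harmonic-mean F1 score
#'
#' `2 * precision * sensitivity / (precision + sensitivity)`, with the
#' convention that F1 is 0 when both inputs are 0. Vectorised.
#'
#' @param precision,sensitivity values in `[0, 1]`.
#' @return the F1 score(s).
#' @examples
#' f1Score(0.8338, 0.8685)
#' @export
f1Score <- function(precision, sensitivity) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(sensitivity >= 0 & sensitivity <= 1))
  denom <- precision + sensitivity
  ifelse(denom == 0, 0, 2 * precision * sensitivity / denom)
}

#' Precision/sensitivity/F1 across score thresholds
#'
#' At threshold `t`, calls whose score is below `t` are removed: false
#' positives disappear, true positives become false negatives. Precision is
#' TP/(TP+FP) (1 when no calls remain), sensitivity TP/(TP+FN); TP+FN
#' equals the truth-set size at every threshold.
#'
#' @param classified the data.frame from [classifyVariants()].
#' @param scoreField `"qual"`, `"gq"` or `"dp"`.
#' @param thresholds ascending numeric thresholds.
#' @return a [BenchmarkCurve-class].
#' @export
sweepThresholds <- function(classified, scoreField = c("qual", "gq", "dp"),
                            thresholds) {
  scoreField <- match.arg(scoreField)
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("thresholds must be sorted ascending")
  score <- classified[[scoreField]]
  isCall <- classified$class %in% c("TP", "FP")
  if (any(isCall) && all(is.na(score[isCall])))
    stop("missing score: calls carry no ", toupper(scoreField))
  truthSize <- sum(classified$class %in% c("TP", "FN"))
  rows <- lapply(thresholds, function(t) {
    kept <- isCall & !is.na(score) & score >= t
    tp <- sum(kept & classified$class == "TP")
    fp <- sum(kept & classified$class == "FP")
    fn <- truthSize - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 1
    sensitivity <- if (truthSize > 0) tp / truthSize else 0
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
               precision = precision, sensitivity = sensitivity,
               f1 = f1Score(precision, sensitivity))
  })
  new("BenchmarkCurve", scoreField = scoreField, table = rbindRows(rows))
}

#' Threshold maximising F1
#'
#' @param curve a [BenchmarkCurve-class].
#' @return list with `threshold` and `f1`; ties broken toward the smallest
#'   threshold.
#' @export
optimalF1 <- function(curve) {
  tab <- curve@table
  if (nrow(tab) == 0) stop("empty curve")
  i <- which.max(tab$f1)  # first maximum = smallest threshold on ties
  list(threshold = tab$threshold[i], f1 = tab$f1[i])
}

#' @rdname sweepThresholds
#' @param curve a [BenchmarkCurve-class].
#' @param path output TSV path.
#' @export
writeCurveTsv <- function(curve, path) {
  utils::write.table(curve@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
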