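# A minimal conventional Bayesian diploid genotyper: BQ-scaled genotype
# likelihoods, a configurable prior over the 10 diploid genotypes, and the
# MAPQ >= 1 / BQ >= 1 hard filter that makes double-masked bases invisible.

.GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
.BASES <- c("A", "C", "G", "T")

# allele-match counts: .GT_MATCH[base, genotype] in {0, 1, 2}
.GT_MATCH <- local({
  m <- matrix(0L, 4, 10, dimnames = list(.BASES, .GENOTYPES))
  for (g in .GENOTYPES) {
    a <- strsplit(g, "")[[1]]
    for (b in .BASES) m[b, g] <- sum(a == b)
  }
  m
})

.BQ_CAP <- 93L

#' Prior over the ten diploid genotypes
#'
#' Mass 1 - 1.5*theta on the homozygous-reference genotype, theta split
#' evenly over the three heterozygotes containing the reference allele, and
#' the remaining theta/2 split evenly over the six genotypes without the
#' reference allele (three homozygous-alternative, three non-reference
#' heterozygotes). Any proper prior suffices for the masking experiments;
#' this one mimics a conventional caller's expected heterozygosity
#' parameter.
#'
#' @param refBase reference base (A/C/G/T).
#' @param theta expected heterozygosity (default 0.001).
#' @return named numeric vector of length 10 summing to 1.
#' @export
genotypePrior <- function(refBase, theta = 0.001) {
  if (!refBase %in% .BASES) stop("refBase must be one of A/C/G/T")
  m <- .GT_MATCH[refBase, ]
  p <- numeric(10)
  p[m == 2L] <- 1 - 1.5 * theta
  p[m == 1L] <- theta / 3
  p[m == 0L] <- theta / 12
  names(p) <- .GENOTYPES
  p
}

#' Log-likelihood of the observations under each diploid genotype
#'
#' Per observation `b` with phred quality `bq`, the base-call error
#' probability is `e = 10^(-bq/10)` (quality capped at 93);
#' `P(b | allele a) = 1 - e` if `b == a`, else `e/3`, and
#' `P(b | G = {a1, a2}) = (P(b | a1) + P(b | a2)) / 2`. The log-likelihood
#' is the sum over observations, computed in log space; with no
#' observations it is 0 for every genotype.
#'
#' @param bases character vector of observed read bases (A/C/G/T; N entries
#'   are dropped).
#' @param bq integer phred base qualities, parallel to `bases`.
#' @return named numeric vector of 10 log-likelihoods.
#' @export
genotypeLikelihoods <- function(bases, bq) {
  keep <- bases %in% .BASES
  bases <- bases[keep]; bq <- bq[keep]
  ll <- stats::setNames(numeric(10), .GENOTYPES)
  if (length(bases) == 0) return(ll)
  e <- 10^(-pmin(bq, .BQ_CAP) / 10)
  lmat <- cbind(log(e / 3),
                log(0.5 * (1 - e) + 0.5 * e / 3),
                log1p(-e))
  for (g in seq_len(10L)) {
    m <- .GT_MATCH[bases, g]
    ll[g] <- sum(lmat[cbind(seq_along(bases), m + 1L)])
  }
  ll
}

#' Pileup columns from coordinate-sorted alignments
#'
#' Builds the per-site observation sets consumed by genotyping. Observations
#' with base quality below `minBq` or mapping quality below `minMapq` are
#' excluded — with the default hard filter of 1 on both, every double-masked
#' base (BQ 0) is invisible. Deletions contribute nothing; secondary,
#' supplementary, duplicate and QC-fail records are skipped; N read bases
#' and N reference sites are dropped.
#'
#' @param x a coordinate-sorted [BsAlignments-class] object.
#' @param reference optional [FastaReference-class]; MD tags are used when
#'   absent.
#' @param minMapq,minBq hard filters (default 1, the recommended setting for
#'   masked data).
#' @param dropEmpty drop covered columns whose observations were all
#'   filtered away (otherwise they are emitted with depth 0).
#' @return list of [PileupColumn-class] objects, in genome order.
#' @export
buildPileup <- function(x, reference = NULL, minMapq = 1L, minBq = 1L,
                        dropEmpty = FALSE) {
  rec <- x@records
  assertCoordinateSorted(rec)
  use <- which(!flagUnmapped(rec$flag) & rec$seq != "*" &
                 !flagSecondary(rec$flag) & !flagSupplementary(rec$flag) &
                 !flagDuplicate(rec$flag) & !flagQcFail(rec$flag))
  ctx <- flagContext(rec$flag)
  acc <- list()
  for (i in use) {
    cols <- alignedColumns(x, i, reference = reference)
    cols <- cols[!is.na(cols$refPos0) & !is.na(cols$refBase) &
                   cols$refBase %in% .BASES, , drop = FALSE]
    if (nrow(cols) == 0) next
    acc[[length(acc) + 1L]] <- data.frame(
      contig = rec$rname[i], pos0 = cols$refPos0, refBase = cols$refBase,
      base = cols$readBase, bq = cols$bq, mapq = rec$mapq[i],
      context = ctx[i], stringsAsFactors = FALSE)
  }
  if (length(acc) == 0) return(list())
  tbl <- do.call(rbind, acc)
  tbl <- tbl[order(tbl$contig, tbl$pos0), , drop = FALSE]
  keepObs <- tbl$base %in% .BASES & tbl$bq >= minBq & tbl$mapq >= minMapq
  key <- paste(tbl$contig, tbl$pos0)
  out <- list()
  for (k in unique(key)) {
    sub <- tbl[key == k, , drop = FALSE]
    obs <- sub[keepObs[key == k],
               c("base", "bq", "mapq", "context"), drop = FALSE]
    rownames(obs) <- NULL
    if (dropEmpty && nrow(obs) == 0) next
    out[[length(out) + 1L]] <- new("PileupColumn", contig = sub$contig[1],
                                   pos0 = as.integer(sub$pos0[1]),
                                   refBase = sub$refBase[1],
                                   observations = obs)
  }
  out
}

#' Flat pileup observation table
#'
#' The vectorised counterpart of [buildPileup()]: one row per surviving read
#' base over the whole alignment set, with the record's conversion context
#' attached. Useful for strand-specific depth summaries (e.g. the
#' opposite-strand depth available to thymine-involving polymorphisms after
#' masking).
#'
#' @inheritParams buildPileup
#' @param reference a [FastaReference-class] (required).
#' @return data.frame with columns `contig`, `pos0`, `refBase`, `base`,
#'   `bq`, `mapq`, `context`.
#' @export
pileupTable <- function(x, reference, minMapq = 1L, minBq = 1L) {
  stopifnot(methods::is(reference, "FastaReference"))
  rec <- x@records
  assertCoordinateSorted(rec)
  use <- !flagUnmapped(rec$flag) & rec$seq != "*" &
    !flagSecondary(rec$flag) & !flagSupplementary(rec$flag) &
    !flagDuplicate(rec$flag) & !flagQcFail(rec$flag) &
    rec$mapq >= minMapq
  sub <- rec[use, , drop = FALSE]
  ctx <- flagContext(sub$flag)
  refStrings <- as.character(reference@sequences)
  refIdx <- match(sub$rname, names(reference@sequences))
  cc <- cpp_columns(sub$seq, sub$qual, sub$cigar, sub$pos0,
                    refStrings, refIdx)
  keep <- cc$rpos0 >= 0L & cc$refCode >= 1L & cc$baseCode >= 1L &
    cc$bq >= minBq
  ri <- cc$rec[keep]
  out <- data.frame(
    contig = sub$rname[ri], pos0 = cc$rpos0[keep],
    refBase = .BASES[cc$refCode[keep]], base = .BASES[cc$baseCode[keep]],
    bq = cc$bq[keep], mapq = sub$mapq[ri], context = ctx[ri],
    stringsAsFactors = FALSE)
  out[order(out$contig, out$pos0), , drop = FALSE]
}

assertCoordinateSorted <- function(rec) {
  mapped <- !flagUnmapped(rec$flag)
  for (ctg in unique(rec$rname[mapped])) {
    p <- rec$pos0[mapped & rec$rname == ctg]
    if (is.unsorted(p)) stop("requires coordinate sort")
  }
  invisible(TRUE)
}

#' Bayesian genotype call at one pileup column
#'
#' Posterior over the 10 diploid genotypes: the prior times the BQ-scaled
#' likelihood, normalised over genotypes. The call is the posterior argmax
#' (ties broken toward a genotype containing the reference allele, then
#' lexicographically). QUAL is the phred-scaled posterior probability of
#' homozygous-reference; GQ the phred-scaled probability that the assigned
#' genotype is wrong; both capped at 9999.
#'
#' @param column a [PileupColumn-class].
#' @param prior named numeric vector over the 10 genotypes, or `NULL` to use
#'   [genotypePrior()] for the column's reference base.
#' @param theta heterozygosity for the default prior.
#' @return a [GenotypeCall-class].
#' @export
callSite <- function(column, prior = NULL, theta = 0.001) {
  refBase <- column@refBase
  if (!refBase %in% .BASES) stop("reference base must be A/C/G/T")
  if (is.null(prior)) prior <- genotypePrior(refBase, theta)
  prior <- prior[.GENOTYPES]
  obs <- column@observations
  ll <- genotypeLikelihoods(obs$base, obs$bq)
  lp <- log(prior) + ll
  m <- max(lp)
  w <- exp(lp - m)
  post <- w / sum(w)
  cand <- which(post == max(post))
  if (length(cand) > 1L) {
    withRef <- cand[.GT_MATCH[refBase, cand] > 0L]
    cand <- if (length(withRef)) withRef else cand
  }
  gIdx <- min(cand)
  gt <- .GENOTYPES[gIdx]
  alleles <- strsplit(gt, "")[[1]]
  homRef <- which(.GENOTYPES == paste0(refBase, refBase))
  logPostHomRef <- (lp[homRef] - m) - log(sum(w))
  qual <- min(9999, -10 / log(10) * logPostHomRef)
  rest <- sum(w) - w[gIdx]
  gq <- if (rest <= 0) 9999 else min(9999, -10 * log10(rest / sum(w)))
  new("GenotypeCall", contig = column@contig, pos = column@pos0 + 1L,
      ref = refBase, alt = sort(setdiff(alleles, refBase)),
      genotype = paste(sort(alleles), collapse = "/"),
      qual = unname(qual), gq = unname(gq),
      dp = nrow(obs), posteriors = post)
}

#' Call variants over a whole alignment set
#'
#' Streams the equivalent of [buildPileup()] then [callSite()] over every
#' covered reference site, using a vectorised engine (identical results to
#' the per-column path, which the test-suite verifies). Sites whose best
#' genotype is homozygous-reference are suppressed unless `emitAll`.
#'
#' @inheritParams buildPileup
#' @param reference a [FastaReference-class] (required: reference bases
#'   anchor both the prior and the site list).
#' @param theta prior heterozygosity.
#' @param emitAll also report homozygous-reference sites.
#' @param vcf optional path; calls are additionally written as VCF 4.2.
#' @return data.frame with one row per emitted call: `contig`, `pos`
#'   (1-based), `ref`, `alt` (comma-joined), `genotype` (sorted allele pair,
#'   e.g. `"C/T"`), `qual`, `gq`, `dp`.
#' @export
callVariants <- function(x, reference, theta = 0.001, minMapq = 1L,
                         minBq = 1L, emitAll = FALSE, vcf = NULL) {
  stopifnot(methods::is(reference, "FastaReference"))
  rec <- x@records
  assertCoordinateSorted(rec)
  use <- !flagUnmapped(rec$flag) & rec$seq != "*" &
    !flagSecondary(rec$flag) & !flagSupplementary(rec$flag) &
    !flagDuplicate(rec$flag) & !flagQcFail(rec$flag) &
    rec$mapq >= minMapq
  sub <- rec[use, , drop = FALSE]
  out <- list()
  refStrings <- as.character(reference@sequences)
  for (ctg in names(reference@sequences)) {
    s <- sub[sub$rname == ctg, , drop = FALSE]
    if (nrow(s) == 0) next
    cc <- cpp_columns(s$seq, s$qual, s$cigar, s$pos0,
                      refStrings[ctg], rep(1L, nrow(s)))
    keep <- cc$rpos0 >= 0L & cc$refCode >= 1L & cc$baseCode >= 1L &
      cc$bq >= minBq
    pos <- cc$rpos0[keep]
    base <- cc$baseCode[keep]
    bq <- pmin(cc$bq[keep], .BQ_CAP)
    if (length(pos) == 0) next
    u <- sort(unique(pos))
    si <- match(pos, u)
    e <- 10^(-bq / 10)
    lmat <- cbind(log(e / 3), log(0.5 * (1 - e) + 0.5 * e / 3), log1p(-e))
    ll <- matrix(0, length(u), 10L)
    for (g in seq_len(10L)) {
      v <- lmat[cbind(seq_along(e), .GT_MATCH[base, g] + 1L)]
      ll[, g] <- rowsum(v, si)
    }
    refCh <- strsplit(refStrings[[ctg]], "", fixed = TRUE)[[1]]
    siteRef <- refCh[u + 1L]
    priorTab <- t(vapply(.BASES, genotypePrior, numeric(10), theta = theta))
    lp <- ll + log(priorTab)[match(siteRef, .BASES), , drop = FALSE]
    mx <- lp[, 1]
    for (g in 2:10) mx <- pmax(mx, lp[, g])
    w <- exp(lp - mx)
    tot <- rowSums(w)
    post <- w / tot
    rowMax <- post[, 1]
    for (g in 2:10) rowMax <- pmax(rowMax, post[, g])
    best <- max.col(post, ties.method = "first")
    ties <- which(rowSums(post == rowMax) > 1L)
    for (i in ties) {
      cand <- which(post[i, ] == rowMax[i])
      withRef <- cand[.GT_MATCH[siteRef[i], cand] > 0L]
      best[i] <- min(if (length(withRef)) withRef else cand)
    }
    homRef <- match(paste0(siteRef, siteRef), .GENOTYPES)
    logPostHomRef <- (lp[cbind(seq_along(u), homRef)] - mx) - log(tot)
    qual <- pmin(9999, -10 / log(10) * logPostHomRef)
    rest <- tot - w[cbind(seq_along(u), best)]
    gq <- ifelse(rest <= 0, 9999, pmin(9999, -10 * log10(rest / tot)))
    dp <- tabulate(si, nbins = length(u))
    emit <- if (emitAll) rep(TRUE, length(u)) else best != homRef
    if (!any(emit)) next
    gt <- .GENOTYPES[best[emit]]
    a1 <- substr(gt, 1, 1); a2 <- substr(gt, 2, 2)
    siteRefE <- siteRef[emit]
    alt <- mapply(function(x1, x2, r)
      paste(sort(setdiff(unique(c(x1, x2)), r)), collapse = ","),
      a1, a2, siteRefE, USE.NAMES = FALSE)
    out[[ctg]] <- data.frame(
      contig = ctg, pos = u[emit] + 1L, ref = siteRefE, alt = alt,
      genotype = paste(a1, a2, sep = "/"), qual = unname(qual[emit]),
      gq = unname(gq[emit]), dp = dp[emit], stringsAsFactors = FALSE)
  }
  calls <- rbindRows(out)
  if (is.null(calls))
    calls <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        genotype = character(0), qual = numeric(0),
                        gq = numeric(0), dp = integer(0))
  if (!is.null(vcf)) writeCallsVcf(calls, reference, vcf)
  calls
}

#' Write genotype calls as a VCF 4.2 file
#'
#' @param calls the data.frame returned by [callVariants()].
#' @param reference the [FastaReference-class] the calls were made against
#'   (for `##contig` header lines).
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @return invisibly, the number of records written.
#' @export
writeCallsVcf <- function(calls, reference, path, sample = "sample1") {
  hdr <- c("##fileformat=VCFv4.2", "##source=bsmask",
           sprintf("##contig=<ID=%s,length=%d>", names(reference@sequences),
                   Biostrings::width(reference@sequences)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Filtered depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  body <- character(0)
  if (nrow(calls) > 0) {
    gtIdx <- vapply(seq_len(nrow(calls)), function(i) {
      alleles <- c(calls$ref[i], strsplit(calls$alt[i], ",", fixed = TRUE)[[1]])
      gt <- strsplit(calls$genotype[i], "/", fixed = TRUE)[[1]]
      paste(sort(match(gt, alleles) - 1L), collapse = "/")
    }, character(1))
    altCol <- ifelse(nzchar(calls$alt), calls$alt, ".")
    body <- paste(calls$contig, calls$pos, ".", calls$ref, altCol,
                  sprintf("%.4f", calls$qual), ".", ".", "GT:GQ:DP",
                  paste(gtIdx, round(calls$gq), calls$dp, sep = ":"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(nrow(calls))
}
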