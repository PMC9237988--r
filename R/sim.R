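# Synthetic data: diploid genomes with truth SNVs, CG/CHG/CHH methylation
# states, stochastic bisulfite conversion, directional WGBS read simulation
# producing the four bisulfite read types (FW+/RC-/FW-/RC+), and in silico
# bisulfite treatment of conventional reads and alignments.

#' Simulate a diploid genome with known SNVs
#'
#' Draws a random reference at the requested GC content, places `nSnps`
#' single-nucleotide variants (a fraction heterozygous, assigned to a random
#' haplotype; the rest homozygous-alternative on both), and applies them to
#' obtain the two haplotypes. Deterministic under `seed`.
#'
#' @param contigLengths named integer vector of contig lengths.
#' @param nSnps total number of SNVs, distributed over contigs in proportion
#'   to length.
#' @param hetFraction fraction of SNVs that are heterozygous (the rest are
#'   homozygous-alternative).
#' @param gcContent GC fraction of the simulated reference.
#' @param seed integer seed.
#' @return a [DiploidTruth-class] object.
#' @export
simulateDiploidGenome <- function(contigLengths = c(chr1 = 100000L), nSnps,
                                  hetFraction = 0.6, gcContent = 0.4,
                                  seed = 1L) {
  if (is.null(names(contigLengths)))
    names(contigLengths) <- paste0("chr", seq_along(contigLengths))
  if (hetFraction < 0 || hetFraction > 1)
    stop("infeasible configuration: hetFraction outside [0, 1]")
  if (nSnps > sum(contigLengths))
    stop("infeasible configuration: more SNVs than positions")
  withSeed(seed, {
    probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
               G = gcContent / 2, T = (1 - gcContent) / 2)
    refs <- lapply(contigLengths, function(L)
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = ""))
    # proportional allocation of SNV counts, remainder to the longest contigs
    alloc <- floor(nSnps * contigLengths / sum(contigLengths))
    rem <- nSnps - sum(alloc)
    if (rem > 0) {
      extra <- order(contigLengths, decreasing = TRUE)[seq_len(rem)]
      alloc[extra] <- alloc[extra] + 1L
    }
    vlist <- list()
    for (ctg in names(contigLengths)) {
      k <- alloc[[ctg]]
      if (k == 0) next
      pos0 <- sort(sample.int(contigLengths[[ctg]], k) - 1L)
      refCh <- strsplit(refs[[ctg]], "", fixed = TRUE)[[1]][pos0 + 1L]
      altCh <- vapply(refCh, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
        USE.NAMES = FALSE)
      vlist[[ctg]] <- data.frame(contig = ctg, pos0 = pos0, ref = refCh,
                                 alt = altCh, stringsAsFactors = FALSE)
    }
    variants <- rbindRows(vlist)
    if (is.null(variants))
      variants <- data.frame(contig = character(0), pos0 = integer(0),
                             ref = character(0), alt = character(0))
    n <- nrow(variants)
    nHet <- round(hetFraction * nSnps)
    genotype <- rep("hom-alt", n)
    if (n > 0 && nHet > 0) genotype[sample.int(n, nHet)] <- "het"
    hap <- integer(n)
    hap[genotype == "het"] <- sample(1:2, sum(genotype == "het"), replace = TRUE)
    variants$genotype <- genotype
    variants$hap <- hap
    reference <- Biostrings::DNAStringSet(unlist(refs))
    names(reference) <- names(contigLengths)
    haplotypes <- list(h1 = .applyVariants(reference, variants, "h1"),
                       h2 = .applyVariants(reference, variants, "h2"))
    new("DiploidTruth", reference = reference, haplotypes = haplotypes,
        variants = variants, seed = as.integer(seed))
  })
}

#' Write the truth variants of a DiploidTruth as a VCF 4.2 file
#'
#' @param truth a [DiploidTruth-class] object.
#' @param path output path.
#' @return invisibly, the number of records written.
#' @export
writeTruthVcf <- function(truth, path) {
  v <- truth@variants
  hdr <- c("##fileformat=VCFv4.2", "##source=bsmask",
           sprintf("##contig=<ID=%s,length=%d>", names(truth@reference),
                   Biostrings::width(truth@reference)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "truth", sep = "\t"))
  body <- character(0)
  if (nrow(v) > 0) {
    gt <- ifelse(v$genotype == "het", "0/1", "1/1")
    body <- paste(v$contig, v$pos0 + 1L, ".", v$ref, v$alt, ".", ".", ".",
                  "GT", gt, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(nrow(v))
}

#' @rdname writeTruthVcf
#' @param what write the reference (`"reference"`) or one haplotype.
#' @export
writeReferenceFasta <- function(truth, path,
                                what = c("reference", "h1", "h2")) {
  what <- match.arg(what)
  seqs <- if (what == "reference") truth@reference else truth@haplotypes[[what]]
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Cytosine context assignment (CG / CHG / CHH)
#'
#' For every cytosine of the requested strand, determines its methylation
#' context reading 5'->3' along that strand: CG when the next base is G, CHG
#' when the next base is H (any base but G) and the following base is G, and
#' CHH otherwise. Cytosines too close to the 3' end for a full lookahead are
#' assigned CHH by convention. Crick-strand cytosines sit at Watson guanine
#' positions; their contexts are evaluated on the reverse complement and
#' reported in Watson coordinates.
#'
#' @param sequence a nucleotide string (Watson strand, A/C/G/T/N).
#' @param strand `"watson"` or `"crick"`.
#' @return data.frame with columns `pos0` (Watson coordinate of the
#'   cytosine) and `context`.
#' @export
assignContexts <- function(sequence, strand = c("watson", "crick")) {
  strand <- match.arg(strand)
  if (strand == "crick") {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sequence)))
    res <- assignContexts(rc, "watson")
    res$pos0 <- nchar(sequence) - 1L - res$pos0
    return(res[order(res$pos0), , drop = FALSE])
  }
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(ch)
  cIdx <- which(ch == "C")
  if (length(cIdx) == 0)
    return(data.frame(pos0 = integer(0), context = character(0)))
  n1 <- ifelse(cIdx + 1L <= L, ch[cIdx + 1L], NA)
  n2 <- ifelse(cIdx + 2L <= L, ch[cIdx + 2L], NA)
  context <- ifelse(!is.na(n1) & n1 == "G", "CG",
                    ifelse(!is.na(n2) & n2 == "G", "CHG", "CHH"))
  data.frame(pos0 = cIdx - 1L, context = context, stringsAsFactors = FALSE)
}

#' Assign methylation states to a diploid genome
#'
#' For every cytosine of each haplotype strand, draws a methylated state
#' from the per-context probability. States are fixed properties of the
#' genome: every simulated molecule of the same haplotype strand shares
#' them, while bisulfite conversion of the unmethylated cytosines is drawn
#' independently per molecule.
#'
#' @param truth a [DiploidTruth-class] object.
#' @param levels named methylation probabilities for CG, CHG, CHH.
#' @param seed integer seed.
#' @return a [MethylationProfile-class] object.
#' @export
methylationProfile <- function(truth,
                               levels = c(CG = 0.8, CHG = 0.4, CHH = 0.05),
                               seed = 1L) {
  withSeed(seed, {
    states <- list()
    for (ctg in names(truth@reference)) {
      states[[ctg]] <- list()
      for (hap in c("h1", "h2")) {
        seq <- as.character(truth@haplotypes[[hap]][[ctg]])
        L <- nchar(seq)
        st <- list()
        for (strand in c("watson", "crick")) {
          cx <- assignContexts(seq, strand)
          v <- logical(L)
          if (nrow(cx) > 0)
            v[cx$pos0 + 1L] <- stats::runif(nrow(cx)) < levels[cx$context]
          st[[strand]] <- v
        }
        states[[ctg]][[hap]] <- st
      }
    }
    new("MethylationProfile", levels = levels, states = states,
        seed = as.integer(seed))
  })
}

#' Simulation configuration constructor
#'
#' Defaults follow the recommended study design for variant calling from
#' WGBS: a paired-end directional library at 40X mean coverage with ~99%
#' bisulfite conversion.
#'
#' @param depth target mean fold-coverage.
#' @param readLength read length (bases).
#' @param fragmentMean,fragmentSd fragment length mean and sd (PE).
#' @param layout `"PE"` or `"SE"`.
#' @param conversionRate probability an unmethylated cytosine converts.
#' @param errorRate per-base sequencing error probability.
#' @param baseQuality phred quality of simulated base calls.
#' @param bqProfile `"constant"` or `"decay"`.
#' @param seed integer seed.
#' @return a [SimConfig-class] object.
#' @export
simConfig <- function(depth = 40, readLength = 100L, fragmentMean = 300,
                      fragmentSd = 30, layout = c("PE", "SE"),
                      conversionRate = 0.99, errorRate = 0.002,
                      baseQuality = 40L, bqProfile = c("constant", "decay"),
                      seed = 1L) {
  layout <- match.arg(layout)
  bqProfile <- match.arg(bqProfile)
  if (layout == "PE" && fragmentMean < readLength)
    stop("infeasible configuration: fragmentMean < readLength")
  new("SimConfig", depth = depth, readLength = as.integer(readLength),
      fragmentMean = fragmentMean, fragmentSd = fragmentSd, layout = layout,
      directional = TRUE, conversionRate = conversionRate,
      errorRate = errorRate, baseQuality = as.integer(baseQuality),
      bqProfile = bqProfile, seed = as.integer(seed))
}

#' Bisulfite-convert one sequence given methylation states
#'
#' Each unmethylated cytosine independently becomes thymine with probability
#' `conversionRate`; methylated cytosines and all other bases are unchanged.
#'
#' @param sequence nucleotide string (the strand carrying the cytosines,
#'   5'->3').
#' @param methylated logical vector along the sequence (TRUE = methylated;
#'   only cytosine positions are consulted).
#' @param conversionRate conversion probability.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return the converted sequence.
#' @export
bisulfiteConvert <- function(sequence, methylated, conversionRate,
                             seed = NULL) {
  run <- function() {
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    if (length(methylated) != length(ch))
      stop("methylated must have one state per base")
    unmeth <- ch == "C" & !methylated
    conv <- unmeth & stats::runif(length(ch)) < conversionRate
    ch[conv] <- "T"
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

# per-base alternatives for uniform substitution errors
.ALT_BASES <- matrix(c("C", "G", "T",
                       "A", "G", "T",
                       "A", "C", "T",
                       "A", "C", "G"), nrow = 4, byrow = TRUE,
                     dimnames = list(c("A", "C", "G", "T"), NULL))

# quality string(s) for a read of length L: [forward, reverse-orientation]
.qualStrings <- function(config) {
  L <- config@readLength
  if (config@bqProfile == "constant") {
    q <- strrep(intToQual(config@baseQuality), L)
    return(c(q, q))
  }
  decay <- config@baseQuality - round(20 * (seq_len(L) - 1L) / max(L - 1L, 1L))
  decay <- pmax(decay, 2L)
  c(intToQual(decay), intToQual(rev(decay)))
}

#' Simulate a directional WGBS alignment set
#'
#' Fragments are sampled uniformly from a random haplotype and a random
#' original strand; bisulfite conversion of unmethylated cytosines (per the
#' [MethylationProfile-class]) is applied per molecule before read
#' extraction; sequencing errors are injected uniformly. Mate and strand
#' flags reproduce the four bisulfite read types: Watson fragments yield
#' FW+ (mate 1 forward, C->T context) and RC- (mate 2 reverse, C->T), Crick
#' fragments yield FW- (mate 1 reverse, G->A) and RC+ (mate 2 forward,
#' G->A). Alignments are emitted at the true position (MAPQ 60) with MD/NM
#' computed against the reference, coordinate-sorted.
#'
#' @param truth a [DiploidTruth-class].
#' @param profile a [MethylationProfile-class] for the same genome.
#' @param config a [SimConfig-class].
#' @return list with `alignments` (a [BsAlignments-class]) and `provenance`
#'   (a data.frame with one row per read: mate, haplotype, original strand,
#'   eligible/converted cytosine counts and the genome positions of
#'   conversions and injected errors).
#' @export
simulateWgbsAlignments <- function(truth, profile, config) {
  stopifnot(methods::is(truth, "DiploidTruth"),
            methods::is(profile, "MethylationProfile"),
            methods::is(config, "SimConfig"))
  L <- config@readLength
  withSeed(config@seed, {
    recs <- list()
    prov <- list()
    for (ctg in names(truth@reference)) {
      G <- Biostrings::width(truth@reference)[match(ctg, names(truth@reference))]
      if (config@layout == "PE") {
        nFrag <- max(1L, round(config@depth * G / (2 * L)))
        fragLen <- as.integer(pmin.int(G, pmax.int(L, round(stats::rnorm(
          nFrag, config@fragmentMean, config@fragmentSd)))))
      } else {
        nFrag <- max(1L, round(config@depth * G / L))
        fragLen <- rep(L, nFrag)
      }
      start0 <- as.integer(floor(stats::runif(nFrag) * (G - fragLen + 1)))
      hap <- sample(c("h1", "h2"), nFrag, replace = TRUE)
      watson <- stats::runif(nFrag) < 0.5

      idx <- sequence(fragLen, from = start0 + 1L)  # 1-based contig positions
      fragId <- rep.int(seq_len(nFrag), fragLen)
      bases <- character(length(idx))
      hch <- lapply(truth@haplotypes, function(h)
        strsplit(as.character(h[[ctg]]), "", fixed = TRUE)[[1]])
      for (h in c("h1", "h2")) {
        sel <- hap[fragId] == h
        bases[sel] <- hch[[h]][idx[sel]]
      }
      # eligibility: unmethylated C on the fragment's original strand
      eligible <- logical(length(idx))
      for (h in c("h1", "h2")) {
        stW <- profile@states[[ctg]][[h]][["watson"]]
        stC <- profile@states[[ctg]][[h]][["crick"]]
        selW <- hap[fragId] == h & watson[fragId]
        selC <- hap[fragId] == h & !watson[fragId]
        eligible[selW] <- bases[selW] == "C" & !stW[idx[selW]]
        eligible[selC] <- bases[selC] == "G" & !stC[idx[selC]]
      }
      conv <- eligible & stats::runif(length(idx)) < config@conversionRate
      bases[conv & watson[fragId]] <- "T"
      bases[conv & !watson[fragId]] <- "A"

      off <- idx - start0[fragId]            # 1..fragLen within fragment
      selA <- off <= L                       # leftmost window (forward read)
      selB <- off > fragLen[fragId] - L      # rightmost window (reverse read)
      windows <- if (config@layout == "PE") list(A = selA, B = selB)
                 else list(A = selA)
      quals <- .qualStrings(config)
      refStr <- as.character(truth@reference[[ctg]])

      for (w in names(windows)) {
        sel <- windows[[w]]
        mat <- matrix(bases[sel], nrow = L)
        posMat <- matrix(idx[sel] - 1L, nrow = L)   # genome pos0 per base
        convMat <- matrix(conv[sel], nrow = L)
        eligMat <- matrix(eligible[sel], nrow = L)
        # uniform sequencing errors, independent per read
        errMat <- matrix(stats::runif(length(mat)) < config@errorRate &
                           mat != "N", nrow = L)
        if (any(errMat)) {
          cur <- mat[errMat]
          pick <- sample.int(3L, sum(errMat), replace = TRUE)
          mat[errMat] <- .ALT_BASES[cbind(match(cur, rownames(.ALT_BASES)), pick)]
        }
        seqs <- do.call(paste0, asplit(mat, 1))
        readStart0 <- if (w == "A") start0 else start0 + fragLen - L
        isReverse <- if (w == "A") rep(FALSE, nFrag) else rep(TRUE, nFrag)
        if (config@layout == "PE") {
          # window A: mate1 of Watson fragments, mate2 of Crick fragments
          mate <- if (w == "A") ifelse(watson, 1L, 2L) else ifelse(watson, 2L, 1L)
          flag <- 1L + 2L +
            (if (w == "A") 32L else 16L) +
            ifelse(mate == 1L, 64L, 128L)
          rnext <- "="
          pnext0 <- if (w == "A") start0 + fragLen - L else start0
          tlen <- if (w == "A") fragLen else -fragLen
        } else {
          mate <- rep(0L, nFrag)
          flag <- ifelse(watson, 0L, 16L)
          isReverse <- !watson
          rnext <- "*"
          pnext0 <- rep(-1L, nFrag)
          tlen <- rep(0L, nFrag)
        }
        qual <- ifelse(isReverse, quals[2], quals[1])
        tg <- cpp_md_batch(seqs, rep(sprintf("%dM", L), nFrag),
                           as.integer(readStart0), refStr,
                           rep(1L, nFrag))
        tags <- paste0("NM:i:", tg$nm, "\tMD:Z:", tg$md)
        qname <- sprintf("%s_frag%07d", ctg, seq_len(nFrag))
        recs[[paste(ctg, w)]] <- data.frame(
          qname = qname, flag = as.integer(flag), rname = ctg,
          pos0 = as.integer(readStart0), mapq = 60L,
          cigar = sprintf("%dM", L), rnext = rnext,
          pnext0 = as.integer(pnext0), tlen = as.integer(tlen),
          seq = seqs, qual = qual, tags = tags, stringsAsFactors = FALSE)
        prov[[paste(ctg, w)]] <- data.frame(
          qname = qname, mate = mate, contig = ctg,
          start0 = as.integer(readStart0), hap = hap,
          strand = ifelse(watson, "+", "-"),
          nEligible = colSums(eligMat), nConverted = colSums(convMat),
          nErrors = colSums(errMat),
          convPos = .posStrings(posMat, convMat),
          errPos = .posStrings(posMat, errMat),
          stringsAsFactors = FALSE)
      }
    }
    rec <- rbindRows(recs)
    provenance <- rbindRows(prov)
    ord <- order(rec$rname, rec$pos0, rec$qname, rec$flag)
    rec <- rec[ord, , drop = FALSE]
    provenance <- provenance[ord, , drop = FALSE]
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(truth@reference),
                        Biostrings::width(truth@reference)),
                sprintf("@PG\tID:bsmask-sim\tPN:bsmask\tVN:%s",
                        utils::packageVersion("bsmask")))
    list(alignments = BsAlignments(rec, header), provenance = provenance)
  })
}

# comma-joined genome positions of flagged entries, one string per column
.posStrings <- function(posMat, flagMat) {
  n <- ncol(posMat)
  out <- character(n)
  if (!any(flagMat)) return(out)
  colIdx <- rep(seq_len(n), each = nrow(posMat))
  hits <- which(flagMat)
  lst <- split(posMat[hits], colIdx[hits])
  out[as.integer(names(lst))] <-
    vapply(lst, paste, character(1), collapse = ",")
  out
}

#' In silico bisulfite treatment of conventional alignments
#'
#' Emulates a directional WGBS library from WGS-style alignments without
#' re-aligning: every read base carries no methylation information, so each
#' fragment is treated as fully unmethylated and converted at
#' `conversionRate`. The fragment's original strand is taken to be Watson
#' when mate 1 (or a single-end read) maps forward — the orientation a
#' directional bisulfite library would have produced for that fragment, and
#' a uniform Bernoulli(1/2) across an unbiased library. Watson fragments
#' have read C bases (reference orientation, both mates) converted to T;
#' Crick fragments have G converted to A. Positions, CIGARs and flags are
#' untouched; MD/NM are recomputed.
#'
#' @param x a [BsAlignments-class] of conventional (non-bisulfite)
#'   alignments.
#' @param reference optional [FastaReference-class]; when `NULL`, MD tags
#'   are used to recompute MD/NM.
#' @param conversionRate per-base conversion probability.
#' @param seed integer seed.
#' @return list with `alignments`, `nEligible` and `nConverted`.
#' @export
convertAlignmentsInSilico <- function(x, reference = NULL,
                                      conversionRate = 0.99, seed = 1L) {
  rec <- x@records
  withSeed(seed, {
    active <- !flagUnmapped(rec$flag) & rec$seq != "*"
    mate1 <- !flagPaired(rec$flag) | flagFirstInPair(rec$flag)
    # fragment strand from the mate-1 orientation, shared by both mates
    m1 <- active & mate1
    fragWatson <- !flagReverse(rec$flag)       # per-record default (SE view)
    byQ <- tapply(which(m1), rec$qname[m1], `[`, 1L)
    hit <- match(rec$qname, names(byQ))
    paired_no_m1 <- active & flagPaired(rec$flag) & is.na(hit)
    if (any(paired_no_m1))
      warning(sum(paired_no_m1), " paired record(s) without a mate-1 ",
              "alignment; treated as single-end for strand assignment")
    use <- !is.na(hit)
    fragWatson[use] <- !flagReverse(rec$flag[byQ[hit[use]]])

    nElig <- 0L; nConv <- 0L
    seqs <- rec$seq
    for (ctxWatson in c(TRUE, FALSE)) {
      sel <- which(active & (fragWatson == ctxWatson))
      if (length(sel) == 0) next
      src <- if (ctxWatson) "C" else "G"
      dst <- if (ctxWatson) "T" else "A"
      ch <- strsplit(seqs[sel], "", fixed = TRUE)
      lens <- lengths(ch)
      flat <- unlist(ch, use.names = FALSE)
      isSrc <- flat == src
      flip <- isSrc & stats::runif(length(flat)) < conversionRate
      nElig <- nElig + sum(isSrc)
      nConv <- nConv + sum(flip)
      flat[flip] <- dst
      ri <- rep.int(seq_along(sel), lens)
      seqs[sel] <- vapply(split(flat, ri), paste, character(1), collapse = "")
    }
    changed <- rec$seq != seqs
    rec$seq <- seqs
    rec <- .refreshMdNm(rec, active & changed, reference)
    list(alignments = BsAlignments(rec, x@header),
         nEligible = nElig, nConverted = nConv)
  })
}

# recompute MD/NM for the selected records, from FASTA or from the original
# MD tag's reference reconstruction
.refreshMdNm <- function(rec, sel, reference) {
  idx <- which(sel)
  if (length(idx) == 0) return(rec)
  if (!is.null(reference)) {
    refStrings <- as.character(reference@sequences)
    refIdx <- match(rec$rname, names(reference@sequences))
    tg <- cpp_md_batch(rec$seq[idx], rec$cigar[idx], rec$pos0[idx],
                       refStrings, refIdx[idx])
  } else {
    md <- getTag(rec$tags[idx], "MD")
    if (anyNA(md))
      stop("no reference source: MD tag absent and no FASTA provided")
    chunks <- character(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      # expand from the ORIGINAL sequence stored in the MD-consistent tags:
      # the MD tag encodes matches relative to the pre-conversion read, so
      # reconstruct the reference chunk with the original expansion rules
      chunks[k] <- mdRecordRefChunk(rec[i, , drop = FALSE], md[k])
    }
    tg <- cpp_md_batch(rec$seq[idx], rec$cigar[idx], rep(0L, length(idx)),
                       chunks, seq_along(idx))
  }
  rec$tags[idx] <- setTag(rec$tags[idx], "MD", "Z", as.character(tg$md))
  rec$tags[idx] <- setTag(rec$tags[idx], "NM", "i", as.character(tg$nm))
  rec
}

#' In silico bisulfite treatment of FASTQ reads
#'
#' Directional-library emulation on raw reads: mate 1 has C converted to T
#' at `conversionRate`, mate 2 has G converted to A; single-end reads behave
#' like mate 1. Base qualities are untouched.
#'
#' @param fastq1 path to the mate-1 (or single-end) FASTQ.
#' @param fastq2 optional mate-2 FASTQ path.
#' @param out1,out2 output paths.
#' @param conversionRate per-base conversion probability.
#' @param seed integer seed.
#' @return list with per-mate `nEligible` and `nConverted` counts,
#'   invisibly.
#' @export
convertReadsInSilico <- function(fastq1, out1, fastq2 = NULL, out2 = NULL,
                                 conversionRate = 0.99, seed = 1L) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- NULL
  if (!is.null(fastq2)) {
    r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq",
                                       with.qualities = TRUE)
    if (length(r1) != length(r2))
      stop("unpaired FASTQ: mate files differ in length (", length(r1),
           " vs ", length(r2), ")")
    if (is.null(out2)) stop("out2 required with fastq2")
  }
  withSeed(seed, {
    convertSet <- function(set, src, dst) {
      ch <- strsplit(as.character(set), "", fixed = TRUE)
      lens <- lengths(ch)
      flat <- unlist(ch, use.names = FALSE)
      isSrc <- flat == src
      flip <- isSrc & stats::runif(length(flat)) < conversionRate
      flat[flip] <- dst
      ri <- rep.int(seq_along(ch), lens)
      out <- Biostrings::DNAStringSet(
        vapply(split(flat, factor(ri, levels = seq_along(ch))),
               paste, character(1), collapse = ""))
      names(out) <- names(set)
      list(set = out, nEligible = sum(isSrc), nConverted = sum(flip))
    }
    c1 <- convertSet(r1, "C", "T")
    Biostrings::writeXStringSet(c1$set, out1, format = "fastq",
                                qualities = S4Vectors::mcols(r1)$qualities)
    stats <- list(nEligible1 = c1$nEligible, nConverted1 = c1$nConverted)
    if (!is.null(r2)) {
      c2 <- convertSet(r2, "G", "A")
      Biostrings::writeXStringSet(c2$set, out2, format = "fastq",
                                  qualities = S4Vectors::mcols(r2)$qualities)
      stats$nEligible2 <- c2$nEligible
      stats$nConverted2 <- c2$nConverted
    }
    invisible(stats)
  })
}
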