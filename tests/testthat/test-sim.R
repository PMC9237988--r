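test_that("diploid genome generation honours counts and determinism", {
  t0 <- simulateDiploidGenome(c(chr1 = 500L), nSnps = 0, seed = 1)
  expect_identical(as.character(haplotypeSequences(t0, "h1")),
                   as.character(referenceSequences(t0)))
  expect_equal(nrow(truthVariants(t0)), 0L)

  t1 <- simulateDiploidGenome(c(chr1 = 5000L), nSnps = 100,
                              hetFraction = 0.6, seed = 2)
  v <- truthVariants(t1)
  expect_equal(nrow(v), 100L)
  expect_equal(sum(v$genotype == "het"), 60L)
  expect_equal(sum(v$genotype == "hom-alt"), 40L)
  expect_true(all(diff(v$pos0) > 0))
  expect_true(all(nchar(v$ref) == 1L & nchar(v$alt) == 1L & v$ref != v$alt))

  t2 <- simulateDiploidGenome(c(chr1 = 5000L), nSnps = 100,
                              hetFraction = 0.6, seed = 2)
  expect_identical(as.character(referenceSequences(t2)),
                   as.character(referenceSequences(t1)))
  expect_identical(truthVariants(t2), v)

  expect_error(simulateDiploidGenome(c(chr1 = 10L), nSnps = 11, seed = 1),
               "infeasible")
})

test_that("haplotypes equal the reference with variants applied, every seed", {
  for (seed in 1:5) {
    tr <- simulateDiploidGenome(c(a = 800L, b = 400L), nSnps = 40,
                                seed = seed)
    v <- truthVariants(tr)
    for (hap in c("h1", "h2")) {
      hapSeq <- as.character(haplotypeSequences(tr, hap))
      for (ctg in c("a", "b")) {
        ch <- strsplit(as.character(referenceSequences(tr)[[ctg]]), "")[[1]]
        vv <- v[v$contig == ctg & (v$genotype == "hom-alt" |
                                     v$hap == (if (hap == "h1") 1 else 2)), ]
        ch[vv$pos0 + 1L] <- vv$alt
        expect_identical(hapSeq[[ctg]], paste(ch, collapse = ""))
      }
    }
  }
})

test_that("cytosine contexts follow the CG/CHG/CHH definition", {
  cx <- assignContexts("CCGG", "watson")
  expect_equal(cx$pos0, c(0L, 1L))
  expect_equal(cx$context, c("CHG", "CG"))
  expect_equal(assignContexts("CAT", "watson")$context, "CHH")
  # trailing cytosines without full lookahead default to CHH
  expect_equal(assignContexts("AC", "watson")$context, "CHH")
  expect_equal(assignContexts("ACA", "watson")$context, "CHH")

  # Crick contexts equal Watson contexts of the reverse complement
  for (seed in 1:5) {
    s <- withr::with_seed(seed, randBases(60))
    got <- assignContexts(s, "crick")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    want <- assignContexts(rc, "watson")
    want$pos0 <- nchar(s) - 1L - want$pos0
    want <- want[order(want$pos0), ]
    rownames(want) <- rownames(got) <- NULL
    expect_identical(got, want)
    # Crick cytosines sit under Watson guanines
    expect_true(all(strsplit(s, "")[[1]][got$pos0 + 1L] == "G"))
  }
})

test_that("bisulfite conversion hits only unmethylated cytosines", {
  s <- "CCCCAGTC"
  allUn <- rep(FALSE, nchar(s))
  expect_equal(bisulfiteConvert(s, allUn, 1, seed = 1), "TTTTAGTT")
  expect_equal(bisulfiteConvert(s, allUn, 0, seed = 1), s)
  allMeth <- rep(TRUE, nchar(s))
  expect_equal(bisulfiteConvert(s, allMeth, 1, seed = 1), s)

  # realised rate within 4 binomial sd of the target
  long <- withr::with_seed(1, randBases(20000))
  n <- sum(strsplit(long, "")[[1]] == "C")
  conv <- bisulfiteConvert(long, rep(FALSE, nchar(long)), 0.99, seed = 3)
  k <- sum(strsplit(long, "")[[1]] == "C" & strsplit(conv, "")[[1]] == "T")
  expect_lt(abs(k - 0.99 * n), 4 * sqrt(n * 0.99 * 0.01) + 1)
})

test_that("simulated libraries hit the target coverage and are reproducible", {
  for (layout in c("PE", "SE")) {
    fx <- smallSim(seed = 41, genome = 20000L, nSnps = 0, depth = 10,
                   layout = layout)
    rec <- records(fx$sim$alignments)
    cover <- sum(nchar(rec$seq)) / 20000
    expect_lt(abs(cover - 10) / 10, 0.1)
    expect_true(all(rec$mapq >= 1L))
    expect_false(is.unsorted(rec$pos0))
    again <- simulateWgbsAlignments(fx$truth, fx$profile, fx$config)
    expect_identical(records(again$alignments), rec)
    expect_identical(again$provenance, fx$sim$provenance)
  }
})

test_that("a noiseless library carries no artifacts and genotypes recover", {
  truth <- simulateDiploidGenome(c(chr1 = 20000L), nSnps = 100, seed = 51)
  prof <- methylationProfile(truth, seed = 52)
  cfg <- simConfig(depth = 40, conversionRate = 0, errorRate = 0, seed = 53)
  sim <- simulateWgbsAlignments(truth, prof, cfg)
  ref <- fastaReference(as.character(referenceSequences(truth)))
  # no C-at-reference-C -> T artifacts anywhere
  tbl <- pileupTable(sim$alignments, ref, minMapq = 0, minBq = 0)
  ct <- tbl[tbl$context == "CT" & tbl$refBase == "C", ]
  truthT <- truthVariants(truth)
  artifact <- ct$base == "T" &
    !(paste(ct$contig, ct$pos0) %in%
        paste(truthT$contig, truthT$pos0)[truthT$alt == "T"])
  expect_equal(sum(artifact), 0L)
  # masking such a library only BQ-zeroes genuine T/A bases
  m <- maskAlignments(sim$alignments, ref)
  expect_lte(basesReplaced(m$stats) / max(basesBqZeroed(m$stats), 1), 0.01)
  # the genotyper recovers nearly all truth genotypes at 40X; sites inside
  # the coverage ramp at the contig boundaries (reads are sampled fully
  # within the contig) are excluded
  calls <- callVariants(m$alignments, ref)
  tt <- truthTable(truth)
  tt <- tt[tt$pos > 100 & tt$pos <= 20000 - 100, ]
  hit <- match(paste(tt$contig, tt$pos), paste(calls$contig, calls$pos))
  recovered <- !is.na(hit) & calls$genotype[hit] == tt$genotype
  expect_gte(mean(recovered), 0.99)
})

test_that("read provenance explains every thymine on FW+ reads", {
  fx <- smallSim(seed = 61, genome = 8000L, nSnps = 40, depth = 8)
  rec <- records(fx$sim$alignments)
  prov <- fx$sim$provenance
  fw1 <- which(rec$flag == 99L)[1:30]
  for (i in fw1) {
    cols <- alignedColumns(fx$sim$alignments, i, reference = fx$ref)
    hapSeq <- strsplit(as.character(
      haplotypeSequences(fx$truth, prov$hap[i])[[rec$rname[i]]]), "")[[1]]
    conv <- as.integer(strsplit(prov$convPos[i], ",")[[1]])
    err <- as.integer(strsplit(prov$errPos[i], ",")[[1]])
    tAtRefC <- cols[!is.na(cols$refBase) & cols$refBase == "C" &
                      cols$readBase == "T", ]
    for (p in tAtRefC$refPos0) {
      explained <- p %in% conv || p %in% err || hapSeq[p + 1L] == "T"
      expect_true(explained)
    }
  }
})

test_that("in silico treatment of alignments is strand-coherent and exact", {
  fx <- smallSim(seed = 71, genome = 6000L, nSnps = 30, depth = 6,
                 conversionRate = 0, errorRate = 0.001)
  aln <- fx$sim$alignments
  # rate 0 leaves records byte-identical
  r0 <- convertAlignmentsInSilico(aln, fx$ref, conversionRate = 0, seed = 5)
  expect_identical(records(r0$alignments), records(aln))
  # fixed seed reproducibility; flags/positions/CIGARs untouched
  r1 <- convertAlignmentsInSilico(aln, fx$ref, conversionRate = 0.99, seed = 5)
  r2 <- convertAlignmentsInSilico(aln, fx$ref, conversionRate = 0.99, seed = 5)
  expect_identical(records(r1$alignments), records(r2$alignments))
  for (col in c("qname", "flag", "rname", "pos0", "cigar", "qual"))
    expect_identical(records(r1$alignments)[[col]], records(aln)[[col]])
  # realised rate within binomial error
  expect_lt(abs(r1$nConverted - 0.99 * r1$nEligible),
            4 * sqrt(r1$nEligible * 0.99 * 0.01) + 1)
  # both mates of a fragment received the same conversion class, the one
  # that matches their flag-derived masking context
  rec <- records(r1$alignments)
  before <- records(aln)
  changed <- which(rec$seq != before$seq)
  for (i in changed) {
    dir <- if (flagContext(rec$flag[i]) == "CT") c("C", "T") else c("G", "A")
    b <- strsplit(before$seq[i], "")[[1]]
    a <- strsplit(rec$seq[i], "")[[1]]
    expect_true(all(b[b != a] == dir[1]) && all(a[b != a] == dir[2]))
  }
  # masking the converted set therefore removes every artificial mismatch
  m <- maskAlignments(r1$alignments, fx$ref)
  tbl <- pileupTable(m$alignments, fx$ref)
  truthT <- truthVariants(fx$truth)
  art <- tbl$context == "CT" & tbl$refBase == "C" & tbl$base == "T"
  expect_equal(sum(art), 0L)
})

test_that("in silico treatment of reads converts the right bases per mate", {
  fq1 <- withr::local_tempfile(fileext = ".fq")
  fq2 <- withr::local_tempfile(fileext = ".fq")
  o1 <- withr::local_tempfile(fileext = ".fq")
  o2 <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGTCCGG", "+", "IJKLMNOP",
               "@r2", "CCCC", "+", "!!!!"), fq1)
  writeLines(c("@r1", "GGGGAAAA", "+", "IIIIIIII",
               "@r2", "GGTT", "+", "IIII"), fq2)
  # rate 0 is the identity on sequence and quality
  convertReadsInSilico(fq1, o1, fq2, o2, conversionRate = 0, seed = 1)
  expect_identical(readLines(o1)[c(2, 4, 6, 8)],
                   readLines(fq1)[c(2, 4, 6, 8)])
  # rate 1 removes every C from mate 1 and every G from mate 2
  convertReadsInSilico(fq1, o1, fq2, o2, conversionRate = 1, seed = 1)
  m1 <- readLines(o1); m2 <- readLines(o2)
  expect_false(any(grepl("C", m1[c(2, 6)])))
  expect_false(any(grepl("G", m2[c(2, 6)])))
  expect_identical(m1[c(4, 8)], readLines(fq1)[c(4, 8)])  # BQ untouched
  # single-end input behaves like mate 1
  st <- convertReadsInSilico(fq1, o1, conversionRate = 1, seed = 2)
  expect_equal(st$nConverted1, st$nEligible1)
  # unpaired mate files are rejected
  writeLines(c("@r1", "AAAA", "+", "IIII"), fq2)
  expect_error(convertReadsInSilico(fq1, o1, fq2, o2, seed = 1),
               "unpaired FASTQ")
})
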