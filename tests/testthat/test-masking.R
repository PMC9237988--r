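test_that("conversion context follows the mate/strand taxonomy", {
  # FW+ : mate 1, forward  -> C>T context
  expect_equal(conversionContext(TRUE, FALSE, FALSE), "CT")
  # RC- : mate 2, reverse  -> C>T context
  expect_equal(conversionContext(TRUE, TRUE, TRUE), "CT")
  # FW- : mate 1, reverse  -> G>A context
  expect_equal(conversionContext(TRUE, FALSE, TRUE), "GA")
  # RC+ : mate 2, forward  -> G>A context
  expect_equal(conversionContext(TRUE, TRUE, FALSE), "GA")
  # single-end behaves like mate 1
  expect_equal(conversionContext(FALSE, FALSE, FALSE), "CT")
  expect_equal(conversionContext(FALSE, FALSE, TRUE), "GA")
  expect_equal(conversionContext(TRUE, FALSE, FALSE, mapped = FALSE), "NONE")
  expect_error(conversionContext(FALSE, TRUE, FALSE), "inconsistent flags")
  # flag-level entry point
  expect_equal(flagContext(c(99L, 147L, 83L, 163L, 0L, 16L, 4L)),
               c("CT", "CT", "GA", "GA", "CT", "GA", "NONE"))
})

test_that("the two masking rules act as specified on aligned mismatches", {
  # CT: ref CCGT, read TCGT -> converted T restored to C with BQ 0; the
  # read T matching reference T is BQ-zeroed (it could hide a converted C
  # allele) but keeps its base
  r <- maskRecord(makeAln("TCGT", md = "0C3"), 1)
  expect_equal(r$record$seq, "CCGT")
  expect_equal(as.integer(charToRaw(r$record$qual)) - 33L, c(0L, 40L, 40L, 0L))
  expect_equal(r$replaced, 1L)
  expect_equal(getTag(r$record$tags, "MD"), "4")
  expect_equal(getTag(r$record$tags, "NM"), "0")

  # CT: ref AAAA, read ATAT -> Ts off a reference C keep their base, lose BQ
  r <- maskRecord(makeAln("ATAT", md = "1A1A",
                          qual = intToQual(rep(30L, 4))), 1)
  expect_equal(r$record$seq, "ATAT")
  expect_equal(as.integer(charToRaw(r$record$qual)) - 33L, c(30L, 0L, 30L, 0L))
  expect_equal(r$replaced, 0L)
  expect_equal(r$zeroed, 2L)

  # GA mirror: ref GGAT, read AGAT
  r <- maskRecord(makeAln("AGAT", md = "0G3", flag = 16L,
                          qual = intToQual(rep(30L, 4))), 1)
  expect_equal(r$record$seq, "GGAT")
  expect_equal(as.integer(charToRaw(r$record$qual)) - 33L, c(0L, 30L, 0L, 30L))

  # unconverted methylated cytosines are untouched
  x <- makeAln("CGCG", md = "4")
  r <- maskRecord(x, 1)
  expect_identical(r$record$seq, "CGCG")
  expect_identical(r$record$qual, records(x)$qual)
  expect_equal(r$replaced + r$zeroed, 0L)
})

test_that("per-base behaviour matches a brute-force rule evaluator", {
  fx <- genRandomAlignments(n = 30, seed = 21)
  rec <- records(fx$aln)
  for (i in which(!bitwAnd(rec$flag, 4L))) {
    ctx <- flagContext(rec$flag[i])
    before <- alignedColumns(fx$aln, i, reference = fx$ref)
    for (scope in c("all-t", "ref-c-only")) {
      r <- maskRecord(fx$aln, i, reference = fx$ref, scope = scope)
      gotSeq <- strsplit(r$record$seq, "")[[1]]
      gotBq <- as.integer(charToRaw(r$record$qual)) - 33L
      beforeBq <- as.integer(charToRaw(rec$qual[i])) - 33L
      for (k in seq_len(nrow(before))) {
        want <- oracleMaskBase(before$readBase[k], before$refBase[k],
                               !is.na(before$refPos0[k]), ctx, scope)
        j <- before$readIndex0[k] + 1L
        expect_identical(gotSeq[j], want$base)
        expect_identical(gotBq[j],
                         if (want$zero) 0L else beforeBq[j])
      }
    }
  }
})

test_that("the compiled batch path matches the per-record reference path", {
  fx <- genRandomAlignments(n = 40, seed = 77)
  rec <- records(fx$aln)
  for (scope in c("all-t", "ref-c-only")) {
    batch <- maskAlignments(fx$aln, fx$ref, scope = scope)
    for (i in seq_len(nrow(rec))) {
      if (bitwAnd(rec$flag[i], 4L)) next
      single <- maskRecord(fx$aln, i, reference = fx$ref, scope = scope)
      got <- records(batch$alignments)[i, ]
      rownames(got) <- rownames(single$record) <- NULL
      expect_identical(got$seq, single$record$seq)
      expect_identical(got$qual, single$record$qual)
      expect_identical(getTag(got$tags, "MD"), getTag(single$record$tags, "MD"))
      expect_identical(getTag(got$tags, "NM"), getTag(single$record$tags, "NM"))
    }
  }
  # and the MD-tag reference source gives the same masked output as FASTA
  viaMd <- maskAlignments(fx$aln, reference = NULL)
  viaFa <- maskAlignments(fx$aln, fx$ref)
  expect_identical(records(viaMd$alignments)$seq, records(viaFa$alignments)$seq)
  expect_identical(records(viaMd$alignments)$qual,
                   records(viaFa$alignments)$qual)
})

test_that("masking is idempotent and conserves everything but SEQ/QUAL/MD/NM", {
  for (seed in c(5, 17)) {
    fx <- smallSim(seed = seed, genome = 4000L, nSnps = 30, depth = 8)
    m1 <- maskAlignments(fx$sim$alignments, fx$ref)
    m2 <- maskAlignments(m1$alignments, fx$ref)
    expect_identical(records(m2$alignments), records(m1$alignments))
    expect_identical(samHeader(m2$alignments), samHeader(m1$alignments))
    expect_equal(basesReplaced(m2$stats), 0)
    # conservation
    a <- records(fx$sim$alignments); b <- records(m1$alignments)
    for (col in c("qname", "flag", "rname", "pos0", "mapq", "cigar",
                  "rnext", "pnext0", "tlen"))
      expect_identical(b[[col]], a[[col]])
  }
})

test_that("mask statistics are internally consistent", {
  fx <- genRandomAlignments(n = 50, seed = 9)
  res <- maskAlignments(fx$aln, fx$ref)
  s <- res$stats
  expect_equal(recordsSeen(s), nRecords(fx$aln))
  expect_equal(recordsSeen(s), recordsMasked(s) + recordsPassedThrough(s))
  expect_lte(basesReplaced(s), basesBqZeroed(s))
  expect_equal(recordsPassedThrough(s),
               sum(bitwAnd(records(fx$aln)$flag, 4L) > 0))
  # every replaced base sat at an aligned ref-C (CT) or ref-G (GA) column
  # with the converted read base
  rec <- records(fx$aln)
  recAfter <- records(res$alignments)
  nRepl <- 0L
  for (i in which(!bitwAnd(rec$flag, 4L))) {
    ctx <- flagContext(rec$flag[i])
    cols <- alignedColumns(fx$aln, i, reference = fx$ref)
    target <- if (ctx == "CT") "T" else "A"
    reftgt <- if (ctx == "CT") "C" else "G"
    changed <- which(strsplit(rec$seq[i], "")[[1]] !=
                       strsplit(recAfter$seq[i], "")[[1]]) - 1L
    for (p in changed) {
      col <- cols[cols$readIndex0 == p, ]
      expect_identical(col$readBase, target)
      expect_identical(col$refBase, reftgt)
    }
    nRepl <- nRepl + length(changed)
  }
  expect_equal(nRepl, basesReplaced(s))
})

test_that("masking an empty set and keep-tags behave as documented", {
  empty <- BsAlignments(header = "@HD\tVN:1.6")
  res <- maskAlignments(empty)
  expect_equal(nRecords(res$alignments), 0L)
  expect_equal(recordsSeen(res$stats), 0)

  x <- makeAln("TCGT", md = "0C3", tags = "NM:i:1\tMD:Z:0C3\tXX:Z:keepme")
  kept <- maskRecord(x, 1, keepTags = TRUE)
  expect_equal(getTag(kept$record$tags, "MD"), "0C3")  # stale, as requested
  expect_equal(kept$record$seq, "CCGT")
  norm <- maskRecord(x, 1)
  expect_equal(getTag(norm$record$tags, "MD"), "4")
  expect_equal(getTag(norm$record$tags, "XX"), "keepme")
})

test_that("maskFile round-trips through SAM with a stats summary", {
  fx <- smallSim(seed = 23, genome = 3000L, nSnps = 20, depth = 6)
  fin <- withr::local_tempfile(fileext = ".sam")
  fout <- withr::local_tempfile(fileext = ".sam")
  fstats <- withr::local_tempfile(fileext = ".tsv")
  fasta <- withr::local_tempfile(fileext = ".fa")
  writeSam(fx$sim$alignments, fin)
  writeReferenceFasta(fx$truth, fasta)
  stats <- maskFile(fin, fout, fasta = fasta, statsFile = fstats)
  out <- readSam(fout)
  expect_equal(nRecords(out), nRecords(fx$sim$alignments))
  expect_true(any(grepl("^@PG\tID:bsmask", samHeader(out))))
  tsv <- read.delim(fstats, header = FALSE)
  expect_equal(tsv$V2[tsv$V1 == "records_seen"], nRecords(out))
  expect_equal(tsv$V2[tsv$V1 == "bases_replaced"], basesReplaced(stats))
})
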