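GTS <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

test_that("the genotype prior is proper and ref-anchored", {
  for (r in c("A", "C", "G", "T")) {
    p <- genotypePrior(r, theta = 0.001)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
    expect_equal(unname(p[paste0(r, r)]), 1 - 1.5 * 0.001)
  }
  expect_error(genotypePrior("N"), "A/C/G/T")
})

test_that("likelihoods follow the BQ-scaled error model", {
  # single C at negligible error: P(C|CC)=1, P(C|CA)=0.5, P(C|AA)~0
  ll <- genotypeLikelihoods("C", 93L)
  expect_equal(exp(ll[["CC"]]), 1, tolerance = 1e-6)
  expect_equal(exp(ll[["AC"]]), 0.5, tolerance = 1e-6)
  expect_lt(exp(ll[["AA"]]), 1e-9)
  # empty observations: log-likelihood 0 for every genotype
  expect_equal(unname(genotypeLikelihoods(character(0), integer(0))),
               rep(0, 10))
  # N bases are skipped
  expect_equal(genotypeLikelihoods(c("C", "N"), c(20L, 20L)),
               genotypeLikelihoods("C", 20L))
  # mixed observations equal the brute-force product over the formula
  bases <- c("C", "T", "C"); bq <- c(20L, 20L, 20L)
  e <- 1e-2
  for (g in GTS) {
    a <- strsplit(g, "")[[1]]
    want <- prod(vapply(bases, function(b) {
      pb <- vapply(a, function(al) if (b == al) 1 - e else e / 3, numeric(1))
      mean(pb)
    }, numeric(1)))
    expect_equal(exp(genotypeLikelihoods(bases, bq)[[g]]), want,
                 tolerance = 1e-12)
  }
})

test_that("site posteriors match enumeration of the Bayesian formula", {
  unif <- setNames(rep(0.1, 10), GTS)
  # single high-quality C under a uniform prior
  col <- new("PileupColumn", contig = "c", pos0 = 0L, refBase = "A",
             observations = data.frame(base = "C", bq = 93L, mapq = 60L,
                                       context = "CT"))
  call <- callSite(col, prior = unif)
  expect_equal(unname(call@posteriors[["CC"]]), 0.4, tolerance = 1e-6)
  for (g in c("AC", "CG", "CT"))
    expect_equal(unname(call@posteriors[[g]]), 0.2, tolerance = 1e-6)
  # C and T reads force the heterozygote
  col2 <- new("PileupColumn", contig = "c", pos0 = 1L, refBase = "C",
              observations = data.frame(base = c("C", "T"), bq = c(93L, 93L),
                                        mapq = 60L, context = "CT"))
  call2 <- callSite(col2, prior = unif)
  expect_equal(call2@genotype, "C/T")
  expect_gt(call2@posteriors[["CT"]], 1 - 1e-6)
  # zero observations: posterior equals the prior, genotype is hom-ref
  col3 <- new("PileupColumn", contig = "c", pos0 = 2L, refBase = "G",
              observations = data.frame(base = character(0), bq = integer(0),
                                        mapq = integer(0),
                                        context = character(0)))
  call3 <- callSite(col3, theta = 0.001)
  expect_equal(call3@posteriors, genotypePrior("G", 0.001))
  expect_equal(call3@genotype, "G/G")
  expect_equal(call3@dp, 0L)
})

test_that("posteriors equal a brute-force oracle on random columns", {
  withr::with_seed(202, {
    for (rep in 1:300) {
      refBase <- sample(c("A", "C", "G", "T"), 1)
      nObs <- sample(0:6, 1)
      obs <- data.frame(base = sample(c("A", "C", "G", "T"), nObs, TRUE),
                        bq = sample(1:60, nObs, TRUE),
                        mapq = rep(60L, nObs),
                        context = sample(c("CT", "GA"), nObs, TRUE),
                        stringsAsFactors = FALSE)
      col <- new("PileupColumn", contig = "c", pos0 = 0L, refBase = refBase,
                 observations = obs)
      call <- callSite(col, theta = 0.001)
      want <- oraclePosterior(obs$base, obs$bq, genotypePrior(refBase, 0.001))
      expect_equal(sum(call@posteriors), 1, tolerance = 1e-9)
      expect_equal(unname(call@posteriors), unname(want), tolerance = 1e-9)
      # GQ/QUAL consistency with the posterior
      expect_equal(call@gq,
                   min(9999, -10 * log10(max(1 - max(want), 1e-1000))),
                   tolerance = 1e-6)
    }
  })
})

test_that("pileup construction applies the hard filters", {
  # five reads over one base; one of them with MAPQ 0
  x <- makeAln(rep("A", 5), cigar = "1M", md = "1", qual = "I",
               qname = sprintf("r%d", 1:5))
  x@records$mapq <- c(60L, 60L, 0L, 60L, 60L)
  ref <- fastaReference(c(c1 = "A"))
  cols <- buildPileup(x, ref, minMapq = 1, minBq = 1)
  expect_length(cols, 1L)
  expect_equal(nrow(cols[[1]]@observations), 4L)
  # a column whose only evidence is masked (BQ 0) stays visible with DP 0
  y <- makeAln("T", cigar = "1M", md = "0C", qual = "!")
  refc <- fastaReference(c(c1 = "C"))
  cols <- buildPileup(y, refc)
  expect_length(cols, 1L)
  expect_equal(nrow(cols[[1]]@observations), 0L)
  expect_length(buildPileup(y, refc, dropEmpty = TRUE), 0L)
  # unsorted input is rejected
  z <- makeAln(c("A", "A"), cigar = "1M", md = "1", qual = "I",
               pos0 = c(5L, 1L), qname = c("a", "b"))
  expect_error(buildPileup(z, ref), "coordinate sort")
})

test_that("pileups match a brute-force per-position scan", {
  fx <- smallSim(seed = 83, genome = 1500L, nSnps = 10, depth = 5)
  want <- oraclePileup(fx$sim$alignments, fx$ref)
  cols <- buildPileup(fx$sim$alignments, fx$ref)
  wantTab <- want$filtered[order(want$filtered$pos0, want$filtered$base,
                                 want$filtered$bq), ]
  gotObs <- do.call(rbind, lapply(cols, function(cc)
    cbind(pos0 = cc@pos0, cc@observations)))
  gotObs <- gotObs[order(gotObs$pos0, gotObs$base, gotObs$bq), ]
  expect_equal(nrow(gotObs), nrow(wantTab))
  expect_equal(gotObs$base, wantTab$base)
  expect_equal(gotObs$bq, wantTab$bq)
  expect_equal(gotObs$context, wantTab$context)
  # covered sites agree too (columns with DP 0 are still emitted)
  expect_setequal(vapply(cols, function(cc) cc@pos0, integer(1)),
                  unique(want$covered$pos0))
  # and the vectorised table agrees with the column view
  tbl <- pileupTable(fx$sim$alignments, fx$ref)
  expect_equal(nrow(tbl), nrow(wantTab))
  tbl <- tbl[order(tbl$pos0, tbl$base, tbl$bq), ]
  expect_equal(tbl$base, wantTab$base)
  expect_equal(tbl$pos0, wantTab$pos0)
})

test_that("whole-set calling equals the per-column path", {
  fx <- smallSim(seed = 89, genome = 2500L, nSnps = 25, depth = 12)
  m <- maskAlignments(fx$sim$alignments, fx$ref)
  calls <- callVariants(m$alignments, fx$ref, emitAll = FALSE)
  cols <- buildPileup(m$alignments, fx$ref)
  manual <- list()
  for (cc in cols) {
    call <- callSite(cc)
    if (call@genotype != paste(call@ref, call@ref, sep = "/"))
      manual[[length(manual) + 1L]] <-
        data.frame(pos = call@pos, genotype = call@genotype,
                   qual = call@qual, gq = call@gq, dp = call@dp)
  }
  manual <- do.call(rbind, manual)
  expect_equal(nrow(calls), nrow(manual))
  expect_equal(calls$pos, manual$pos)
  expect_equal(calls$genotype, manual$genotype)
  expect_equal(calls$qual, manual$qual, tolerance = 1e-9)
  expect_equal(calls$gq, manual$gq, tolerance = 1e-9)
  expect_equal(calls$dp, manual$dp)
})

test_that("calling is invariant to record order within a position", {
  fx <- smallSim(seed = 97, genome = 2000L, nSnps = 20, depth = 10)
  m <- maskAlignments(fx$sim$alignments, fx$ref)
  calls <- callVariants(m$alignments, fx$ref)
  rec <- records(m$alignments)
  perm <- withr::with_seed(1, {
    o <- order(rec$pos0, runif(nrow(rec)))  # shuffle within equal positions
    rec[o, ]
  })
  calls2 <- callVariants(BsAlignments(perm, samHeader(m$alignments)), fx$ref)
  expect_equal(calls2, calls)
})

test_that("an empty alignment set yields a header-only VCF", {
  ref <- fastaReference(c(c1 = "ACGT"))
  f <- withr::local_tempfile(fileext = ".vcf")
  calls <- callVariants(BsAlignments(header = "@HD\tVN:1.6"), ref, vcf = f)
  expect_equal(nrow(calls), 0L)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))
  expect_true(any(grepl("^##contig=<ID=c1", lines)))
})

test_that("VCF output round-trips through an independent VCF parser", {
  fx <- smallSim(seed = 101, genome = 4000L, nSnps = 40, depth = 15)
  m <- maskAlignments(fx$sim$alignments, fx$ref)
  f <- withr::local_tempfile(fileext = ".vcf")
  calls <- callVariants(m$alignments, fx$ref, vcf = f)
  back <- readVcfVariants(f)
  expect_equal(nrow(back), nrow(calls))
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$genotype, calls$genotype)
  expect_equal(back$dp, as.numeric(calls$dp))
  expect_equal(back$qual, calls$qual, tolerance = 1e-3)
})
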