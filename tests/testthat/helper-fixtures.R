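# Fixture builders and independent brute-force oracles. The oracles are
# deliberately written as naive per-character walks so they share no code
# path with the package implementation.

# one-record (or multi-record) BsAlignments from minimal arguments
makeAln <- function(seq, cigar = paste0(nchar(seq), "M"), md = NULL,
                    flag = 0L, pos0 = 0L, qual = NULL, rname = "c1",
                    mapq = 60L, qname = "r1", tags = NULL,
                    header = character(0)) {
  n <- length(seq)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # phred 40
  if (is.null(tags)) tags <- if (is.null(md)) rep("", n)
                             else paste0("MD:Z:", md)
  BsAlignments(data.frame(
    qname = rep_len(qname, n), flag = rep_len(as.integer(flag), n),
    rname = rep_len(rname, n), pos0 = rep_len(as.integer(pos0), n),
    mapq = rep_len(as.integer(mapq), n), cigar = rep_len(cigar, n),
    rnext = "*", pnext0 = -1L, tlen = 0L, seq = seq,
    qual = rep_len(qual, n), tags = rep_len(tags, n),
    stringsAsFactors = FALSE), header)
}

randBases <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# Random alignments over a random reference, with MD/NM written during an
# explicit per-base walk (independent of the package's MD code). Includes
# soft clips, insertions, deletions, both contexts and some unmapped records.
genRandomAlignments <- function(n = 20, refLen = 400, seed = 1,
                                mismatchRate = 0.1, withIndels = TRUE) {
  withr::with_seed(seed, {
    refCh <- sample(c("A", "C", "G", "T"), refLen, TRUE)
    recs <- list()
    for (i in seq_len(n)) {
      if (runif(1) < 0.1) {  # unmapped, no sequence
        recs[[i]] <- data.frame(
          qname = sprintf("r%03d", i), flag = 4L, rname = "*", pos0 = -1L,
          mapq = 0L, cigar = "*", rnext = "*", pnext0 = -1L, tlen = 0L,
          seq = "*", qual = "*", tags = "", stringsAsFactors = FALSE)
        next
      }
      pos0 <- sample.int(refLen - 160L, 1) - 1L
      ops <- c("S"[runif(1) < 0.3], "M")
      if (withIndels) {
        # bounded so the reference span stays well inside the contig
        while (runif(1) < 0.4 && sum(ops == "M") < 5)
          ops <- c(ops, sample(c("I", "D"), 1), "M")
      }
      if (runif(1) < 0.2) ops <- c(ops, "S")
      lens <- ifelse(ops == "M", sample(8:25, length(ops), TRUE),
                     sample(1:4, length(ops), TRUE))
      read <- character(0); nm <- 0L; rp <- pos0
      for (k in seq_along(ops)) {
        if (ops[k] %in% c("S", "I")) {
          read <- c(read, sample(c("A", "C", "G", "T"), lens[k], TRUE))
          if (ops[k] == "I") nm <- nm + lens[k]
        } else if (ops[k] == "M") {
          for (j in seq_len(lens[k])) {
            rb <- refCh[rp + 1L]
            if (runif(1) < mismatchRate) {
              b <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
              nm <- nm + 1L
            } else b <- rb
            read <- c(read, b)
            rp <- rp + 1L
          }
        } else if (ops[k] == "D") {
          nm <- nm + lens[k]
          rp <- rp + lens[k]
        }
      }
      # MD written in a second explicit walk over the finished read
      rp2 <- pos0; qi <- 0L; md2 <- ""; run2 <- 0L
      for (k in seq_along(ops)) {
        if (ops[k] %in% c("S", "I")) { qi <- qi + lens[k]; next }
        if (ops[k] == "D") {
          md2 <- paste0(md2, run2, "^",
                        paste(refCh[rp2 + seq_len(lens[k])], collapse = ""))
          run2 <- 0L; rp2 <- rp2 + lens[k]; next
        }
        for (j in seq_len(lens[k])) {
          rb <- refCh[rp2 + 1L]
          if (read[qi + 1L] == rb) run2 <- run2 + 1L
          else { md2 <- paste0(md2, run2, rb); run2 <- 0L }
          qi <- qi + 1L; rp2 <- rp2 + 1L
        }
      }
      md2 <- paste0(md2, run2)
      flag <- sample(c(0L, 16L, 99L, 83L, 147L, 163L), 1)
      seqStr <- paste(read, collapse = "")
      recs[[i]] <- data.frame(
        qname = sprintf("r%03d", i), flag = flag, rname = "chrT",
        pos0 = pos0, mapq = sample(0:60, 1),
        cigar = paste0(lens, ops, collapse = ""), rnext = "*",
        pnext0 = -1L, tlen = 0L, seq = seqStr,
        qual = paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1]],
                            nchar(seqStr), TRUE), collapse = ""),
        tags = paste0("NM:i:", nm, "\tMD:Z:", md2), stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, recs)
    ref <- fastaReference(c(chrT = paste(refCh, collapse = "")))
    list(aln = BsAlignments(rec, c("@HD\tVN:1.6",
                                   sprintf("@SQ\tSN:chrT\tLN:%d", refLen))),
         ref = ref)
  })
}

# --- independent oracles -------------------------------------------------

# character-by-character MD expander (state machine; no regex)
oracleMdExpand <- function(md, cigar, seq) {
  # query indices of aligned bases, via a naive cigar walk
  num <- ""; qIdx <- integer(0); qi <- 0L; nDel <- 0L
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch >= "0" && ch <= "9") { num <- paste0(num, ch); next }
    len <- as.integer(num); num <- ""
    if (ch %in% c("M", "=", "X")) { qIdx <- c(qIdx, qi + seq_len(len)); qi <- qi + len }
    else if (ch %in% c("I", "S")) qi <- qi + len
    else if (ch == "D") nDel <- nDel + len
  }
  readCh <- strsplit(seq, "")[[1]]
  aligned <- character(length(qIdx)); deleted <- character(0)
  j <- 0L; num <- ""; inDel <- FALSE
  flushNum <- function(num, j, aligned) {
    if (num == "") return(list(j, aligned))
    n <- as.integer(num)
    if (n > 0) {
      aligned[j + seq_len(n)] <- readCh[qIdx[j + seq_len(n)]]
      j <- j + n
    }
    list(j, aligned)
  }
  for (ch in strsplit(md, "")[[1]]) {
    if (ch >= "0" && ch <= "9") {
      if (inDel) inDel <- FALSE
      num <- paste0(num, ch)
    } else if (ch == "^") {
      res <- flushNum(num, j, aligned); j <- res[[1]]; aligned <- res[[2]]
      num <- ""; inDel <- TRUE
    } else {
      if (inDel) deleted <- c(deleted, toupper(ch))
      else {
        res <- flushNum(num, j, aligned); j <- res[[1]]; aligned <- res[[2]]
        num <- ""
        j <- j + 1L
        aligned[j] <- toupper(ch)
      }
    }
  }
  res <- flushNum(num, j, aligned); j <- res[[1]]; aligned <- res[[2]]
  stopifnot(j == length(qIdx), length(deleted) == nDel)
  list(aligned = aligned, deleted = deleted)
}

# per-base double-masking rule evaluator
oracleMaskBase <- function(readBase, refBase, aligned, context,
                           scope = "all-t") {
  target <- if (context == "CT") "T" else "A"
  reftgt <- if (context == "CT") "C" else "G"
  if (readBase == target) {
    if (aligned && !is.na(refBase) && refBase == reftgt)
      return(list(base = reftgt, zero = TRUE))
    if (scope == "all-t") return(list(base = readBase, zero = TRUE))
  }
  list(base = readBase, zero = FALSE)
}

# direct product-space evaluation of the genotype posterior
oraclePosterior <- function(bases, bq, prior) {
  gts <- names(prior)
  lik <- vapply(gts, function(g) {
    a <- strsplit(g, "")[[1]]
    p <- 1
    for (i in seq_along(bases)) {
      e <- 10^(-min(bq[i], 93) / 10)
      pb <- function(al) if (bases[i] == al) 1 - e else e / 3
      p <- p * (0.5 * pb(a[1]) + 0.5 * pb(a[2]))
    }
    p
  }, numeric(1))
  w <- prior * lik
  w / sum(w)
}

# naive per-position pileup scan over a record table
oraclePileup <- function(aln, ref, minMapq = 1, minBq = 1) {
  rec <- records(aln)
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    flag <- rec$flag[i]
    if (bitwAnd(flag, 4L) || rec$seq[i] == "*") next
    if (bitwAnd(flag, 256L) || bitwAnd(flag, 512L) || bitwAnd(flag, 1024L) ||
        bitwAnd(flag, 2048L)) next
    ctx <- flagContext(flag)
    qi <- 0L; rp <- rec$pos0[i]
    num <- ""
    readCh <- strsplit(rec$seq[i], "")[[1]]
    bqs <- as.integer(charToRaw(rec$qual[i])) - 33L
    for (ch in strsplit(rec$cigar[i], "")[[1]]) {
      if (ch >= "0" && ch <= "9") { num <- paste0(num, ch); next }
      len <- as.integer(num); num <- ""
      if (ch %in% c("M", "=", "X")) {
        for (j in seq_len(len)) {
          rb <- refBases(ref, rec$rname[i], rp, rp + 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            contig = rec$rname[i], pos0 = rp, refBase = rb,
            base = readCh[qi + 1L], bq = bqs[qi + 1L], mapq = rec$mapq[i],
            context = ctx, stringsAsFactors = FALSE)
          qi <- qi + 1L; rp <- rp + 1L
        }
      } else if (ch %in% c("I", "S")) qi <- qi + len
      else if (ch %in% c("D", "N")) rp <- rp + len
    }
  }
  if (length(rows) == 0) return(NULL)
  tbl <- do.call(rbind, rows)
  tbl <- tbl[tbl$refBase %in% c("A", "C", "G", "T"), , drop = FALSE]
  keep <- tbl$base %in% c("A", "C", "G", "T") & tbl$bq >= minBq &
    tbl$mapq >= minMapq
  list(covered = tbl, filtered = tbl[keep, , drop = FALSE])
}

# small simulated data set shared by several tests
smallSim <- function(seed = 7, genome = 20000L, nSnps = 150, depth = 15,
                     layout = "PE", conversionRate = 0.99,
                     errorRate = 0.002) {
  truth <- simulateDiploidGenome(c(chr1 = genome), nSnps = nSnps,
                                 seed = seed)
  prof <- methylationProfile(truth, seed = seed + 1000L)
  cfg <- simConfig(depth = depth, layout = layout,
                   conversionRate = conversionRate, errorRate = errorRate,
                   seed = seed + 2000L)
  sim <- simulateWgbsAlignments(truth, prof, cfg)
  ref <- fastaReference(as.character(referenceSequences(truth)))
  list(truth = truth, profile = prof, config = cfg, sim = sim, ref = ref)
}
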