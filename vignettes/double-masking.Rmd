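---
title: "Double-masking bisulfite alignments for conventional variant calling"
author: "bsmask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-masking bisulfite alignments for conventional variant calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmask)
```

## The problem

Sodium bisulfite deaminates unmethylated cytosine to uracil, read as thymine
after PCR, while 5-methylcytosine is protected. A whole-genome bisulfite
sequencing (WGBS) library therefore contains four read types — the forward
(FW) and reverse complement (RC) of the converted Watson strand, and the same
for the converted Crick strand — and every C→T (Watson view) or G→A
(Crick view) mismatch against the reference is ambiguous: it may be a genuine
polymorphism or a chemical artifact. Conventional variant callers have no way
to make that distinction, yet they embody years of engineering that
bisulfite-specific callers do not.

The observation `bsmask` operationalises is that the ambiguity is resolvable
*per strand*: an artifact is non-complementary (a converted Watson C leaves
the paired Crick G untouched), so any variant involving thymine on one strand
can be assessed from alignments of the opposite strand. Conventional callers
cannot reason about strands, but they all scale genotype likelihoods by the
per-base quality (BQ). Setting BQ to zero on every base that *could* be a
conversion artifact makes those bases invisible to the likelihood while
leaving the alignment intact — an indirect strand-specificity imposed through
a field every caller already respects.

## The double-masking procedure

Each mapped alignment carries exactly one *conversion context*, a pure
function of its SAM flags:

| read type | flags                       | context |
|-----------|-----------------------------|---------|
| FW+       | mate 1, forward             | C→T    |
| RC−       | mate 2, reverse             | C→T    |
| FW−       | mate 1, reverse             | G→A    |
| RC+       | mate 2, forward             | G→A    |

Single-end reads behave like mate 1. Because the context derives from the
aligner's mate/strand decision, directional and non-directional libraries
need no special casing.

Two rules are then applied to a C→T-context record (the G→A context is the
mirror image with G/A):

1. **Base replacement.** At every aligned column where the reference is C
   and the read is T, the read base is rewritten to C and its BQ set to 0.
   This stops the caller from even nominating millions of conversion sites
   as candidate variants.
2. **BQ zeroing.** Every *remaining* T on the read — whether it matches a
   reference T, mismatches some other base, or sits in an insertion or soft
   clip — keeps its base but has its BQ set to 0, because any such thymine
   may have arisen from conversion of an unmethylated C allele.

Everything else (flags, CIGAR, position, MAPQ, other tags) is untouched; the
MD and NM tags are recomputed by default since replacement changes the
mismatch structure (`keepTags = TRUE` disables this for consumers that want
the original tags). The machine-checkable consequence, which the test suite
asserts on every simulated library, is that after masking no T on a
C→T-context record and no A on a G→A-context record carries positive
quality: evidence for thymine-involving variants can only come from
opposite-strand alignments. Masking is idempotent.

The scope of rule 2 is genuinely open to a narrower reading in which only
the replaced bases lose quality. We commit to the broad reading — it is the
only one that yields the strand-specificity property above — and expose
`scope = "ref-c-only"` so the narrow variant remains testable. Read-base N
is never replaced or zeroed; a reference N never triggers replacement but
rule 2 still applies.

Downstream, callers must be run with a hard filter of 1 on both minimum
MAPQ and minimum BQ so that the zero-quality bases are excluded from the
model rather than dragged in as maximal-error observations.

## The genotyping model

To validate masking end-to-end without external callers, the package
includes a deliberately minimal diploid Bayesian genotyper. At one site
with filtered observations $D$, the posterior over the ten unordered
diploid genotypes $G$ built from {A,C,G,T} is

$$P(G \mid D) = \frac{P(G)\,P(D \mid G)}{\sum_i P(G_i)\,P(D \mid G_i)}.$$

Each observed base $b$ with quality $q$ has error probability
$e = 10^{-q/10}$ (quality capped at 93, the phred+33 encoding ceiling), and

$$P(b \mid \{a_1, a_2\}) = \tfrac12 P(b \mid a_1) + \tfrac12 P(b \mid a_2),
\qquad P(b \mid a) = \begin{cases}1 - e & b = a\\ e/3 & b \ne a.\end{cases}$$

Likelihoods are accumulated in log space. The prior puts $1 - 1.5\theta$ on
homozygous-reference, $\theta/3$ on each heterozygote containing the
reference allele, and $\theta/12$ on each of the six remaining genotypes
($\theta$ = 0.001 by default, the conventional human-scale heterozygosity;
any proper prior works for the recovery experiments). QUAL is the
phred-scaled posterior of homozygous-reference, GQ the phred-scaled
probability that the argmax genotype is wrong; both are capped at 9999.
Argmax ties are broken toward a genotype containing the reference allele,
then lexicographically, for determinism. Overlapping mates are *not*
collapsed — both observations count — since fragment-level deduplication is
a caller-specific choice. `callVariants()` uses a vectorised engine; the
test suite verifies it is numerically identical (to 10⁻⁹) to the
column-at-a-time `callSite()` path and to a brute-force enumeration of the
posterior formula.

## What the simulator emulates

`simulateDiploidGenome()` draws a reference at a chosen GC content (default
0.40, a plant-like composition), places SNVs — 60% heterozygous by default,
assigned to a random haplotype — and materialises both haplotypes. Truth is
SNV-only: the benchmarking semantics (below) are defined per substitution,
and indel-aware matching is out of scope.

`methylationProfile()` assigns each cytosine of each haplotype strand a
context (CG if the next strand-local base is G; CHG if the base after next
is G; CHH otherwise, including cytosines too close to the 3′ end for a full
lookahead) and draws a methylated state at per-context probabilities. The
defaults, 0.8/0.4/0.05 for CG/CHG/CHH, describe a plant-like methylome in
which the non-CpG contexts matter; the states are fixed properties of the
genome while conversion is drawn independently per molecule.

`simulateWgbsAlignments()` samples fragments uniformly from a random
haplotype and a random original strand, converts unmethylated cytosines of
that strand at `conversionRate` (default 0.99, typical of a successful
bisulfite treatment), extracts directional paired-end or single-end reads
whose flags reproduce the FW+/RC−/FW−/RC+ taxonomy, and injects uniform
substitution errors at `errorRate` (default 0.002). Base quality is a
constant 40 by default (`bqProfile = "decay"` gives a linear 20-phred 3′
fall-off); the error rate is deliberately *larger* than the 10⁻⁴ the
qualities claim, so the genotyper's error term is exercised under mild
miscalibration. Reads are emitted at their true positions with MAPQ 60 and
consistent MD/NM tags — alignment itself, and its failure modes, are not
simulated. A per-read provenance table records haplotype, original strand,
and the genomic positions of every conversion and injected error, so tests
can audit that each observed thymine has an explanation.

The default configuration — paired-end, directional, 40X — is the study
design under which variant calling from WGBS is expected to work well; the
test suite exercises it on a 100 kb genome with 1,000 SNVs, and smaller
variations (10–15X, SE and PE) for the masking invariants. Sizes were chosen
so the full suite runs comfortably on a laptop while leaving binomial noise
well inside the asserted margins.

`convertAlignmentsInSilico()` and `convertReadsInSilico()` emulate a WGBS
library from conventional (WGS) data. Reads carry no methylation
information, so every C is treated as unmethylated. For reads, mate 1
receives C→T and mate 2 G→A, the directional pattern. For alignments, the
fragment's "original strand" is defined as Watson when mate 1 (or the
single-end read) maps forward: the WGS fragment orientation is itself a fair
coin, so this is a uniform per-fragment strand assignment, and it is the one
coherent with the flag-derived context that masking will later use — an
independent coin flip would make half the fragments' conversion invisible to
masking and the emulation meaningless. Conversion is drawn independently per
base; overlapping mate bases may therefore disagree, a simplification
relative to a real shared molecule.

## Benchmarking semantics

`classifyVariants()` matches SNVs by exact position and requires both the
substitution context (reference allele) and the unphased genotype to agree:
a truth site called with the wrong genotype produces one false positive
*and* one false negative, an uncalled truth site a false negative, a call
off the truth set a false positive. `sweepThresholds()` removes calls below
a QUAL/GQ/DP threshold (true positives so removed become false negatives),
keeping TP+FN equal to the truth-set size at every threshold; precision is
TP/(TP+FP) with the empty-call-set convention of 1, sensitivity TP/(TP+FN),
and F1 their harmonic mean (0 when both are 0). `optimalF1()` takes the
curve maximum, ties to the smallest threshold. Haplotype-aware rescue,
variant decomposition and region stratification are out of scope; inputs
are assumed normalised, which the package's own writers guarantee.

## Numerical and interface choices

* Coordinates are 0-based half-open everywhere internally; conversion to
  1-based happens only when writing or reading SAM/VCF. This matches the
  binary SAM convention and confines off-by-one risk to the file boundary.
* The MD tag takes precedence over FASTA when both are available (it is
  self-contained per record); `strict = TRUE` verifies their agreement and
  fails on conflict, which catches reference mix-ups cheaply.
* Lowercase (soft-masked) FASTA is uppercased; characters outside A/C/G/T/N
  are rejected. Records with `*` sequence, and unmapped records, pass
  through all operations untouched.
* Secondary, supplementary, duplicate and QC-fail alignments are masked
  according to their own flags but skipped by the genotyper: masking must
  stay caller-agnostic, filtering is the caller's job.
* Posterior normalisation subtracts the row maximum before exponentiating;
  QUAL/GQ are computed from log-space quantities so extreme posteriors do
  not underflow before the phred transform.

## Limitations

The simulator produces uniform coverage, perfect mapping, no PCR
duplicates, no adapters and indel-free truth, so passing tests demonstrate
the correctness of masking, genotyping and benchmarking — not robustness to
alignment error, mapping bias or library pathology, which dominate real
WGBS data. Masking assumes reference-orientation SEQ as stored by standard
bisulfite aligners; three-letter aligners that store converted coordinates
differently are out of scope, as are CRAM input, methylation-level calling
and multi-sample genotyping.
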