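---
title: "Measuring allele-specific expression in polyploids from coverage depth"
author: "polyase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allele-specific expression in polyploids from coverage depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyase)
```

## The problem

In a polyploid organism assembled from distinct parental genomes — an
experimentally produced allotriploid fish, an allopolyploid plant, a
trisomic or polyploid tumour cell — each gene carries one allele per
haplome (parental chromosome set). Measuring how expression is shared
between those alleles from RNA-seq is harder than in diploids for two
reasons. First, a single SNP almost never separates three or more
alleles, so informative sites discriminate *one* allele each, and
different alleles of the same transcript are tagged by different numbers
of sites. Second, coverage depth varies strongly along a transcript
(splice forms, ambiguous alignments), so a read count accumulated over
each allele's private sites confounds allele usage with the local depth
at those sites and with the site count per allele.

`polyase` addresses both: allele attribution happens only *fractionally*
at discriminatory sites, and the magnitude comes from a whole-transcript
expression summary that is robust to coverage spikes.

## Consensus genotypes and discriminatory SNPs

Each parental strain is sequenced separately and aligned to the common
transcriptome; `polyase` consumes the resulting samtools mpileup text.
Per position, the most frequent non-reference base is the candidate
variant, and a call is made by `callConsensus()` under the thresholds of
`consensusThresholds()`:

| parameter | default | meaning |
|---|---|---|
| `minCoverage` | 15 | raw depth below which a position is `N` (`LOW_COVERAGE`) |
| `minBaseQuality` | 25 (Phred) | reads below this do not enter base tallies (still count toward depth) |
| `minVarFreq` | 0.20 | minimum variant allele frequency, inclusive |
| `minVarReads` | 5 | minimum variant-supporting reads, inclusive |
| `maxP` | 0.01 | one-sided Fisher exact p must be strictly below |
| `homFreq` | 0.75 | at or above: homozygous variant; below: heterozygous IUPAC code |
| `strandMinFraction` | 0.10 | minority strand must carry this fraction of variant reads |

Design notes on the open points:

* The exact test contrasts the observed reference/variant split with an
  all-reference expectation (`[[ref, var], [ref + var, 0]]`); its
  one-sided p reduces to a hypergeometric tail and is computed in closed
  form.
* The variant-frequency denominator is the quality-passing read count at
  the position; the 15x coverage gate uses raw depth. The source method
  description does not pin down this interaction; this is the VarScan-like
  reading.
* Inclusive boundaries for "20%", "5 reads" and "15x"; strict for
  "p below 0.01".
* The homozygous-call frequency (0.75) and strand-filter minority
  fraction (0.10) are not forced by the method description; they follow
  VarScan's documented defaults.
* Candidates failing the support rules (frequency or read floor) fall
  back to a homozygous *reference* call — weak evidence is treated as
  noise. Candidates with support that fail the exact test or strand
  filter are reported `N` (`INSIGNIFICANT`, `STRAND_FAIL`) — strong but
  unconfirmed evidence makes the position untrustworthy. Only one
  candidate variant is considered per position (ties broken
  alphabetically); tri-allelic pileups are beyond the calling model.

A site then discriminates strain *s* (`classifySite()`, `findDsnps()`)
when *s*'s call is a single unambiguous base, no other strain is `N`,
and that base is absent from the IUPAC expansion of every other strain's
call. Heterozygous strains can never be discriminated (the discriminated
strain must be homozygous for its difference) but do not block another
strain so long as the expansions exclude its base; one site may
discriminate several strains at once (the definition is per strain).
Indels never enter dSNP logic: deletion placeholders and indel strings
in the pileup contribute to depth only. ASE needs every allele, so
`selectCompleteTranscripts()` keeps transcripts with at least one dSNP
per strain.

## From coverage to allele values

Whole-transcript expression is the geometric mean of depth over covered
positions (`geometricMeanDepth()`), computed as the exponential of the
mean log depth so long, deeply covered transcripts cannot overflow.
Uncovered positions are excluded rather than zeroing the product; a
transcript with no coverage has expression 0.

Cross-sample comparability uses the DESeq median-of-ratios construction
on these geometric means (`coverageSizeFactors()`): per transcript, the
geometric mean across samples is the representative value; a sample's
factor is the median ratio of its values to the representatives,
excluding transcripts with a zero anywhere. Factors are invariant under
global rescaling — normalisation fixes between-sample ratios, not the
absolute scale. Normalisation is applied to the expression values
*before* allele fractions are multiplied in; since the fractions are
ratios within one sample, the order only affects the reported scale, and
normalising first keeps every reported quantity in the same units.

At a dSNP `p` for strain `s`, with `n(p)` reads covering the position
and `n_s(p)` of them carrying the discriminating base, the fractional
expression is `e_s(p) = G * n_s(p) / n(p)`. The denominator is the raw
read count at the site — every aligned read, including sequencing-error
bases, dilutes the allele fraction; only exact matches to the
discriminating base are credited (`dsnpReadCounts()` applies no base
quality floor here by default). Per strain, ASE is the mean of the
strictly positive `e_s(p)`; if all are zero, zero is reported
(`aseValues()`). Whole-gene expression is the sum of the allele values,
which on balanced data tracks the geometric-mean expression itself — a
useful internal consistency check that the tests exercise.

## Imbalance classification

For each transcript (`classifyImbalance()`):

* `equalExpressionTest()` is a Pearson chi-square goodness of fit of the
  allele values against equal expression (expected = total / ploidy,
  df = ploidy − 1), applied to the ASE values as count-like quantities.
  The method description names only "a goodness of fit test"; this is
  the simplest faithful reading. No multiple-testing correction is
  applied — the downstream cutoff is a raw p < 0.01, reproduced as-is.
* The coefficient of variation uses the sample (n − 1) standard
  deviation over the mean. That choice is forced by the published
  landmarks: for three alleles `(x, x, 0)` gives `sqrt(3)/2 = 0.866` and
  `(x, 0, 0)` gives `sqrt(3) = 1.732`; the population form reproduces
  neither.
* Categories: `even` when the equality test is not rejected
  (p >= `alpha`, default 0.01); otherwise exactly one allele above
  `fold` (default 2) times the median allele value is that strain's
  `up`; else exactly one below median/`fold` is `down`; everything else
  is `spread`. The median (not the mean) is the comparison basis because
  with as few as three observations one outlier drags the mean. When
  several alleles cross the threshold in the same direction the
  transcript is `spread` — one category per transcript.
* Quadrants: whole-gene change versus the parental average
  (`|log2 ratio| > log2(fold)`) crossed with allele dispersion
  (`cv > sqrt(3)/2`, the one-silenced-allele line). The parental
  reference is the arithmetic mean of the parents' normalised
  whole-gene expression.

`concordance()` counts transcripts with identical categories across two
polyploid individuals; `chromosomeRankTable()` lays categories out in
within-chromosome rank order, ties taking sequential ranks stably in
input order.

## The synthetic-data generator

`simulateTriploidExperiment()` reproduces the validation design as a
closed loop with no external aligner: reads are exact substrings of
strain-specific references, so their placements are known and
`placementsToPileup()` builds the mpileup evidence directly from truth.
What it emulates, and the defaults:

* uniform-composition transcripts (default 300 of 1,500 bp — a typical
  mRNA length and a problem size a laptop handles in seconds);
* per strain, 5 substitution variants per transcript at distinct
  positions (`simulateStrainVariants()`), every one a true dSNP by
  construction;
* error-free paired 100 bp reads with a 250 bp fragment size placed
  uniformly, in the FR layout of an aligned proper pair (leftmost mate
  forward). An optional consequence faithfully mirrored from real
  transcriptome alignments: positions within 150 bp of a transcript end
  see mostly single-strand coverage, so variant sites there fail the
  strand filter and are lost — on 1,500 bp transcripts roughly a fifth
  of sites, which is why recovered transcripts average fewer than the
  five generated dSNPs per strain;
* parental samples expressing only their own haplome at 400 fragments
  per transcript (about 50x mean coverage — comfortably above the 15x
  gate, as a dedicated parental sequencing run would be);
* polyploid allele fractions drawn from Dirichlet(1, 1, 1) (the flat
  prior over the simplex: balanced, skewed and near-silenced transcripts
  all occur), fragment totals uniform on 200–2,000, split by
  `allocateReads()` with largest-remainder rounding (ties by strain
  order) so totals are conserved exactly.

Everything is driven by one seed and is bit-reproducible. What the
generator does **not** model — and therefore what passing recovery tests
do not establish about real data: sequencing errors and quality
variation (an optional uniform substitution error would sit naturally in
`generateFragments()`, but the validation design is error-free),
positional coverage bias, isoform structure, alignment ambiguity and
reference bias against divergent strains, and PCR strand artifacts (the
strand filter's actual target). Recovery is scored by
`evaluateRecovery()` as the per-transcript Pearson correlation between
true and estimated allele values; transcripts with near-equal true
values can score near zero despite tiny absolute errors — the
correlation measures trend agreement, not accuracy — and constant
vectors are flagged rather than scored.

## Numerical and degenerate-input choices

* Geometric means in log space; empty coverage gives 0, and an all-zero
  ASE triple is reported as zero with the dispersion undefined (flagged
  `NA`, never silently dropped).
* Size factors are undefined without a transcript positive in every
  sample; that is an error, not a silent 1.
* `n = 0` at a dSNP gives fractional expression 0.
* The pileup parser enforces the declared depth against the resolved
  observation count and the base/quality string lengths; disagreement is
  a format error naming the position.
* Coordinates are 1-based inclusive everywhere externally (the mpileup
  convention); mapping-quality columns are ignored (filtering is on base
  quality only).
* All report tables are written with fixed significant precision and
  deterministic column order, so identical runs byte-reproduce outputs.

## Scope and limitations

The package consumes pileups, not BAM files: alignment is deliberately
out of scope, as are indel genotyping, isoform deconvolution, TPM-style
length normalisation, and extrapolating an allele that has no dSNP from
the remaining alleles (a natural extension that would enlarge the usable
transcript set). Classification thresholds (2-fold, cv 0.866, p 0.01)
are interpretable conventions, not fitted quantities; with only a few
individuals there is no power to calibrate them, and conclusions should
be read accordingly.
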