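---
title: "Codon-pair log-odds scanning: model, calibration and design notes"
author: "codonscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-pair log-odds scanning: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ab initio and homology-based gene finders over-predict: a substantial
fraction of predicted exons, especially short ones, match nothing in the
curated annotation. `codonscan` implements a homology-based *filter* for
such predictions. It exploits the substitution signature that protein
constraint leaves in alignments of coding DNA from two diverged genomes:
first and second codon positions are strongly conserved, while synonymous
changes accumulate at third positions, so coding alignments tend to show a
mismatch roughly every three sites. Non-coding alignments at the same
overall nucleotide identity distribute their mismatches without that
periodic structure. A predicted exon whose aligned sequence does not carry
the coding signature is flagged as a likely false positive.

## Scoring model

The scoring unit is the aligned codon pair: three consecutive alignment
columns read as one triplet in each row. From a training corpus of
in-frame aligned orthologous CDS pairs, the package counts every aligned
codon pair (columns touching a gap or an ambiguity code are excluded) and
forms a 64 x 64 log-odds matrix in natural-log units:

$$S(a, b) = \ln \frac{q(a, b)}{f(a)\, f(b)},$$

where $q$ is the (symmetrised, smoothed) observed codon-pair frequency and
$f$ the marginal codon frequencies. A score of zero means a pair occurs
exactly as often as expected if the two positions were independent;
positive scores mark pairs over-represented in coding alignments
(identities, synonymous third-position changes), negative scores mark
pairs that coding constraint disfavours.

Design choices a user should know about:

* **Logarithm base.** Natural log. The extreme-value theory below is
  base-free (the decay constant absorbs the base); nats are the simplest
  internally consistent choice and are recorded in the matrix file header.
* **Symmetrisation.** The direction of comparison between two genomes is
  arbitrary, so counts are symmetrised, making `score_codon_pair()`
  order-independent.
* **Smoothing.** Pseudocount mass (`pseudocount` = 0.5 by default, as
  `4096 * pseudocount` pseudo-observations) is distributed over cells in
  proportion to the *expected* frequency of each pair, the product of
  smoothed marginals. A flat per-cell pseudocount was rejected after
  analysis: it gives never-observed codons -- stop codons, for CDS
  training data -- marginals made purely of pseudocount mass, so their
  expected frequencies are vanishingly small and their log-odds come out
  large and *positive* (for a stop-stop identity, about
  $+\ln(T/4096p)$ at training size $T$). Under the expected-frequency
  scheme every unobserved pair instead shares a uniform negative floor,
  $\ln(4096p/(T + 4096p))$, which deepens as the training corpus grows.
  All 64 codons are carried in the table because the scanner meets stop
  triplets constantly in off-frame and non-coding sequence.
* **Training scale matters.** The pseudocount floor is the matrix's
  penalty for "never seen in coding data"; with only a few thousand
  training codons it is so shallow that the matrix cannot penalise
  non-coding mismatch patterns and the null drift (below) turns positive.
  The package's fixtures and examples train on roughly 200,000 codon
  columns (760 pairs x 260 codons), about one tenth of the
  ~2M-codon ortholog corpus the method is designed around; this is the
  smallest scale at which all calibration diagnostics are comfortable.

## Scanning: six framings and locally maximal segments

A pairwise genomic alignment does not come with a reading frame, so the
scanner evaluates all six framings: frames 0/1/2 of the given strand and
frames 0/1/2 of the joint reverse complement (both rows complemented and
reversed together, preserving column correspondence). Columns containing
a gap or ambiguity in either row terminate codon accumulation; framing
restarts at the next gap-free run, so codon phase is always well defined
and no segment spans a gap (the package deliberately has no gap penalty:
the training rule already excludes indel columns, and inventing a penalty
would add a free parameter the method does not need).

Within one framing the *region score* of a codon range is the sum of its
codon-pair scores. The scanner enumerates every **locally maximal scoring
segment** -- a segment whose score cannot be improved by extending or
shortening either end, and which is not contained in a higher-scoring such
segment -- with the linear-time all-maximal-scoring-subsequences
algorithm over the per-codon score vector. The implementation is validated
in the test suite against an independent brute-force enumeration on
thousands of random score vectors. Ties (possible with discrete scores)
are broken deterministically: leftmost start, then shortest extent.

One consequence worth knowing: a locally maximal segment anchored on a
genuine coding block legitimately stretches into the flanking null
sequence, up to wherever the cumulative score last reached its minimum.
Segment boundaries are therefore fuzzy outward, and block *coverage*, not
exact boundary agreement, is the right way to read the output.

## Significance: extreme-value statistics calibrated by simulation

Scores are only meaningful against chance. For the best segment score $S$
found in a non-coding region of $N$ nucleotides, the package uses the
one-dimensional extreme-value approximation

$$P = \min\{1,\; k N e^{-aS}\},$$

with constants $k$ and $a$ calibrated by simulation rather than derived
analytically -- the calibration-by-simulation route also absorbs the
six-fold framing multiplicity, because the null is scanned with exactly
the same six-frame machinery as real queries.

**The null model.** Aligned neutral DNA between two diverged genomes:
an ancestral i.i.d. sequence at 40% GC, copied, with exactly
`round(0.30 * L)` sites substituted to a different base -- matching the
approximate genome-wide GC content and the ~70% nucleotide identity of
aligned human-mouse DNA. Replacement bases are drawn from a zero-diagonal
kernel built from symmetric flows whose row sums equal the stationary
base probabilities, so detailed balance holds and the expected
composition is *exactly* invariant; transitions carry half of the
minority-composition mass (roughly 40-48% of substitutions), retaining
transition/transversion realism. (The seemingly natural alternative --
redrawing from the stationary distribution restricted to the three other
bases -- is quietly biased: its flows do not balance, and at 40% GC it
enriches the derived sequence to about 41.3% GC, several standard errors
off over 100 kb.)

**Calibration, stage 1 (decay).** All positive locally maximal segments
from `n_sequences` simulated null alignments are collected (cutoff 0, so
the regression sees the widest score range), binned (width 1 nat), and
the natural log of the mean number of segments per sequence exceeding
each bin centre is regressed on the bin centre by ordinary least squares.
Minus the slope is $a$. Bins supported by fewer than one segment per 20
sequences are dropped before fitting: such sparse-tail bins form noisy
plateaus that systematically flatten the slope. The trimming rule is
expressed on the per-sequence exceedance, so duplicating the whole
collection changes nothing.

**Calibration, stage 2 (level).** Because one conserved stretch scores
in several framings at once, segments cluster: the expected *count* of
segments above $S$ overstates the probability that the *best* segment
exceeds $S$ by the inter-frame correlation factor (a factor of 4-6 in
our experiments). Since $P$ in the formula above is a statement about the
best segment, $k$ is re-anchored after the slope fit: with $a$ held
fixed, $\ln k$ is chosen by least squares so that $kNe^{-aS}$ matches the
upper-half order statistics of the per-sequence best scores. Against a
1000-replicate ground-truth simulation this two-stage estimator is
well-centred, while the pure count-based intercept is conservative by the
clustering factor and a best-scores-only fit wastes the precision of the
millions of collected segments.

**What $N$ means.** $N$ is the nucleotide length of the region actually
searched -- the alignment (or exon window) scanned -- not a codon count
and not the whole chromosome. All six framings of one region share one
$N$; the multiplicity is inside $k$ by construction.

**Using the calibration.** `ka_pvalue(S, N, calibration = .)` converts a
score to a P-value; `ka_score_cutoff(p, N, .)` inverts it, and
`scan_alignment()` uses that inversion as its default enumeration cutoff
(so every reported segment carries a meaningful P-value).
Single-calibration runs with 100 sequences retain visible sampling noise
in the tail (the test suite therefore pools three calibration replicates
when checking that fresh null sequences are called significant at the
nominal rate). For production use, more or longer null sequences tighten
the calibration; the defaults reproduce the conditions the method was
described under (100 sequences of 100 kb).

## Filtering predicted exons

`test_exons()` maps each predicted exon interval (coordinates on the
ungapped target row) into the alignment, scans the window (plus an
optional flank, default 0) in all six framings regardless of the exon's
declared strand, takes the best segment score, and computes $P$ with $N$
equal to the window's nucleotide length. An exon passes when
$P \le \alpha$ (boundary inclusive; default $\alpha = 0.01$). Exons that
do not map into the alignment fail with reason `"unmappable"`; windows
with no positive-scoring codon pair get $P = 1$. No multiple-testing
correction is applied across exons -- the flat per-exon cutoff is the
method's operating convention; apply `p.adjust()` to the `p_value`
column if a corrected analysis is wanted.

Evaluation follows exon-level any-overlap truth labelling (a prediction
overlapping an annotated exon by at least `min_overlap` nucleotides on a
compatible strand is a true positive -- boundary mismatches are
accepted), with three reported rates: positive predictive value
$TP/(TP+FP)$, sensitivity $TP/(TP+FN)$, and a false positive rate in the
form $FP/(TP+FN)$. That last denominator is unconventional but is the
form the evaluation scheme defines; where negatives are enumerable
(nucleotide-level ROC with a known total length) the conventional
$FP/(FP+TN)$ is also reported, clearly labelled `fpr_std`. The
filter-effect test is a Pearson chi-square on the 2 x 2 table of TP/FP
counts before versus after filtering, one degree of freedom, no
continuity correction (the counts this test is meant for are in the
thousands, where the correction is immaterial).

## The synthetic-data generator

Every fixture the package needs is generated in code:

* **Coding alignments** (`simulate_coding_alignment()`): ancestral codons
  drawn from a usage vector (uniform over the 61 sense codons by
  default), the partner derived by per-codon events -- a *synonymous*
  event replaces the codon by a single-nucleotide neighbour encoding the
  same amino acid, a *nonsynonymous* event by a single-nucleotide
  neighbour encoding a different one, both transition-biased
  (`transition_bias` = 4, a typical mammalian value), both refusing to
  create stop codons. Defaults: synonymous 0.4 and nonsynonymous 0.05
  events per codon, giving ~86% nucleotide and ~58% codon identity with
  first/second-position identity near 0.97-0.98 -- the conservation
  profile of a typical mammalian ortholog pair. Synonymous events are
  single-nucleotide changes, not whole synonymous-class swaps: class
  swaps (Ser TCx <-> AGy, Leu TTR <-> CTN) would corrupt exactly the
  first/second-position conservation that makes the matrix discriminate.
* **Non-coding alignments** (`simulate_noncoding_pair()`): the null model
  above.
* **Mosaics** (`build_mosaic()`): coding blocks planted at known
  coordinates (minus-strand blocks reverse-complemented) in a non-coding
  background, with truth annotations; `simulate_predictions()` overlays
  jittered true exons and short false ones, emulating a gene finder's
  error profile.
* **Bundles** (`make_fixture_bundle()`): a complete miniature experiment
  on disk (training FASTA, matrix TSV, calibration JSON, mosaic, GFF3
  truth and predictions, MD5 manifest), byte-reproducible per seed.

What the generator does *not* emulate: splice sites, introns with
consensus structure, promoters, UTRs, CpG hypermutability, codon-usage
variation along genes, indels inside exons, and alignment error. Passing
tests on this synthetic world demonstrate that the scoring, scanning,
calibration and evaluation machinery is correct and self-consistent --
not that any particular sensitivity/PPV figure will transfer to real
genomes. One quantitative difference is worth stating: with uniform
codon usage and these rates the synthetic matrix separates coding from
non-coding much more weakly than a matrix trained on real orthologs, so
the fitted decay $a$ is of order 0.04/nat and significant segments need
hundreds of nats. The calibration machinery is scale-free and handles
either regime; only the absolute score thresholds differ.

## Problem sizes and numerical conventions

* Default experiment sizes: training 760 pairs x 260 codons; calibration
  100 null sequences (10-100 kb; the package's own analyses use 10-20 kb
  and the per-nucleotide normalisation of $k$ makes the fitted constants
  comparable across lengths); benchmark mosaics of 15 kb with six planted
  exons (20-150 codons) and eight false predictions, 20 replicate seeds.
* Coordinates: 0-based half-open in all interval tibbles; 1-based closed
  in GFF3 on disk; BED stays 0-based half-open; alignment columns and
  ungapped positions in scan output are 1-based inclusive.
* Segment accumulation uses extended-precision partial sums so that tie
  handling matches R's own `cumsum()` semantics exactly.
* Degenerate inputs: an empty alignment scans to an empty table; a
  framing shorter than three usable columns is a zero-row view; an
  all-negative score vector has no maximal segments; a matrix built with
  `pseudocount = 0` may contain `-Inf` (documented sentinel) and is then
  rejected by the scanner, which requires finite scores.
* Determinism: every stochastic stage accepts a seed (model objects carry
  it); identical seeds give byte-identical sequences, matrices,
  calibrations and fixture bundles.

## Known limitations

* The filter needs a homologous partner sequence and a trustworthy
  pairwise alignment; exons outside the aligned region are untestable and
  are reported as failed with a reason, which conflates "no evidence"
  with "evidence against" if read carelessly.
* Genes under unusual selection (the classic example being MHC loci,
  which evolve under positive selection with atypical substitution
  patterns) do not match an averaged matrix and will be penalised.
* $P = kNe^{-aS}$ is an asymptotic approximation; for very short windows
  (a few codons) it is rough, and the per-window $N$ makes P-values
  across exons of different lengths not strictly comparable as evidence.
* Matrices, calibrations and alignments must belong together: a
  calibration is valid only for the matrix it was simulated with (the
  `matrix_id` field is there to catch mismatches, not enforce them).
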