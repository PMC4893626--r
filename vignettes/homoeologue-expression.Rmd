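---
title: "Analysing homoeologue expression in hybrid and allopolyploid transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing homoeologue expression in hybrid and allopolyploid transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoexpr)
```

## The biological problem

When two species hybridize, the offspring carries one gene copy from
each parental genome; after whole-genome duplication the resulting
allopolyploid carries two of each.  The two copies of every gene --
its *homoeologues* -- sit in a common nuclear and cellular environment
but keep their parental cis-regulatory sequences.  Two questions
organise the analysis of such transcriptomes:

1. **Expression level dominance (ELD).**  At the whole-gene level,
   does the hybrid's total expression resemble the maternal parent
   (R), the paternal parent (C), their mid-parent average, or neither?
2. **Homoeologue expression bias (HEB).**  Within the hybrid, do the
   R- and C-derived copies contribute equally to that total, and does
   any imbalance repeat the parental divergence or arise anew?

The package implements a complete read-count pipeline for a four-group
design -- maternal parent R, paternal parent C, an F1 diploid hybrid
and a later-generation allotetraploid (called F18 throughout, after
the study system it emulates: an eighteenth-generation allotetraploid
of red crucian carp, maternal, crossed with common carp) -- plus a
synthetic-data generator that fabricates the whole experiment with
known ground truth.

## Differential expression on pooled counts

Expression is normalized as RPKM (reads per kilobase of exon per
million mapped reads).  For a contrast between groups A and B each
gene's replicate counts are pooled per group and tested with a
two-sided Fisher's exact test on the 2x2 table

    [ count_A          count_B        ]
    [ lib_A - count_A  lib_B - count_B ]

where `lib` is the pooled library size (total mapped reads).  The
two-sided p-value follows the point-probability rule -- the sum of the
probabilities of all tables no more probable than the observed one --
which is the convention of standard exact-test implementations, and is
verified in the test suite against both an independent
binomial-coefficient enumeration and `stats::fisher.test` for every
table with margins up to 30.  P-values are Benjamini-Hochberg adjusted
across genes (`stats::p.adjust`), and a gene is called `up` or `down`
only when q <= 0.05 **and** the fold change exceeds 2 (|log2FC| > 1).
The fold change is computed from RPKM of the pooled counts with a
pseudocount of 0.5 added only there (never to the test), so silenced
genes get a finite fold change.

Three choices deserve comment:

* **Replicates are pooled**, not modelled.  The replicate structure
  enters only through the prefilter (a gene must have >= 1 read in
  every biological replicate of every group) and through pooling.
  This mirrors the two-library exact-test design that the RPKM +
  Fisher + FDR convention comes from.  Pooling makes the test
  anti-conservative in the presence of biological overdispersion; the
  fold-change gate is what keeps the false-call rate controlled, and
  the null-calibration test (2,000 simulated genes with no programmed
  effects at negative-binomial dispersion 0.05) checks exactly this.
* **"Fold change > 2"** is interpreted on normalized expression, as
  |log2 RPKM ratio| > 1.
* **FDR <= 0.05** is applied to the BH-adjusted q-value.

## The twelve-category dominance classification

Each gene of a hybrid gets three calls: hybrid vs R, hybrid vs C, and
R vs C.  Of the 27 possible call triples, 12 map to the Roman-numeral
categories, the all-`ns` triple is `conserved`, and the remaining 14
(e.g. a hybrid indistinguishable from both parents while the parents
differ) are `ambiguous` rather than forced into a category:

| category | hybrid vs R | hybrid vs C | R vs C | reading |
|---|---|---|---|---|
| VII  | up   | ns   | down | paternal dominance, expression up |
| VIII | down | ns   | up   | paternal dominance, expression down |
| IX   | ns   | down | down | maternal dominance, expression down |
| X    | ns   | up   | up   | maternal dominance, expression up |
| XI   | up   | down | down | intermediate, R < C |
| XII  | down | up   | up   | intermediate, R > C |
| I-III  | down | down | any | below both parents (R>C / R=C / R<C) |
| IV-VI  | up   | up   | any | above both parents (R<C / R=C / R>C) |

The assignment of VII/VIII to the paternal side and IX/X to the
maternal side, and the membership of the four directional gene lists
(hybrid up/down versus each parent), are fixed by the categorisation
scheme of Rapp, Udall and Wendel (2009), which this table follows.
The numeral order *within* the transgressive trios I-III and IV-VI is
not recoverable from published category totals (any permutation gives
the same directional lists); the parental-relation ordering above is
therefore a documented convention of this package.  Two enumeration
tests pin the table down: the 27 triples partition exactly into
12 + 1 + 14, and swapping the two parents' roles maps VII<->X,
VIII<->IX, XI<->XII, I<->III, IV<->VI and fixes II and V.

## Homoeologue-specific reads

Orthologue pairs between the two parental transcript sets are called
by reciprocal best BLASTN hits (e-value <= 1e-20, alignment >= 300 bp;
ties broken deterministically by e-value, then alignment length, then
subject id, so the orthologue set is reproducible).  Diagnostic SNPs
are the mismatched columns of the pairwise global alignment of each
pair, optionally validated against parental pileups: a site is kept
only if each parent with coverage >= 5 shows its expected allele at
frequency >= 0.9.  These two validation thresholds are package
defaults chosen at values typical of fixed-difference validation; the
procedure, not the numbers, is the load-bearing part.

A hybrid read votes R at every diagnostic site where it carries the R
allele and C at a C allele; it is assigned to the majority-vote bin
and is `ambiguous` on a tie, when it covers no informative site, or
when its alignment is not a simple gap-free match.  The per-read rule
is a package convention (the classic custom-script approach is not
specified at read level); binning conservation (R + C + ambiguous =
reads overlapping the pair) and 100% fidelity of non-ambiguous
assignments on error-free synthetic reads are asserted in the tests.

**Silencing and novel expression** are called at 10 reads per million
mapped reads of the library: an R homoeologue silent in the hybrid
while parent R expressed the gene is R-silencing (C symmetric), and a
gene expressed in the hybrid while silent in both parents is novel
expression.  Per-million normalization against the library's total
mapped reads is the default; normalizing against informative
(assigned + ambiguous) reads is available through the `lib_size`
argument since the choice is not dictated by the threshold's wording.

## Bias states and transitions

The parental bias state of a pair is the whole-gene DE call between
the parental libraries (`R>C`, `R=C`, `R<C`).  The progeny state
tests the hybrid's R bin against its C bin with a two-sided Fisher's
exact test against equal expectation at P < 0.05 (per pair, no
multiplicity correction -- a significance call in the style of the
transition table it mirrors).  The 1:1 null is a deliberate choice:
the F1 carries one copy of each homoeologue and the allotetraploid
two of each, so equal contribution is the dosage-neutral expectation
at both ploidies.  A null proportional to the parental read ratio is
possible by pre-scaling the bins, but is not the default.

Transitions over the 3x3 (parental, progeny) grid are a total
function: 3 cells keep the parental condition (including the unbiased
diagonal cell), 2 cells lose parental bias, 4 cells show novel bias
(bias from unbiased parents, or reversal).  Two summary rows
complement the grid: **overall bias** (R or C only when the progeny
test is significant) and **potential bias**, which assigns *every*
pair by whether the normalized R/C ratio exceeds 1.  A ratio of
exactly 1 is not "greater than 1" and therefore counts as potential C
bias; the tie is documented here because it is arbitrary, and it only
matters for identical bins.  Pairs with zero reads in both bins are
reported as `R=C` with a `no_data` flag rather than dropped.

## Mid-parent trajectories: merger versus doubling

The mid-parent value (MPV) of a gene is the average of the two
parents' replicate-mean RPKM -- the additive expectation for a
hybrid.  Because the exact-test machinery needs integer counts, the
MPV enters DE testing as a pseudo-library: pooled R plus pooled C
counts halved and rounded, with the pooled library sizes likewise
averaged.  This preserves the Fisher machinery instead of inventing a
new statistic for one contrast.

Three calls -- MPV vs F1, MPV vs F18, F1 vs F18 -- partition genes
into: `no-change` (all ns), `doubling` (MPV = F1 but F1 != F18:
hybridization left expression additive, polyploidization moved it),
`merger` (MPV != F1 = F18: hybridization moved it and doubling kept
it), and `other`.  "Equality" between F1 and F18 is a direct DE test
between their libraries, not identity of category labels, because the
partition's =/!= notation is the same one used for the MPV contrasts;
the same partition applied to bias states (`classify_heb_trajectory`)
uses state identity, since states are already trichotomous.  Both
partitions are verified exhaustively (27 call triples split 1/6/6/14;
27 state triples split 3/6/6/12).

## Homoeologue-specific qPCR

Relative expression uses the 2^-ddCt method (amplification efficiency
assumed 2.0; efficiency correction is out of scope) against a
reference-gene assay and a calibrator sample.  The homoeologue ratio
reported by `homoeolog_bias` defaults to the **expression ratio**
2^(meanCT_C - meanCT_R), because a lower CT means more transcript; a
raw mean-CT ratio (meanCT_R / meanCT_C) is also implemented because
published figure legends sometimes print that convention ("CT ratio >
1 = R bias") even though it runs against CT semantics.  Both modes
give the same *direction* of call; only the reported ratio differs.
Bias is called at P < 0.05 by a t-test on replicate CT differences
(paired when replicate counts match); technical replicates in perfect
agreement are treated as exact (p of 0 or 1), which only occurs with
noise-free data.  A homoeologue undetected in all replicates is
reported as a silenced side, mirroring non-amplification of one
homoeologue-specific primer pair.

## The synthetic-data generator

`sim_design()` fixes the experiment the package validates against:
four groups with 3 biological replicates, one million mapped reads
per library, gene lengths uniform on 500-2,000 bp, fixed R/C
differences at 1% of sites, negative-binomial counts with dispersion
0.05 shared across groups, and log-normal baseline expression (sdlog
0.5).  Effects are programmed at 4-fold: any two unequal expression
levels differ by at least that factor, and a biased homoeologue pair
splits 4:1.  The category mix defaults to 70% conserved with the 12
categories sharing the rest; the transition mix defaults to the
parental condition dominating (70%), bias loss (14%) and novel bias
(12%), with silencing (0.35%) and novel expression (0.1%) at the
per-mille scale on which such events are reported in hybrid
transcriptomes.  These defaults are the package's standing study
conditions; tests do not tune them.

Internal consistency requires care in three places:

* **One parental relation per gene.**  A gene's dominance category
  and its bias transition both imply an R-vs-C relation, and the two
  hybrids share one pair of parents.  The generator therefore draws
  the parental relation first (from the category-mix marginal), then
  draws each hybrid's category and each hybrid's progeny state
  conditional on it.  Mixture proportions are honoured conditionally;
  the marginal over parental states follows the category mix.
* **Level placement.**  With effects at fold f, unequal parents
  differ by f, except for genes carrying an intermediate category
  (XI/XII) in either hybrid, which need a mid level separated from
  both parents by f and so get an f^2 parental ratio.  Keeping most
  effects at f keeps each library's total programmed mass close to
  the others -- important because RPKM-plus-exact-test inherits the
  compositional bias of total-count normalization, and a generator
  that loaded one library with heavy transgressive mass would shift
  every null gene's apparent fold change.  Real transcriptomes keep
  this shift small for the same reason: differentially expressed
  genes are a small mass fraction.
* **Homoeologue splitting.**  A hybrid gene's total count is
  negative-binomial; the split between its R and C components is
  binomial at the programmed mixing proportion, conditional on the
  total.  Biologically, the allelic ratio within a sample is
  cis-regulated and far more stable than total expression, so
  replicate-level biological noise belongs on the total, not on each
  component independently; statistically, this makes the exact test's
  sampling assumption for the progeny-state call correct rather than
  overdispersed.

Silencing and novel-expression genes are drawn from the fully
conserved pool so the rest of the programme is untouched (an
oversubscribed pool rejects the design, naming the genes).  Reads for
hybrid libraries are drawn per homoeologue in numbers equal to the
simulated component counts, with the true origin recorded in the read
name and alignments written as gap-free SAM records against the R
transcript -- valid because orthologue pairs differ only by
substitutions.  No sequencing errors are simulated by default, which
keeps binning ground truth exact.  CT tables use
ct = baseline - log2(expression) + Gaussian noise, with silenced
components emitted as not-detected.

What the generator does **not** emulate: splice isoforms, GC and
length biases, sequencing errors, indels between homoeologues,
multi-mapping across paralogues, and partially informative reads
(simulated alignments are gap-free and full-length).  Passing
recovery tests therefore demonstrates the correctness of the
statistical machinery under its own assumptions, not robustness to
alignment artefacts in real data.

## Validation sizes and numerical choices

The test suite runs the recovery and calibration checks at 2,000
genes and one-million-read libraries -- large enough that a 4-fold
effect at average coverage is detected with near-certainty, so
recovery failures indicate classification errors rather than power --
and the exact-test oracle exhaustively covers all 2x2 tables with
margins up to 30.  Read-level checks use smaller designs (tens of
genes, tens of thousands of reads) where per-read bookkeeping is
cheap.  Percentages in report tables are rounded half-up at the
printed precision (so 62.5% prints as 63%, not banker's-rounded), and
every printed percentage is re-derived from its own count and
denominator by an audit that fails the run on any mismatch.

## Known limitations

* Pooled-count exact tests ignore replicate variance; with strong
  biological overdispersion the q-values are optimistic and only the
  fold-change gate protects the calls.  A replicate-aware NB GLM
  (edgeR/DESeq2 style) is deliberately out of scope because the
  pipeline reproduces the pooled-test convention.
* The progeny-state test's 1:1 null is an assumption; pairs with few
  informative reads default to `R=C`, so bias prevalence is
  underestimated at low coverage.
* `ambiguous` dominance triples and `other` trajectories are reported,
  not interpreted.
* Orthologue calling trusts the supplied BLAST tables; the package
  does not run the aligner or BLAST itself.
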