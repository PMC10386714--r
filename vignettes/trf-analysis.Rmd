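---
title: "Analysing tRNA-derived fragments and m7G tRNA methylation with trfscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing tRNA-derived fragments and m7G tRNA methylation with trfscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfscope)
```

## The biological problem

N7-methylguanosine (m7G) sits in the variable loop of many tRNAs — position
46 in standard tRNA numbering — where it is written by the METTL1/WDR4
complex. When the mark is lost, a subset of tRNAs (notably tRNA-Cys and
tRNA-Ala) is cleaved into small fragments. The fragments of interest are 5'
tRNA-derived fragments beginning with a run of terminal guanosines
("5'TOGs": 5 G when Cys-derived, 4 G when Ala-derived, around 20 or 30 nt
long), which displace initiation factors from mRNA caps and repress
translation. Detecting this axis in data requires four bespoke
computations: classifying small-RNA reads into a tRF taxonomy, testing
fragments for differential abundance between wild-type (WT) and knockout
(KO) conditions, mapping m7G positions from aniline-cleavage (AlkAniline-seq)
5'-end pile-ups, and screening RNA-modifying proteins for coherent
differential expression across tumour cohorts. `trfscope` implements each
stage, together with synthetic-data generators that emulate the inputs.

## Fragment classification

Reads are trimmed (3' adapter at its first occurrence with one mismatch
tolerated in matches of at least 10 nt; reads below 23 nt dropped; 4 nt
then removed from both ends) and placed on a compact mature-tRNA reference
by an exhaustive best-stratum Hamming scan (`align_fragments()`, default at
most 2 mismatches, reads with more than 500 loci discarded). This emulates
ungapped short-read alignment with `-v 2 -m 500`-style semantics while
staying simple enough to verify against a brute-force scan, which the test
suite does exhaustively. External alignments (SAM/BAM/BED) can be ingested
instead (`ingest_alignments()`), with secondary alignments merged into one
fragment record.

Fragment identity is the trimmed read *sequence*, not the locus: by
default a multi-mapped read contributes exactly one count, with its loci
carried as annotation, which keeps totals equal to aligned reads. How the
original extraction apportioned multi-mapped reads is not documented, so a
`count_mode = "per-locus"` alternative (one count per locus) is exposed on
`count_fragments()`.

The taxonomy is applied per locus with the windows in priority order
(5'-anchored before 3'-anchored before internal):

* `start < 10` (0-based): 5'-anchored. Length > 35 nt → `FIVE_HALF`;
  otherwise a 5'-terminal G run of at least `min_tog_g` (default 4) →
  `FIVE_TOG`; else `FIVE_PRIME_TRF`. The textual rule admits starts down to
  −10, but upstream starts cannot occur on a mature-tRNA reference, so the
  lower bound is vacuous here.
* `trna_len − end < 10` → `THREE_PRIME_TRF`.
* otherwise `INT_TRF`.

Rows whose loci disagree are `AMBIGUOUS` by default (a majority policy is
available; ties stay ambiguous). Retained lengths are 18–50 nt inclusive;
rows with fewer than 10 raw counts over all samples are removed and a
pseudo-count of 1 is then added. Two boundary choices were genuinely open
and are parameters: a fragment of exactly 35 nt goes to the short-5' branch
(`half_min_len = 35`, exclusive), which makes the partition total; and
`min_tog_g` defaults to 4 because the observed 5'TOGs carry 4 (Ala) or 5
(Cys) terminal G but no minimum is prescribed — lowering it can only grow
the 5'TOG class (a monotonicity the tests assert).

## Differential abundance

Counts are normalised with median-of-ratios size factors
(`size_factors()`; library-size fallback with a warning when no fragment is
positive everywhere). For each fragment the test compares group means of
normalised counts on the log2 scale:

* log2FC = log2((μ̂_KO + ε)/(μ̂_WT + ε)) with ε = 0.5 normalised counts, so
  estimates stay finite at zero means (the classification stage's
  pseudo-count already mitigates zeros);
* Wald statistic log2FC / SE with the delta-method SE under
  Var(K) = μ + αμ²; two-sided normal p-values; Benjamini–Hochberg
  adjustment over tested rows. All-zero rows get log2FC 0 and p 1. A Wald
  test (the default of the NB tools this stage replaces) was chosen over a
  likelihood-ratio test: it needs no per-fragment GLM fits and its
  calibration is directly checkable by simulation.

The dispersion α is estimated by method of moments from pooled
within-group variances of normalised counts. At 2–4 replicates per group a
*per-fragment* moment estimate is extremely noisy (4 degrees of freedom at
3 vs 3), and plugging it into a normal-reference Wald test inflates the
type-I error well above nominal. The default therefore pools the estimate
across fragments (the mean of per-fragment estimates, floored at 1e-8),
which is nearly unbiased and gives close-to-nominal calibration; the
acceptance tests verify a rejection fraction between 0.03 and 0.07 at
p < 0.05 on 10,000 null fragments (α = 0.1, mean 100, 3 vs 3).
`dispersion = "per-fragment"` keeps the raw estimate for users who want
fragment-specific variances and accept the anticonservative behaviour.
Dispersion shrinkage, outlier handling and GLM covariates are deliberately
out of scope.

Enriched fragments are flagged at log2FC > 2 and raw p < 0.05 by default —
raw because that is how the discovery threshold is stated; the adjusted
p-value is computed and reported, and `use_adjusted = TRUE` switches the
flag. The looser preset (1.5, 0.05) used for fragment size/abundance
summaries is one argument away.

## m7G site calling from cleavage profiles

For each species, condition and replicate, NCleavage divides each
position's 5'-end count by the species' total; fractions sum to 1 and are
invariant to sequencing depth (both assertions in the tests). Calling uses
the KO as control: a position p is a candidate when the base at p − offset
is G in the reference, and is called when the mean WT fraction at p is at
least `min_frac` (default 0.05) and the smoothed ratio
(WT + δ)/(KO + δ) is at least `min_ratio` (default 5), with δ = 1 / mean
profile depth preventing division by zero on clean knockouts. The reported
site is the guanosine p − offset; among several called positions per
species the largest WT − KO difference is marked as the top site.

Two choices here are declared surrogates for procedure left implicit in the
original workflow. First, the registration `offset = 1`: aniline scission
3' of the abasic site leaves the downstream fragment's 5' end one position
after the modified G; offset 0 is supported for pipelines registered
differently. Second, the thresholds: the original call of "methylated"
isoacceptors is visual, so `min_frac`/`min_ratio` were fixed once at values
that separate a 0.3-fraction signal from multinomial background by an
order of magnitude, and are exposed as arguments. On planted simulations
(signal fraction 0.3, depth 10^4) the caller's precision and recall exceed
0.9 over 20 independent references, and on unannotated species the
background per-position fraction stays an order of magnitude below
`min_frac`.

## The cross-cohort expression screen

Per cohort, a gene's tumour-class Z-score is the class *mean* minus the
reference (N) mean, divided by the reference SD (n−1). The phrase
"expression of cancerous samples" could also be read per sample (mean of
per-sample Z); both agree up to the shared SD normalisation, and the
group-mean reading is the default. Per-cohort significance is a classical
equal-variance one-way ANOVA across the groups present (cohorts lacking a
class fall back to the groups they have; with two groups this is exactly
the pooled-variance two-sample test, F = t²). A gene is a hit when it is
significant in at least `min_datasets = 3` cohorts *and* its coherence
(percent of containing cohorts in which it is significant) is at least 75 —
a conjunctive reading, so a gene significant in 2 of 2 cohorts has
coherence 100 but is not a hit. Non-significant cohort Z-values are
reported alongside a `significant` indicator matrix rather than blanked
out. With a +2 SD shift planted in P and M across five cohorts of
10/10/10 samples, per-cohort ANOVA power is essentially 1 and the screen
recovers the gene in at least 95 % of runs while flagging at most 1 % of
null genes — both checked in the acceptance tests.

## PAR-CLIP and polysome quantification

`parclip_quant()` computes RPM (1e6·count/library size), RPKM
(1e3·RPM/length) and log2((RPM_IP + 1)/(RPM_control + 1)) enrichment, with
per-RNA-class median log2 RPM summaries. `cv_filter()` removes peaks seen
in fewer than two replicates, then keeps those with CV = 100·sd/mean below
30 %. `polysome_proportions()` normalises each transcript's per-fraction
abundance by its total; `polysome_fc()` is the ratio of polysome to
non-polysome shares, returning `Inf` (flagged) for transcripts with all
mass in polysome fractions and `NA` for empty rows. The lab formulas —
volume `(length × width)² × 0.526` (kept verbatim although it differs from
the usual ellipsoid proxy (width² × length)/2) and OD = log10(255/mean)
(base 10, the optical-density convention; the printed formula leaves the
base implicit) — live in `tumour_volume()` and `dab_od()`.

## What the generators emulate — and what they do not

All simulated quantities derive per-purpose RNG streams from one global
seed (`split_seed()`), so adding a new simulated quantity never perturbs
existing fixtures.

* `make_trna_reference()` builds ~76-nt species with an anticodon at
  34–36, terminal CCA, and a variable-loop guanosine at index
  `length − 31` (position 46 on a 76-mer) for the annotated species, which
  double as TOG sources with 5 or 4 leading G. Real tRNAs vary in length
  and post-transcriptional processing; nothing downstream hard-codes
  position 46 — every species carries its own annotation.
* `simulate_fragment_reads()` draws per-fragment counts from NB(μ, αμ²+μ)
  with α = 0.02 by default — the order of dispersion typical of
  near-isogenic cultured clones — around means set by the design:
  full-length reads (35 % of depth), planted 5'-anchored TOG fragments of
  20 and 30 nt at 400 expected WT counts with a log2 excess of 3 in KO,
  and random background fragments sharing the remaining mass. Technical
  library-size factors vary at most two-fold. Reads are exact substrings:
  no sequencing errors, adapter artefacts or UMIs are simulated, so
  passing tests demonstrate the pipeline's logic, not robustness to
  base-calling noise (mismatch tolerance is exercised separately with
  mutated copies).
* `simulate_cleavage_profiles()` draws multinomial 5'-end counts with the
  signal fraction (0.3 WT, 0.005 KO) at the registered position and
  uniform background elsewhere. Real AlkAniline-seq background is
  position-dependent (other modifications, structure); uniform background
  makes the caller's thresholds interpretable but optimistic.
* `simulate_expression_cohorts()` uses unit-variance Gaussian noise on the
  log2 scale with planted SD-unit shifts; real cohorts have
  platform-specific variance structure and batch effects.
* `simulate_polysome_profile()` concentrates unshifted transcripts in early
  fractions (exponential decay) and moves a set mass fraction of shifted
  transcripts into the polysome fractions. Consequently the absolute
  polysome fold change of unshifted transcripts is far below 1 — what is
  meaningful (and tested) is that it is uniform across transcripts and
  rises monotonically with shifted mass.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally and 1-based in reports
(`site_1based`). Empty inserts, adapter-only reads and sub-minimum reads
are dropped with tallies; non-nucleotide reads are skipped with a warning
count. Zero-depth designs produce empty read collections; zero-total
cleavage profiles yield all-zero fractions with a warning and are excluded
from calling; all-zero count rows test as null (log2FC 0, p 1); zero
reference-group SD yields a missing Z with a warning. Tie-breaks are
deterministic everywhere (first locus primary in SAM export, largest
WT − KO difference for top sites, majority-class ties fall to
`AMBIGUOUS`).

## Problem sizes used by the checks

The suite runs at desk scale, chosen so each behavioural claim is measured
with adequate Monte-Carlo resolution: classifier/oracle equivalence is
exhaustive (~1,000 start/length pairs on a 76-nt species); null
calibration uses 10,000 NB fragments at 3 vs 3; fold-change recovery uses
50 simulated experiments; m7G precision/recall uses 20 independent
references at depth 10^4; the screen uses 100 planted runs plus one
10,000-gene null screen; aligner/brute-force agreement uses 500 random
reads against a 4-species reference.

## Known limitations

The aligner is an exhaustive scanner intended for compact tRNA references
(≲ 10^5 nt), not genomes; alignments are ungapped and sense-strand only.
The NB test has no dispersion shrinkage, so per-fragment mode is
anticonservative at small n (hence the pooled default). The m7G caller
assumes the KO is a clean control; residual methylation inflates the
denominator and costs sensitivity. tRF nomenclature databases, CCA-aware
3'-variant collapsing, survival analysis and deconvolution are out of
scope.
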