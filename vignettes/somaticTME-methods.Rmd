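---
title: "Models and methods behind somaticTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somaticTME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

somaticTME computes the tumour-genomic and tumour-microenvironment
features used to characterise whole-genome-sequenced cancer cohorts:
mutational and rearrangement signatures, kataegis and its
co-localization with rearrangement breakpoints, copy-number and
homologous-recombination-deficiency (HRD) features, chromothripsis-like
complex events, immune subtypes from bulk expression, and survival
stratifications. Because the patient-level data such pipelines are run
on is access-restricted, the package ships a synthetic cohort generator
with complete ground truth; every module is validated by recovering what
the generator planted.

## Mutational signatures

Per-sample SNV catalogues are counted over the 96 trinucleotide
substitution channels (pyrimidine-strand normalised; channel order is
substitution-class major, 5' then 3' flank). Signatures are extracted by
non-negative matrix factorisation with the Frobenius objective and
multiplicative updates — the simplest defensible NMF variant — using by
default 50 random restarts, relative-change tolerance 1e-6 and at most
10,000 iterations; the best restart by reconstruction error is kept, the
signature rows are normalised to probabilities and ordered by attributed
mutation load. NMF is only identifiable when the data cone is anchored
by near-pure samples (separability); the synthetic reference signatures
are therefore sparse, as real substitution signatures are.

Exposures are refit per sample by constrained least squares: minimise
\(\lVert m/\lVert m\rVert_1 - S^\top e\rVert_2^2\) subject to
\(e \ge 0,\ \sum_i e_i = 1\), solved as non-negative least squares on a
sum-to-one-augmented system and renormalised. Refits are checked in the
tests against a dense simplex grid search (step 0.01). The
overfitting guard then iteratively drops the smallest exposure below
10% (ties by signature index) and refits on the remaining signatures
until every retained exposure is at least 10% or one signature remains.
Whether that guard was originally applied once or to a fixed point is
ambiguous; we iterate, which is the stricter reading and idempotent.

Extracted signatures are matched to a reference set by cosine
similarity; matches with cosine below 0.80 are reported with a
"-like" suffix, mirroring how weakly matching rearrangement signatures
are conventionally named. Reference profiles load from TSV; no COSMIC
vectors are embedded (licensing and version drift), and all tests use
synthetic references.

## Rearrangement signatures

SVs are classified into 32 classes: deletions, duplications and
inversions in five half-open size bins ([1, 10) kb, [10, 100) kb,
[100 kb, 1 Mb), [1, 10) Mb, [10 Mb, inf)) plus translocations, each
split by a clustered-breakpoint flag. An SV is clustered iff either
breakend falls in a fixed 1 Mb genome bin holding at least 10 of that
sample's breakends — the quoted, deterministic rule, preferred over
distance-based interval merging. Flags are per sample; sub-1 kb sizes
clamp into the lowest bin with a warning, and a size of exactly 10 Mb
belongs to the top bin. The same NMF/cosine machinery as for SNVs runs
on the 32-channel catalogue; no exposure pruning is applied to
rearrangement signatures (the 10% rule is stated for substitution
signatures only) — presence thresholds are applied downstream instead.

## Kataegis

Hypermutation is detected per sample with sliding windows (default
10 kb window, 5 kb step). Each window's mutation count is tested with
an exact binomial upper tail under a uniform per-bp rate (the
chromosome's mutation total over its length); the 32 per-trinucleotide
compositions are likewise tested against the chromosome's trinucleotide
frequencies, and the smallest such p-value is reported per window.
Count p-values are BH-adjusted pooled across all windows of the sample
(empty windows count toward the family size; they carry p = 1 and so
never change another window's q-value). Overlapping significant windows
are merged, and a merged region is a locus iff it contains at least 6
mutations with mean inter-mutation distance at most 2 kb — the
field-standard kataegis definition, used because the upstream tool's
exact score formulas are unpublished; absolute locus counts are
therefore not comparable to counts from that tool, but the planted-
cluster recovery suite pins sensitivity and specificity. The APOBEC
score of a locus is the fraction of member mutations that are C>T or
C>G at TCA/TCT (TpCpW); a locus is APOBEC iff the score is at least 0.5
(boundary inclusive).

## Kataegis-SV co-localization

APOBEC loci and SV breakends are pooled over the cohort into fixed 1 Mb
bins (a locus increments every bin it overlaps; every SV contributes
both breakends). A bin is co-localised iff both counts strictly exceed
their genome-wide per-bin means — the plain-means reading of the
published rule; a z-score variant (mean + z sd) sits behind the `z`
argument. The per-chromosome co-localised frequency is the percentage
of flagged bins; a chromosome is enriched iff that frequency strictly
exceeds the mean frequency over chromosomes (recomputed from the data,
never hard-coded). The combined percent multiplies (a) the proportion
of samples with at least one APOBEC locus on the chromosome by (b) the
co-localised frequency, and chromosomes are ranked descending with ties
sharing the minimum rank. Frequency (a) is a sample proportion rather
than a locus share; the brute-force oracle tests cover the whole
chain on toy genomes.

## Copy-number and HRD features

Ploidy is the length-weighted mean total copy number. Percent genome
altered counts bases with total copy number different from 2 — an
absolute baseline, not one relative to rounded ploidy; the choice
matters only for near-tetraploid genomes and is deliberate for
simplicity. Categories follow the quoted thresholds (0 homozygous
deletion, 1 loss, >= 6 gain/amplification), and a gene is amplified iff
ploidy < 2.7 and copy number >= 6, or ploidy >= 2.7 and copy
number >= 9. Sub-clonal burden sums the lengths of segments with
sub-clonal q < 0.05 per chromosome and genome-wide, divided by the
respective lengths.

HRD components follow the standard genomic-scar conventions (the cited
scar calculator does not print its thresholds, so they are explicit
configurable arguments here): LOH counts segments with minor copy
number 0 longer than 15 Mb not spanning a whole chromosome; telomeric
allelic imbalance counts minor-unequal-major segments reaching a
telomere, not crossing the centromere, longer than 11 Mb; large-scale
transitions count adjacent-segment breakpoints with both flanks at
least 10 Mb after smoothing away segments under 3 Mb. HRD-sum is their
unweighted sum; a sample is HRD iff HRD-sum > 42 and an externally
supplied HRDetect probability > 0.7 (indeterminate when the probability
is absent and HRD-sum > 42 — the trained classifier is consumed, never
reimplemented).

## Complex events

Per chromosome: interleaved clusters are connected components of the
overlap-without-nesting relation on intra-chromosomal SV intervals;
copy-number oscillations are the longest run of consecutive
state-alternating segments confined to two (or three) distinct values,
counted as steps; breakpoint enrichment is a binomial upper tail with
success probability chromosome length over genome length, BH across
chromosomes; the exponential-spacing test compares inter-breakpoint
gaps against the exponential law with the known chromosome-wide rate
(breakpoint count over chromosome length) by a one-sample KS test —
locally clustered breakpoints produce gaps far below that rate's
expectation and reject. (Without a region length the rate is estimated
and the scale-free KS statistic is compared against a cached
Monte-Carlo null instead.) The fragment-joins test is a chi-square
goodness-of-fit of the four join types (deletion-like, duplication-like,
head-to-head and tail-to-tail inversion) against equal proportions,
with a simulated p-value at small counts; inversions without
orientation are split evenly between the two inversion types. An event
is called when interleaved > 10, oscillations > 6, enrichment q < 0.05,
exponential q < 0.05 and joins q < 0.2 (criterion A), or
interleaved > 30 with exponential q < 0.05 (criterion B). A sample is a
complex genome with at least one called event by default; the stricter
"more than one" variant is exposed via `min_events` because the two
published phrasings disagree and the cohort-level count supports the
inclusive one.

## Immune subtyping

Cell-type abundance proxies are single-sample rank-based enrichment
scores in the ssGSEA form (weight exponent 0.25, running-sum statistic
normalised by the out-of-set gene count); this fully specifiable
statistic stands in for kernel-based GSVA scoring, and the clustering
consumes z-scored values either way. Consensus k-means selects k by
four votes — elbow (largest second difference of within-cluster sum of
squares), mean silhouette width, the gap statistic with 50 references,
and the Calinski-Harabasz index — requiring 3-of-4 agreement, else the
silhouette winner with a warning. The published fourth criterion,
"Euclidean distances", is not a k-selection rule as written;
Calinski-Harabasz (Euclidean-based) stands in and is flagged here
deliberately. The final assignment is the run among 1000 random-restart
k-means runs that agrees best with the co-assignment consensus matrix;
that agreement is the reported stability. Only the assignment is
permuted, not the k selection. Clusters are labelled hot (highest
lymphoid + myeloid mean), suppressed (highest myeloid minus lymphoid
contrast), cold (lowest overall mean) and moderate, with ties broken by
cluster id and C1..Ck fallbacks off k = 4.

Differential expression contrasts one cluster against the rest with
log2 fold changes of pseudocount-shifted means and two-sided Wilcoxon
rank-sum p-values, BH-adjusted; the moderated-linear-model alternative
is a standard routine outside this package's re-specification scope,
and the significance thresholds (|logFC| > 1.5, q < 0.05) are
preserved. Pre-ranked GSEA uses the classic weighted running-sum
statistic with a gene-permutation null and same-sign NES normalisation
(via fgsea's simple permutation routine).

## Survival

Presence calls use exposure >= 15% (boundary inclusive); tertiles split
at the empirical order statistics with `ceiling(n/3)` observations in
the lower and `floor(n/3)` in the upper group, ties going to the lower
group — exposure distributions have mass at zero, so tie handling is
stated explicitly. Kaplan-Meier curves and the log-rank test are
implemented directly (full hypergeometric covariance; equal to
`survival::survdiff` at unit weights, which the tests assert to 1e-6)
because the weighted variant — every subject's at-risk and event
contributions multiplied by its inverse-probability weight — is not
available in the standard routine. IPW propensities come from the
stage x treatment cross-tabulation (exact for categorical covariates; a
stratum missing a group gets +0.5 smoothing on all its cells), with
weights normalised to mean 1 within groups. The binomial enrichment
test, BH adjustment and Pearson correlation wrap the standard exact
routines.

## The synthetic cohort

The default cohort is 60 samples on a 22 x 100 Mb toy genome (GRCh37
lengths load from a bundled table when realistic coordinates are
wanted; desk-scale lengths keep the full pipeline in minutes).
Trinucleotide frequencies are Dirichlet(5) per chromosome — mildly
non-uniform without pathological zeros. Each sample draws: signature
exposures from a flat Dirichlet over four synthetic reference
signatures (the first APOBEC-like with mass on TpCpW C>T/C>G); 2,000
background SNVs plus Poisson(3) planted APOBEC kataegis clusters of
8-12 mutations with inter-mutation gaps <= 2 kb (matching the
detector's locus definition so sensitivity is well defined), 40% of
them on the hotspot chromosome (chr8 by default), each hotspot locus
accompanied by a small deletion so kataegis and breakpoints genuinely
co-localise; 200 SVs from a mixture of three reference rearrangement
signatures, with 40% of samples additionally planted as complex
genomes — clustered breakpoints in a 1 Mb window of the oscillating
chromosome (chr18 by default) whose copy-number profile alternates
between two states; segment profiles built to hit the target ploidy
exactly (mixing floor and floor+1 states) with a sub-clonal block of
known size flagged at q < 0.05; expression for 2,000 genes with four
planted immune archetypes (separation 3, noise 0.5 on the log scale)
over 18 disjoint marker sets named after the ConsensusTME cell types;
and exponential survival with per-archetype hazards (0.02, 0.08, 0.04,
0.05 per month), exponential censoring at rate 0.01 truncated at 120
months.

What the generator does *not* emulate: real sequence context (no FASTA;
contexts travel in the VCF `TNC` tag), mutation-rate covariates along
the genome, correlated signature activity, subclonal phylogenies,
realistic SV mechanisms, batch effects or dropout in expression, and
non-proportional hazards. Passing recovery tests therefore demonstrate
that the implementations compute their definitions correctly and are
calibrated under clean null models — not that the defaults are tuned
for any particular real cohort.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally (VCF and BEDPE convert at
the boundary); all boundary comparisons in the rules above are strict
or inclusive exactly as stated, and every threshold lives in
`pipeline_config()`. Zero-mutation samples get zero exposure rows
flagged rather than NaNs; all-censored data yields a flat survival
curve; a single-chromosome genome can never be co-localization
enriched (its frequency equals the mean). The sum-to-one constraint in
the QP refit uses penalty weight 1e4 with exact renormalisation, which
the grid oracle shows is ample. Problem sizes in the recovery suite
(50 samples x 5,000 SNVs for refit accuracy, 100 seeded replicates for
kataegis and subtype selection, 1,000 null simulations for log-rank
calibration) were chosen to make the Monte-Carlo bounds sharp at desk
scale.

## Known limitations

Exposure uncertainty is not quantified (no bootstrap); NMF k is a
configuration value with a stability report rather than an automatic
selection rule; the exact scores of the upstream kataegis tool are not
reproduced; HRDetect probabilities must be supplied externally; and the
multivariate Cox adjustment is deliberately left to the standard
survival routines rather than re-specified here.
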