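# somaticTME

Tumour genomic and immune-microenvironment feature analysis for
whole-genome-sequenced cancer cohorts, with a fully specified synthetic
cohort generator for validation.

Cancer WGS + RNA studies characterise each tumour by a common set of
derived features: which mutational processes were active, whether
localized hypermutation (kataegis) co-occurs with structural
rearrangement, how unstable and sub-clonal the copy-number landscape
is, whether the genome shows homologous recombination deficiency (HRD)
or chromothripsis-like complex events, which immune microenvironment
subtype the tumour expresses, and how all of these stratify survival.
The patient data behind such studies is usually access-restricted, so
this package pairs every analysis module with a generator that plants
known truth and a recovery suite that checks the module finds it.

## What it computes

* **SNV signatures** — 96-context catalogues; NMF extraction
  (Frobenius, multiplicative updates, multi-restart); cosine matching
  to a reference set; exposure refitting by constrained quadratic
  programming, `min ||m/||m||₁ − Sᵀe||²` s.t. `e ≥ 0, Σe = 1`; and the
  overfitting guard that iteratively drops exposures < 10% and
  reassigns their mutations.
* **Rearrangement signatures** — clustered-breakpoint flagging
  (≥ 10 breakends in a 1 Mb bin), the 32-class type × size × clustered
  scheme, NMF extraction and "-like" naming below cosine 0.80.
* **Kataegis** — sliding-window exact binomial tests against the
  chromosome-wide rate, BH over all windows, locus calling at ≥ 6
  mutations with mean inter-mutation distance ≤ 2 kb, APOBEC scoring
  at TpCpW (TCA/TCT) C>T/C>G.
* **Co-localization** — cohort-pooled 1 Mb bins flagged when kataegis
  and breakpoint counts both exceed their genome-wide means;
  per-chromosome frequencies, enrichment against the mean frequency,
  and the combined-percent ranking (sample frequency × bin frequency).
* **Copy number & HRD** — ploidy, percent genome altered, CNA
  categories (0 / 1 / ≥ 6), ploidy-corrected amplification
  (< 2.7 & ≥ 6, or ≥ 2.7 & ≥ 9), sub-clonal CNA percentages at
  FDR < 0.05, and the LOH + tAI + LST HRD-sum with the > 42 / > 0.7
  HRD call.
* **Complex events** — interleaved SV clusters, copy-number
  oscillations, chromosomal enrichment, exponential-spacing and
  fragment-joins tests; criteria "interleaved > 10, oscillations > 6,
  q < 0.05 / < 0.05 / < 0.2" or "interleaved > 30 with exponential
  q < 0.05".
* **Immune subtyping** — ssGSEA-style single-sample enrichment for 18
  cell types, consensus k-means with 3-of-4 k-selection (elbow,
  silhouette, gap, Calinski-Harabasz) and 1000-run stability,
  hot/suppressed/moderate/cold labels, neutrophil/T-cell ratio,
  Wilcoxon differential expression (|logFC| > 1.5, q < 0.05) and
  pre-ranked GSEA.
* **Survival** — presence (≥ 15%) and tertile stratification,
  Kaplan-Meier, (IPW-weighted) log-rank, BH adjustment, exact binomial
  enrichment, Pearson correlation.

## Worked example

```r
library(somaticTME)

co  <- simulate_cohort(n_samples = 24,
                       genome = generate_genome(8, 5e7, seed = 7),
                       seed = 7, n_mut = 800, n_sv = 100)
res <- run_cohort_pipeline(co, seed = 7,
                           config = pipeline_config(nmf_restarts = 10,
                                                    consensus_n_perm = 200,
                                                    consensus_k_range = 2:6))

round(head(res$snv_exposures, 4), 3)
#>            RefSig1 RefSig2 RefSig3 RefSig4
#> Sample_001   0.183   0.817   0.000   0.000
#> Sample_002   0.122   0.574   0.304   0.000
#> Sample_003   0.000   0.272   0.181   0.547
#> Sample_004   0.288   0.182   0.531   0.000
```

Pruned exposure proportions per reference signature: Sample_001 is an
80/20 mixture of signatures 2 and 1 (RefSig1 is the APOBEC-like
profile); entries below 10% were dropped and their mutations
reassigned.

```r
head(res$kataegis_loci[, c("sample_id", "chrom", "start", "end",
                           "n_mut", "apobec_score", "class")], 2)
#>    sample_id chrom    start      end n_mut apobec_score  class
#> 1 Sample_001  chr3 14414390 14425799    11            1 APOBEC
#> 2 Sample_001  chr8 11683655 11692691    10            1 APOBEC
```

Each locus is a merged run of significant windows: 10-11 mutations in
~10 kb, all at TpCpW C>T/C>G contexts (APOBEC score 1).

```r
head(res$colocalization[order(res$colocalization$rank),
     c("chrom", "kataegis_freq", "coloc_freq", "combined_percent",
       "rank", "enriched")], 3)
#>   chrom kataegis_freq coloc_freq combined_percent rank enriched
#> 8  chr8      70.83333         16       11.3333333    1     TRUE
#> 1  chr1      25.00000          6        1.5000000    2     TRUE
#> 3  chr3      41.66667          2        0.8333333    3    FALSE
```

chr8 — the generator's kataegis/SV hotspot — ranks first: 70.8% of
samples carry an APOBEC locus there and 16% of its 1 Mb bins hold both
kataegis and breakpoint excess, giving combined percent 11.3.

```r
res$survival
#>           comparison  statistic           p           q
#> 1     immune_cluster 13.6689198 0.003392267 0.007724104
#> 2 immune_cluster_ipw 13.3915287 0.003862052 0.007724104
#> 3    apobec_presence  0.6078758 0.435588721 0.435588721
#> 4         rs_tertile  3.9550576 0.046730718 0.062307624

unlist(res$recovery)
#>           exposure_mae   kataegis_sensitivity       ploidy_max_error
#>             0.01838738             1.00000000             0.00500000
#>    subclonal_max_error           hotspot_rank               immune_k
#>             0.00000000             1.00000000             4.00000000
#>             immune_ari complex_flag_agreement
#>             1.00000000             1.00000000
```

The immune clusters separate survival (log-rank p = 0.0034; IPW-adjusted
p = 0.0039), and the recovery block confirms the planted truth was
found: exposure mean absolute error 0.018, every planted kataegis
cluster detected, the hotspot chromosome ranked first, k = 4 immune
clusters recovered with adjusted Rand index 1, and every planted
complex genome flagged.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/somatic-tme.R simulate --out cohort --seed 1
Rscript inst/cli/somatic-tme.R run-all --in cohort --out results --seed 1
```

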