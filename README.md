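# chromalink

Integrative epigeno-proteomics for patient-matched cancer cohorts: linking
chromatin accessibility (ATAC-seq peaks) to RNA and protein abundance
across disease states, and testing whether element accessibility predicts
protein levels beyond RNA.

## Who this is for

Analysts with matched multi-omic tumor cohorts (e.g. normal / primary /
metastasis, or molecular subtypes) who want to move past per-layer
differential lists and ask *which regulatory elements drive coordinated
RNA-and-protein changes*. The package also ships a fully synthetic
multi-omics cohort generator with planted ground truth, so the entire
pipeline is testable — and demonstrable — without access to patient data.

## What it computes

- **Peak set construction**: summits extended ±100 bp to 200 bp peaks,
  unioned into a disjoint cohort peak set.
- **Per-layer normalization**: log₂-CPM (prior count 5) + quantile
  normalization + replicate averaging for peak counts; log-CPM transform
  for RNA; gene-body accessibility RPKM; peptide→protein rollup as log₂
  sample/reference-channel ratios with missing-value fill and per-channel
  rescaling.
- **Differential features**: Welch tests for all pairwise state
  comparisons, BH-controlled at FDR 1% (peaks) / 10% (RNA, protein, gene
  accessibility).
- **Peak–gene linkage**: for each gene and state, Pearson correlation of
  cis-peak accessibility (±250 kb of the first TSS) with RNA, tested
  against a per-gene Gaussian null built from 10,000 random trans-peak
  correlations; links at BH FDR 0.05, annotated with promoter/non-promoter
  class, distance, gene-body/distal location and exon/intron position:

  p = 1 − Φ((r − μ_null) / σ_null)

- **Cross-omic summaries**: sample-wise paired correlations
  (element–RNA Pearson, protein–RNA Spearman; "high paired" = both > 0.5),
  gene-wise fold-change correlation/concordance, differential non-promoter
  activity scores, exact-binomial exonic enrichment.
- **Protein predictive significance**: patients split at random into two
  halves; half A categorizes linked gene–element pairs by differential
  flags (a: neither, b: gene only, c: element only, d: both); half B fits
  `protein ~ RNA + RNA×Accessibility` per pair and tests the interaction
  with a partial F on (1, n−3) df; categories are compared on their
  FDR-significant counts with a two-sided Fisher exact test. A no-split
  "modified" variant serves small cohorts.
- **Footprints & networks**: differential TF-footprint set logic (bound in
  one state, unbound in the other), the gene-body vs distal Fisher test,
  and permutation enrichment of protein–protein interaction subnetworks
  (1000 uniform gene-set draws, Gaussian z-score p plus empirical p).

## Worked example

```r
library(chromalink)

cfg <- simulation_config(seed = 1)   # 18 patients x Normal/Tumor/Met
bundle <- simulate_cohort(cfg)       # annotation, counts, peptides, truth
res <- run_cohort_analysis(bundle, seed = 1)

nrow(res$links)        # significant peak-gene links
res$paired_summary     # high-paired fractions by element class
res$gene_wise          # fold-change Spearman + concordance
res$predictive         # protein predictive significance (d vs a)
res$network            # PPI permutation enrichment
```

Output on this configuration:

```
Multi-omics cohort: 54 samples (3 states), 1246 peaks, 500 genes, 116100 peptide rows
significant links: 977 of 23976 tested pairs
    peak_class         category   n n_high fraction_high
1     promoter not_differential 105      2        0.0190
2 non_promoter not_differential 318     13        0.0409
3     promoter     differential  21     17        0.8095
4 non_promoter     differential  71     48        0.6761
gene-wise Spearman: 0.848  concordance: 100 %
protein predictive significance (d vs a): p = 1.71e-06
Network permutation (uniform null, 1000 perms): E_obs = 65, null 37.23 +/- 6.07, z = 4.57, p = 2.4e-06 (empirical 0.000999)
```

Reading it: of 23,976 tested cis pairs, 977 link at FDR 0.05 and recover
planted regulatory couplings. Differential elements are strongly enriched
for high paired correlations (68–81% vs 2–4% background) — the synthetic
analogue of the coordination observed in real cohorts. Category-d pairs
(both gene and element differential) carry planted
accessibility-beyond-RNA effects, and the Fisher comparison against
category a detects them (p ≈ 2×10⁻⁶); the planted interaction module is
likewise detected by the network permutation (z ≈ 4.6).

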