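---
title: "Methods: linking chromatin accessibility to RNA and protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking chromatin accessibility to RNA and protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In patient-matched cancer cohorts profiled at three layers — chromatin
accessibility (ATAC-seq peaks), RNA abundance and protein abundance
(isobaric-label shotgun proteomics) — protein and RNA levels are only
moderately correlated gene-by-gene, yet genes whose expression changes
between disease states (normal tissue, primary tumor, metastasis, or
molecular subtypes) tend to show much tighter coordination across all three
layers. `chromalink` implements the analysis chain needed to quantify this:
which accessible elements regulate which genes, which gene–element pairs are
differential, and whether element accessibility adds predictive value for
protein abundance beyond what RNA already explains.

## Data model and normalization

All genomic coordinates are 0-based half-open (BED convention); conversion
to 1-based closed happens only at the boundary of GenomicRanges calls.

* **Peaks.** Insertion-density summits are extended by 100 bp per side to
  200 bp intervals (shorter at chromosome edges) and unioned across the
  cohort into a disjoint peak set (`extend_summits()`,
  `merge_peak_regions()`). Peak counts are normalized by log2-CPM with a
  library-scaled prior count of 5, quantile normalization across all
  replicate columns, and a log2 average over technical replicates
  (`normalize_atac()`). The log-CPM value for count $c$ in a column with
  library size $L_j$ and scaled prior $p_j = 5 L_j/\bar L$ is
  $\log_2\!\big((c+p_j)/(L_j+2p_j)\times 10^6\big)$.
* **RNA.** Raw counts are transformed with the same log-CPM (prior 5)
  (`transform_rna()`). A variance-stabilizing count transform would serve
  equally: the downstream statistics depend only on approximate linearity
  of the transformed values, and monotone re-expressions leave the Spearman
  summaries unchanged.
* **Gene accessibility.** ATAC reads over the gene body (promoter-peak bp
  excluded upstream of this package) divided by gene length in kb and
  library size in millions (RPKM), then quantile normalized
  (`gene_body_rpkm()`). The denominator uses the full gene-body length; a
  `quantile = FALSE` switch exposes raw RPKM.
* **Protein.** Peptide-level intensities per run are processed as: missing
  values set to the run minimum (the most literal reading of a "minimum
  value in that run": the global minimum across that run's peptides and
  channels); each channel rescaled so its total matches the reference
  channel total; per gene, peptide intensities summed in sample and
  reference channels and the ratio taken (weighting toward intense
  peptides); log2; technical replicates averaged (`rollup_protein()`).
  Replicate averaging happens after the log transform. A gene undetected in
  a run is missing (NA) for that run's samples, never zero.

## Differential testing

Pairwise state comparisons (later vs earlier state) use a Welch t-test per
feature on the normalized log-scale values, BH-adjusted within each layer ×
comparison (`call_differential()`). FDR thresholds follow the assay
character: 1% for peak accessibility (union peak sets are noisy), 10% for
RNA, protein and gene accessibility. A gene is "differentially expressed"
when significant in any comparison at the RNA or protein layer. The Welch
test stands in for moderated count/intensity models; every downstream
module consumes only (logFC, q, flag), so the substitution is contained.
Pairwise comparisons are used rather than an omnibus ANOVA, and the tests
are unpaired by default — on a patient-matched cohort the patient random
effect makes unpaired tests conservative, which costs some power but never
inflates the FDR (a paired mode can be emulated by differencing matched
columns upstream).

## Peak–gene linkage

For each gene, candidate cis peaks overlap a 500 kb window (250 kb each
side of the first TSS). Within each state, the Pearson correlation of each
candidate peak's accessibility with the gene's transformed RNA is compared
against a per-gene, per-state null: the correlations of the gene's RNA with
10,000 random trans peaks (peaks on other chromosomes), fitted as a
Gaussian (mean, n−1 sd). Because the null is built per gene and state, it
absorbs gene-specific expression quirks (heavy tails widen the null). The
one-sided upper-tail p, $1-\Phi((r-\mu)/\sigma)$, targets activating
elements; a two-sided option exists. BH is applied within state across all
tested pairs, links called at q < 0.05, and the union over states reported
with per-state provenance (`link_peaks_to_genes()`). On toy genomes with
fewer than 10,000 eligible trans peaks the null samples with replacement;
the sampling pool is sorted first so results are invariant to peak input
order. Constant peaks and degenerate (σ = 0) nulls are skipped.

Links are annotated with: promoter vs non-promoter class (strand-aware
−1000/+100 window around the first TSS, by interval overlap; summit mode is
an option — the window is only meaningful in transcription orientation, so
it is mirrored on the − strand and clamped at chromosome edges), unsigned
distance to the gene body with a containment flag, and an exonic /
intronic / outside label assigned by summit position (a peak can straddle a
junction; the summit gives a single-label partition for the binomial
count).

## Cross-omic summaries

* **Sample-wise**: per linked pair, Pearson(accessibility, RNA) and
  Spearman(protein, RNA) across matched samples; "high paired" means both
  exceed 0.5 (strict). `classify_paired()` reports the high-paired fraction
  in differential vs non-differential elements, per element class.
* **Gene-wise**: Spearman correlation of RNA vs protein log fold changes
  over gene × comparison records significant at both layers, plus the
  fraction of sign-concordant records (zero fold change counts as
  non-concordant).
* **NP activity score**: per gene and comparison, the sum of log2 fold
  changes of its differential non-promoter peaks; additive over disjoint
  peak sets, zero when empty.
* **Exonic enrichment**: upper-tail exact binomial test of the exonic count
  among exonic+intronic NP elements against the expected exonic fraction,
  which defaults to the mean per-gene exonic length fraction computed from
  the annotation (a pooled-bp mode is provided; the two differ whenever
  long and short genes have different exon density, so both are exposed and
  neither is hard-coded).

## Protein predictive significance

The core statistic. Patients are randomly halved (samples of one patient
never straddle the split; patient-matched tissues are not exchangeable, so
splitting is at patient level with a sample-level option). Set A furnishes
the differential flags that place each linked gene–element pair into one of
four categories — (a) neither differential, (b) gene expression only, (c)
element only, (d) both. Set B fits, per pair,

$$\text{protein} = \beta_0 + \beta_1\,\text{RNA} +
\beta_2\,(\text{RNA}\times\text{Accessibility})$$

with no accessibility main effect, exactly as the model is specified, and
tests the added interaction term against the RNA-only reduced model with a
partial F on (1, n−3) df — for a single added term this F equals the
squared t of $\beta_2$, and the overall-regression F variant is exposed as
an alternative reading. P-values are BH-adjusted within the union of the
compared categories (where the adjustment scope was ambiguous, the union
was chosen; it is the scope that makes the two categories' counts
comparable), pairs at q < 0.05 counted per category, and the two categories
compared with a two-sided Fisher exact test — the protein predictive
significance p-value. Degenerate fits (constant accessibility → collinear
interaction; perfect fits) are flagged, not silently dropped. The modified
variant for small cohorts skips the split and compares two classes,
differentially active (differential at both RNA and protein and linked to a
differential footprint within the gene body) vs not.

## Footprints and networks

Differential footprint sites are those with an explicit bound call in one
state and an explicit unbound call in the other (absence of a call is not
evidence of unbound). The location test contrasts footprinted vs background
non-promoter links on gene-body vs distal position (two-sided Fisher).
Network enrichment of a gene set counts edges of its induced subgraph in a
deduplicated undirected interaction network, then permutes: 1000 uniform
draws of equal-size gene sets from the network-overlapped proteome, a
Gaussian fitted to the permuted counts, and the one-sided upper-tail p from
the observed z-score. The Gaussian approximation can be poor for small
sets, so the empirical-quantile p is always reported alongside; a
degree-preserving rewiring null is available (`mode = "rewire"`), with the
uniform node-draw null as the default operationalization of "permuting the
database".

## The synthetic cohort

The generator (`simulation_config()`, `simulate_cohort()`) emulates the
study conditions: 18 patients × {Normal, Tumor, Met} = 54 matched samples
(the subset profiled on all three platforms in such cohorts), ~500 genes on
a 4 × 10 Mb toy genome, ~2.5 peaks per gene.

Coupling is induced by a per-gene, per-sample latent activity
$\ell_{gi}$ (30% of its variance a patient random effect). RNA log2 signal
is the latent itself; the gene's planted linked peak loads on it with
`rho_acc_rna` (0.8; the promoter peak with 0.5 — constitutive regulation,
which also populates the "neither differential" category), and protein
loads with `rho_rna_prot` = 0.25 at baseline — chosen so the cohort-wide
median protein–RNA correlation lands near the ~0.2–0.3 reported for human
tissue — or `rho_coordinated` = 0.8 for coordinated genes. Coordinated
genes additionally load protein on the linked peak's
accessibility-specific residual (`gamma_acc_prot` = 0.4): accessibility
then genuinely predicts protein beyond RNA, which is the phenomenon the
predictive-significance test exists to detect, planted as ground truth.

20% of genes are differential (log2 shift 1.5 in Tumor+Met for 70% of
them, Met-only for the rest, random sign): coordinated genes (half) shift
all three layers plus their element; the remainder split into
expression-only (RNA+protein) and element-only (peak and gene-body
accessibility) classes, populating categories b and c. Counts are negative
binomial around the exponentiated signals with dispersion 0.02 — technical
over-dispersion only, since biological variation enters through the latent;
the accessibility layer uses a 0.7 log2 biological scale (narrower dynamic
range than expression) and mean peak counts near $2^7$. Peptides (~4 per
gene, log-normal, 0.3 log2 measurement noise, 5% missing at random) are
grouped into runs of 9 sample channels plus a reference channel.
Footprint calls are emitted as bound/unbound flags per state — inside the
linked peak where it overlaps the gene body, since footprints are only
detectable within accessible peaks — never derived from reads. The
interaction network plants a dense module (size 10, density 0.8) among
coordinated genes over an Erdős–Rényi background (p = 0.01).

What the generator does **not** emulate: read-level data, motif sequence
content, isotope/charge structure in MS, batch effects beyond run/reference
structure, copy-number or isoform complexity, and any dependence of the
protein–RNA coupling on state (the per-state knob exists in principle but
the default is state-invariant coupling, consistent with reports that
tissue type does not move this correlation). Passing tests therefore
demonstrate that the machinery is correct and calibrated under a fair
generative model — not that real cohorts satisfy that model.

## Numerical choices and degenerate inputs

* Quantile normalization maps ties to the mean of their tied reference
  quantiles — deterministic and order-independent; the "identical sorted
  columns" property is exact only for tie-free columns.
* BH excludes NA p-values from the test count and is stable under input
  permutation.
* Zero variance in both groups of a Welch test yields p = 1 on equal means.
* Distances are intervening bp between half-open intervals: book-ended
  peak and gene have distance 0 but are not flagged as overlapping.
* Null-model sampling is seeded and sorted-pool based, so the entire
  pipeline is byte-identical across reruns of the same config + seed.
* Trans-null σ uses the n−1 sample standard deviation; σ = 0 nulls error.
* With fewer than 10,000 eligible trans peaks, sampling is with
  replacement, which reproduces the small pool's moments rather than
  inventing spread.

## Problem sizes used by the shipped checks

The test suite simulates cohorts of 60–500 genes and 8–18 patients; the
calibration and power checks (null link FDR, rho = 0.9 recovery,
interaction-test calibration, predictive-significance power) each run 20
seeded replicates at 500 genes × 54 samples, and
`scripts/acceptance.R` runs the full default configuration once per seed.
These sizes make every property measurable in minutes while keeping the
per-state sample size (18) equal to the matched-cohort scale the defaults
emulate; statistics that scale with cohort size (link counts, category
counts) are reported at this scale, not at the hundreds-of-thousands-of-
peaks scale of a real cohort.

## Known limitations

* The Welch stand-in lacks variance moderation; at n = 18 per state its
  power is below that of moderated models, so planted-effect recovery rates
  here are conservative relative to the published tooling.
* The Gaussian trans-peak null assumes approximate normality of null
  correlations; the suite checks Gaussian vs empirical tail agreement only
  in the p ∈ [0.01, 0.5] range.
* The interaction model has no accessibility main effect by design; with
  strictly positive RNA values the interaction term largely absorbs it, but
  centred data would change that reading.
* Unpaired differential tests on matched cohorts are conservative (see
  above); the FDR guarantees hold, sensitivity estimates are lower bounds.
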