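# End-to-end analysis: normalization of all layers, differential calls,
# linkage, cross-omic correlation summaries and the predictive-significance
# tests, on a cohort bundle.

#' Normalize all cohort layers
#'
#' ATAC peak counts: log-CPM (prior 5) -> quantile normalization ->
#' log2-average of technical replicates.  RNA: log-CPM transform.
#' Gene-body accessibility: RPKM + quantile normalization.  Protein:
#' peptide-to-protein rollup of reference-channel ratios.
#'
#' @param cohort an `omics_cohort`.
#' @param annotation the matching `gene_annotation`.
#' @return list of matrices `atac`, `rna`, `gene_acc`, `protein`, all with
#'   biological-sample columns.
#' @export
normalize_cohort <- function(cohort, annotation) {
  atac <- normalize_atac(cohort$atac_counts,
                         cohort$atac_sheet$sample_id[
                           match(colnames(cohort$atac_counts),
                                 cohort$atac_sheet$column_id)])
  rna <- transform_rna(cohort$rna_counts)
  g <- annotation$genes[match(rownames(cohort$gene_acc_counts),
                              annotation$genes$gene_id), ]
  gene_acc <- gene_body_rpkm(cohort$gene_acc_counts, g$end - g$start)
  protein <- rollup_protein(cohort$peptides, cohort$design)
  list(atac = atac, rna = rna, gene_acc = gene_acc, protein = protein)
}

#' Run the full integrative analysis on a cohort bundle
#'
#' Normalizes every layer, calls pairwise differential features at the
#' layer thresholds, links peaks to genes against per-gene trans-peak
#' nulls, computes sample-wise paired correlations and their
#' classification, gene-wise fold-change correlation, NP activity scores,
#' differential footprint location tests, the split-sample protein
#' predictive significance and the PPI-network permutation for the
#' differentially active gene set.
#'
#' @param bundle output of [simulate_cohort()] (or an equivalent list with
#'   `annotation`, `cohort`, `footprints`, `edges`).
#' @param seed seed for the linkage null sampling, the sample split and
#'   the network permutation.
#' @param link_fdr link FDR (default 0.05).
#' @param n_null trans-null sample size (default 10000).
#' @param n_perm network permutations (default 1000).
#' @return list of results; see elements `norm`, `differential`, `flags`,
#'   `tested_pairs`, `links`, `paired`, `paired_summary`, `gene_wise`,
#'   `activity`, `predictive`, `footprint_test`, `network`.
#' @export
run_cohort_analysis <- function(bundle, seed = 1L, link_fdr = 0.05,
                                n_null = 10000L, n_perm = 1000L) {
  cohort <- bundle$cohort
  annotation <- bundle$annotation
  ss <- cohort$sample_sheet
  states <- cohort$states
  norm <- normalize_cohort(cohort, annotation)

  diff <- list(
    atac_peak = call_differential(norm$atac, ss, "atac_peak",
                                  states = states),
    rna = call_differential(norm$rna, ss, "rna", states = states),
    protein = call_differential(norm$protein, ss, "protein",
                                states = states),
    gene_accessibility = call_differential(norm$gene_acc, ss,
                                           "gene_accessibility",
                                           states = states)
  )
  flags <- list(
    gene = differential_gene_flags(diff$rna, diff$protein),
    rna = differential_flags(diff$rna),
    protein = differential_flags(diff$protein),
    element = differential_flags(diff$atac_peak),
    gene_acc = differential_flags(diff$gene_accessibility)
  )

  tested <- link_peaks_to_genes(norm$atac, norm$rna, cohort$peaks,
                                annotation, ss, n_null = n_null,
                                fdr = link_fdr, seed = seed)
  links <- significant_links(tested)

  paired <- sample_wise_correlations(norm$atac, norm$rna, norm$protein,
                                     links)
  paired_summary <- classify_paired(paired, flags$element)

  # gene-wise: gene x comparison records significant at both RNA & protein
  gw <- merge(diff$rna[diff$rna$significant,
                       c("feature_id", "comparison", "logFC")],
              diff$protein[diff$protein$significant,
                           c("feature_id", "comparison", "logFC")],
              by = c("feature_id", "comparison"),
              suffixes = c("_rna", "_protein"))
  gene_wise <- if (nrow(gw) >= 3)
    gene_wise_correlation(gw$logFC_rna, gw$logFC_protein) else NULL

  comparisons <- unique(diff$atac_peak$comparison)
  activity <- do.call(rbind, lapply(comparisons, function(cmp)
    np_activity_scores(links, diff$atac_peak, cmp)))

  # split-sample protein predictive significance on linked pairs
  split <- split_samples(ss, seed = seed)
  pairs <- unique(links[, c("gene_id", "peak_id")])
  names(pairs)[2] <- "element_id"
  rna_A <- call_differential(norm$rna[, split$set_A, drop = FALSE],
                             ss, "rna", states = states)
  prot_A <- call_differential(norm$protein[, split$set_A, drop = FALSE],
                              ss, "protein", states = states)
  atac_A <- call_differential(norm$atac[, split$set_A, drop = FALSE],
                              ss, "atac_peak", states = states)
  cat_pairs <- categorize_pairs(pairs,
                                differential_gene_flags(rna_A, prot_A),
                                differential_flags(atac_A))
  fits <- fit_interaction_models(cat_pairs, norm$protein, norm$rna,
                                 norm$atac, split$set_B)
  predictive <- tryCatch(
    protein_predictive_significance(fits, compare = c("d", "a")),
    error = function(e) structure(list(message = conditionMessage(e)),
                                  class = "try-error"))

  # footprints: union of differential sites over state pairs vs baseline
  fp <- bundle$footprints
  site_sets <- lapply(states[-1], function(st)
    differential_footprint_sites(fp, st, states[1]))
  diff_sites <- unique(do.call(rbind, site_sets))
  np_links <- links[links$peak_class == "non_promoter", ]
  footprint_test <- tryCatch(
    footprint_location_test(np_links, cohort$peaks, diff_sites),
    error = function(e) structure(list(message = conditionMessage(e)),
                                  class = "try-error"))

  active <- names(flags$gene)[!is.na(flags$gene) & flags$gene]
  network <- if (length(active) >= 2 && nrow(bundle$edges) > 0) {
    bg <- intersect(rownames(norm$protein),
                    unique(c(bundle$edges$from, bundle$edges$to)))
    if (length(intersect(active, bg)) >= 2 && length(bg) > length(active)) {
      permuted_network_pvalue(intersect(active, bg), bundle$edges, bg,
                              n_perm = n_perm, seed = seed)
    } else NULL
  } else NULL

  list(norm = norm, differential = diff, flags = flags,
       tested_pairs = tested, links = links, paired = paired,
       paired_summary = paired_summary, gene_wise = gene_wise,
       gene_wise_records = gw, activity = activity, split = split,
       fits = fits, predictive = predictive,
       diff_sites = diff_sites, footprint_test = footprint_test,
       network = network)
}

#' Write the analysis result tables as TSV
#'
#' Deterministic plain-text outputs: tested pairs/links, differential
#' records per layer, paired correlations with their category summary,
#' activity scores and interaction fits.
#'
#' @param results output of [run_cohort_analysis()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis_tsv <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(
    format(df, digits = 10, trim = TRUE, scientific = TRUE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(results$tested_pairs, "tested_pairs.tsv")
  wt(results$links, "links.tsv")
  for (layer in names(results$differential))
    wt(results$differential[[layer]],
       sprintf("differential_%s.tsv", layer))
  wt(results$paired, "paired_correlations.tsv")
  wt(results$paired_summary, "paired_summary.tsv")
  wt(results$activity, "np_activity_scores.tsv")
  wt(results$fits, "interaction_fits.tsv")
  invisible(dir)
}
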