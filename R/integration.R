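# Cross-omic correlation summaries: sample-wise paired correlations,
# gene-wise fold-change correlation/concordance, the differential NP
# activity score, and exon/intron enrichment.

#' Sample-wise paired correlations for linked element-gene pairs
#'
#' For each unique (element, gene) pair in `links`: the Pearson correlation
#' of element accessibility with transformed RNA and the Spearman
#' correlation of protein with RNA, across shared samples.  Pairs with
#' fewer than `min_samples` complete observations or constant vectors are
#' skipped with a warning.
#'
#' @param acc_mat normalized element accessibility (elements x samples).
#' @param rna_mat transformed RNA (genes x samples).
#' @param prot_mat protein log-ratios (genes x samples); NAs allowed.
#' @param links data.frame with columns `peak_id`, `gene_id` (extra
#'   columns such as `peak_class` are carried through).
#' @param min_samples minimum shared samples (default 6).
#' @return data.frame with `element_id`, `gene_id`, `r_elem_rna`,
#'   `r_prot_rna`, `high_paired` plus carried columns.
#' @export
sample_wise_correlations <- function(acc_mat, rna_mat, prot_mat, links,
                                     min_samples = 6L) {
  pairs <- unique(links[, intersect(c("peak_id", "gene_id", "peak_class",
                                      "location", "exon_intron", "distance"),
                                    names(links))])
  samples <- intersect(colnames(acc_mat), colnames(rna_mat))
  samples <- intersect(samples, colnames(prot_mat))
  n_skipped <- 0L
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    el <- pairs$peak_id[i]; g <- pairs$gene_id[i]
    if (!el %in% rownames(acc_mat) || !g %in% rownames(rna_mat) ||
        !g %in% rownames(prot_mat)) return(NULL)
    a <- acc_mat[el, samples]; r <- rna_mat[g, samples]
    p <- prot_mat[g, samples]
    ok_ar <- !is.na(a) & !is.na(r)
    ok_pr <- !is.na(p) & !is.na(r)
    if (sum(ok_ar) < min_samples || sum(ok_pr) < min_samples ||
        sd(a[ok_ar]) == 0 || sd(r[ok_ar]) == 0 ||
        sd(p[ok_pr]) == 0 || sd(r[ok_pr]) == 0) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    cbind(pairs[i, , drop = FALSE],
          r_elem_rna = cor(a[ok_ar], r[ok_ar]),
          r_prot_rna = cor(p[ok_pr], r[ok_pr], method = "spearman"))
  })
  if (n_skipped > 0)
    .warnf("%d pair(s) skipped (too few shared samples or constant values)",
           n_skipped)
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("no pairs with enough shared samples")
  names(out)[names(out) == "peak_id"] <- "element_id"
  out$high_paired <- pmin(out$r_elem_rna, out$r_prot_rna) > 0.5
  rownames(out) <- NULL
  out
}

#' Fractions of high paired correlation by differential category
#'
#' Splits pairs into differential vs not-differential by the element's
#' differential flag and reports the fraction of high-paired pairs
#' (both correlations > 0.5) per category, separately for promoter and
#' non-promoter element classes when available.
#'
#' @param pairs output of [sample_wise_correlations()].
#' @param element_flags named logical vector: element id -> differential.
#' @return data.frame with `peak_class`, `category`, `n`, `n_high`,
#'   `fraction_high` (NA and flagged when a category is empty).
#' @export
classify_paired <- function(pairs, element_flags) {
  if (!"high_paired" %in% names(pairs))
    pairs$high_paired <- pmin(pairs$r_elem_rna, pairs$r_prot_rna) > 0.5
  category <- ifelse(
    !is.na(element_flags[pairs$element_id]) & element_flags[pairs$element_id],
    "differential", "not_differential")
  cls <- if ("peak_class" %in% names(pairs)) pairs$peak_class else "all"
  grid <- expand.grid(peak_class = unique(cls),
                      category = c("not_differential", "differential"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- cls == grid$peak_class[i] & category == grid$category[i]
    n <- sum(sel)
    data.frame(peak_class = grid$peak_class[i], category = grid$category[i],
               n = n, n_high = sum(pairs$high_paired[sel]),
               fraction_high = if (n > 0) mean(pairs$high_paired[sel])
                               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n == 0))
    .warnf("empty category: fraction undefined for %d cell(s)",
           sum(out$n == 0))
  out
}

#' Gene-wise fold-change correlation and concordance
#'
#' Spearman correlation of RNA vs protein log fold changes over gene x
#' comparison records, plus the fraction of records whose fold changes
#' agree in sign (a zero fold change counts as non-concordant).
#'
#' @param rna_logFC,protein_logFC aligned numeric vectors (>= 3 records).
#' @return list with `spearman_rho`, `concordance`, `n`.
#' @export
gene_wise_correlation <- function(rna_logFC, protein_logFC) {
  ok <- !is.na(rna_logFC) & !is.na(protein_logFC)
  if (sum(ok) < 3) .stopf("gene_wise_correlation needs >= 3 records")
  list(
    spearman_rho = cor(rna_logFC[ok], protein_logFC[ok], method = "spearman"),
    concordance = mean(rna_logFC[ok] * protein_logFC[ok] > 0),
    n = sum(ok)
  )
}

#' Differential NP activity scores
#'
#' Per gene and comparison, the sum of log2 fold changes of the gene's
#' linked differential non-promoter peaks in that comparison.  Genes with
#' no contributing peak score 0 with `n_peaks = 0`.
#'
#' @param links link table (significant links) with `peak_id`, `gene_id`,
#'   `peak_class`.
#' @param atac_records output of [call_differential()] for the peak layer.
#' @param comparison single comparison label (e.g. `"Tumor_vs_Normal"`).
#' @param gene_ids genes to score; defaults to genes present in `links`.
#' @return data.frame with `gene_id`, `comparison`, `score`, `n_peaks`.
#' @export
np_activity_scores <- function(links, atac_records, comparison,
                               gene_ids = NULL) {
  rec <- atac_records[atac_records$comparison == comparison &
                        atac_records$significant, ]
  np <- unique(links[links$peak_class == "non_promoter",
                     c("peak_id", "gene_id")])
  np <- np[np$peak_id %in% rec$feature_id, ]
  np$logFC <- rec$logFC[match(np$peak_id, rec$feature_id)]
  if (is.null(gene_ids)) gene_ids <- unique(links$gene_id)
  score <- setNames(rep(0, length(gene_ids)), gene_ids)
  n_pk <- setNames(rep(0L, length(gene_ids)), gene_ids)
  if (nrow(np) > 0) {
    s <- tapply(np$logFC, np$gene_id, sum)
    n <- tapply(np$logFC, np$gene_id, length)
    keep <- intersect(names(s), gene_ids)
    score[keep] <- s[keep]
    n_pk[keep] <- n[keep]
  }
  data.frame(gene_id = gene_ids, comparison = comparison,
             score = unname(score), n_peaks = unname(n_pk),
             stringsAsFactors = FALSE)
}

#' Exonic enrichment of NP elements (exact binomial test)
#'
#' Upper-tail exact binomial test of the observed exonic count against the
#' expected exonic fraction (by default the mean exonic length fraction of
#' the analyzed gene bodies):
#' \eqn{p = P(X \ge k), X \sim Bin(n_{exonic}+n_{intronic}, p_0)}.
#'
#' @param n_exonic,n_intronic counts of exonic and intronic NP elements.
#' @param expected_fraction expected exonic proportion in (0, 1).
#' @return list with `p`, `k`, `n`, `expected_fraction`.
#' @export
exonic_enrichment_test <- function(n_exonic, n_intronic, expected_fraction) {
  n <- n_exonic + n_intronic
  if (n == 0) .stopf("no exonic or intronic elements to test")
  if (expected_fraction <= 0 || expected_fraction >= 1)
    .stopf("expected_fraction must be in (0, 1)")
  p <- binom.test(n_exonic, n, p = expected_fraction,
                  alternative = "greater")$p.value
  list(p = p, k = n_exonic, n = n, expected_fraction = expected_fraction)
}

#' Mean exonic length fraction of gene bodies
#'
#' Pooled over the given genes: the mean of per-gene exonic bp divided by
#' gene-body length.  Used as the expected fraction in
#' [exonic_enrichment_test()]; `mode = "pooled_bp"` instead returns total
#' exonic bp over total gene-body bp.
#'
#' @param annotation a `gene_annotation`.
#' @param gene_ids subset of genes (default all).
#' @param mode `"mean_per_gene"` (default) or `"pooled_bp"`.
#' @return a proportion.
#' @export
mean_exonic_fraction <- function(annotation, gene_ids = NULL,
                                 mode = c("mean_per_gene", "pooled_bp")) {
  mode <- match.arg(mode)
  g <- annotation$genes
  if (!is.null(gene_ids)) g <- g[g$gene_id %in% gene_ids, ]
  len <- g$end - g$start
  if (mode == "mean_per_gene") mean(g$exonic_bp / len)
  else sum(g$exonic_bp) / sum(len)
}
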