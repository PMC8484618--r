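# Protein predictive significance: split-sample categorization of
# gene-element pairs, interaction linear-model partial F-tests, and the
# Fisher comparison of FDR-significant fits between categories; plus the
# no-split modified variant.

#' Split samples into two random sets at the patient level
#'
#' Patients are randomly halved (all of a patient's samples stay together,
#' since matched tissues are not exchangeable); set sizes differ by at most
#' one patient.  `unit = "sample"` splits at the sample level instead.
#'
#' @param sample_sheet data.frame with `sample_id`, `patient`.
#' @param seed integer seed.
#' @param unit `"patient"` (default) or `"sample"`.
#' @return list with `set_A`, `set_B` (sample id vectors).
#' @export
split_samples <- function(sample_sheet, seed = 1L,
                          unit = c("patient", "sample")) {
  unit <- match.arg(unit)
  set.seed(seed)
  if (unit == "sample") {
    ids <- sample(sample_sheet$sample_id)
    nA <- floor(length(ids) / 2)
    return(list(set_A = sort(ids[seq_len(nA)]), set_B = sort(ids[-seq_len(nA)])))
  }
  patients <- unique(sample_sheet$patient)
  if (length(patients) < 2) .stopf("need >= 2 patients to split")
  shuffled <- sample(patients)
  nA <- floor(length(patients) / 2)
  pa <- shuffled[seq_len(nA)]
  list(
    set_A = sort(sample_sheet$sample_id[sample_sheet$patient %in% pa]),
    set_B = sort(sample_sheet$sample_id[!sample_sheet$patient %in% pa])
  )
}

#' Categorize gene-element pairs by differential flags
#'
#' Four-way partition: (a) neither gene expression nor element
#' differential, (b) gene expression only, (c) element only, (d) both.
#' Pairs with a missing flag are excluded with a warning.
#'
#' @param pairs data.frame with `gene_id`, `element_id`.
#' @param gene_flags named logical: gene id -> differentially expressed.
#' @param element_flags named logical: element id -> differential.
#' @return `pairs` with a `category` column (letters a-d).
#' @export
categorize_pairs <- function(pairs, gene_flags, element_flags) {
  gf <- gene_flags[pairs$gene_id]
  ef <- element_flags[pairs$element_id]
  ok <- !is.na(gf) & !is.na(ef)
  if (any(!ok))
    .warnf("%d pair(s) excluded: missing differential flag", sum(!ok))
  pairs <- pairs[ok, , drop = FALSE]
  gf <- gf[ok]; ef <- ef[ok]
  pairs$category <- ifelse(gf & ef, "d",
                    ifelse(gf & !ef, "b",
                    ifelse(!gf & ef, "c", "a")))
  rownames(pairs) <- NULL
  pairs
}

#' Partial F-test for the RNA x accessibility interaction
#'
#' Fits `protein ~ rna + rna:accessibility` (no accessibility main effect)
#' and tests the added interaction term against the RNA-only reduced model:
#' \eqn{F = (RSS_{red} - RSS_{full}) / (RSS_{full} / (n - 3))} on
#' (1, n-3) df.  For this single added term F equals the squared t of the
#' interaction coefficient.
#'
#' @param protein,rna,accessibility aligned per-sample numeric vectors
#'   (rows with any NA dropped; n >= 5 required).
#' @return list with `F`, `p`, `df1`, `df2`, `t`, `n`, `perfect_fit`.
#' @export
interaction_f_test <- function(protein, rna, accessibility) {
  ok <- complete.cases(protein, rna, accessibility)
  protein <- protein[ok]; rna <- rna[ok]; accessibility <- accessibility[ok]
  n <- length(protein)
  if (n < 5) .stopf("interaction_f_test needs >= 5 complete samples")
  inter <- rna * accessibility
  X_full <- cbind(1, rna, inter)
  if (qr(X_full)$rank < 3)
    .stopf("interaction term collinear with RNA (constant accessibility?)")
  full <- lm(protein ~ rna + inter)
  red <- lm(protein ~ rna)
  rss_full <- sum(residuals(full)^2)
  rss_red <- sum(residuals(red)^2)
  df2 <- n - 3
  perfect <- rss_full < .Machine$double.eps * sum(protein^2)
  if (perfect) {
    Fstat <- Inf
    p <- .Machine$double.xmin
  } else {
    Fstat <- (rss_red - rss_full) / (rss_full / df2)
    p <- pf(Fstat, 1, df2, lower.tail = FALSE)
  }
  list(F = Fstat, p = p, df1 = 1L, df2 = df2,
       t = sign(coef(full)[["inter"]]) * sqrt(Fstat), n = n,
       perfect_fit = perfect)
}

#' Fit interaction models for a table of gene-element pairs
#'
#' Runs [interaction_f_test()] per pair over the given sample columns,
#' returning NA for pairs that cannot be fitted (too few complete samples
#' or collinear interaction), and BH-adjusts within the tested set.
#'
#' @param pairs data.frame with `gene_id`, `element_id` (and optionally
#'   `category`).
#' @param prot_mat,rna_mat gene x sample matrices.
#' @param acc_mat element x sample matrix.
#' @param samples sample ids to use (e.g. split set B).
#' @param fdr significance threshold on BH-adjusted p (default 0.05).
#' @return `pairs` with added `F`, `p`, `q`, `significant`.
#' @export
fit_interaction_models <- function(pairs, prot_mat, rna_mat, acc_mat,
                                   samples, fdr = 0.05) {
  samples <- intersect(samples, colnames(prot_mat))
  res <- vapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene_id[i]; el <- pairs$element_id[i]
    if (!g %in% rownames(prot_mat) || !g %in% rownames(rna_mat) ||
        !el %in% rownames(acc_mat)) return(c(NA_real_, NA_real_))
    fit <- tryCatch(
      interaction_f_test(prot_mat[g, samples], rna_mat[g, samples],
                         acc_mat[el, samples]),
      error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    c(fit$F, fit$p)
  }, numeric(2))
  pairs$F <- res[1, ]
  pairs$p <- res[2, ]
  pairs$q <- bh_adjust(pairs$p)
  pairs$significant <- !is.na(pairs$q) & pairs$q < fdr
  pairs
}

#' Protein predictive significance between two categories
#'
#' BH-adjusts the interaction-test p-values within the union of the two
#' compared categories, counts significant vs not per category, and
#' compares the two proportions with a two-sided Fisher exact test -- the
#' protein predictive significance p-value.
#'
#' @param fits output of [fit_interaction_models()] with a `category`
#'   column (raw `p` is re-adjusted within the compared union).
#' @param compare two category labels (default d vs a).
#' @param fdr FDR threshold for the significant count (default 0.05).
#' @return list with `contingency` (2x2 matrix), `fisher_p`, `odds_ratio`,
#'   `compare`, `fdr`.
#' @export
protein_predictive_significance <- function(fits, compare = c("d", "a"),
                                            fdr = 0.05) {
  stopifnot(length(compare) == 2)
  sub <- fits[fits$category %in% compare & !is.na(fits$p), ]
  n_per <- table(factor(sub$category, levels = compare))
  if (any(n_per == 0))
    .stopf("category '%s' has no testable pairs",
           compare[which(n_per == 0)[1]])
  q <- bh_adjust(sub$p)
  sig <- q < fdr
  tab <- rbind(
    significant = tapply(sig, factor(sub$category, levels = compare), sum),
    not_significant = tapply(!sig, factor(sub$category, levels = compare), sum)
  )
  ft <- fisher.test(tab)
  list(contingency = tab, fisher_p = ft$p.value,
       odds_ratio = unname(ft$estimate), compare = compare, fdr = fdr)
}

#' Modified protein predictive significance (no sample split)
#'
#' Two-class variant for small cohorts: pairs are classed as differentially
#' active or not (differentially active = differential at both RNA and
#' protein and linked to a differential footprint within the gene body);
#' categorization and fitting both use the full cohort.  The Fisher
#' comparison is of FDR-significant interaction fits between the two
#' classes.
#'
#' @param fits output of [fit_interaction_models()] over the full cohort.
#' @param active named logical or logical vector aligned with `fits` rows:
#'   differentially active.
#' @param fdr FDR threshold (default 0.05).
#' @return as [protein_predictive_significance()].
#' @export
modified_predictive_significance <- function(fits, active, fdr = 0.05) {
  if (!is.null(names(active))) active <- active[fits$gene_id]
  fits$category <- ifelse(active, "active", "not_active")
  if (length(unique(fits$category[!is.na(fits$p)])) < 2)
    .stopf("all pairs fall in one class; comparison undefined")
  protein_predictive_significance(fits, compare = c("active", "not_active"),
                                  fdr = fdr)
}

#' Differentially active genes for the modified test
#'
#' Genes significant at both the RNA and protein layers in some pairwise
#' comparison AND carrying a differential footprint site within the gene
#' body.
#'
#' @param rna_flags,protein_flags named logical vectors per gene.
#' @param diff_sites differential footprint sites (data.frame with `chrom`,
#'   `start`, `end`), e.g. from [differential_footprint_sites()].
#' @param annotation a `gene_annotation`.
#' @return named logical vector over the union of flagged genes.
#' @export
differentially_active_genes <- function(rna_flags, protein_flags,
                                        diff_sites, annotation) {
  genes <- union(names(rna_flags), names(protein_flags))
  both <- setNames(
    !is.na(rna_flags[genes]) & rna_flags[genes] &
      !is.na(protein_flags[genes]) & protein_flags[genes],
    genes)
  g <- annotation$genes[match(genes, annotation$genes$gene_id), ]
  has_fp <- rep(FALSE, length(genes))
  ok <- !is.na(g$gene_id)
  if (nrow(diff_sites) > 0 && any(ok)) {
    gr_sites <- .bed_to_gr(diff_sites)
    gr_genes <- .bed_to_gr(g[ok, c("chrom", "start", "end")])
    ov <- GenomicRanges::findOverlaps(gr_sites, gr_genes, type = "within")
    has_fp[which(ok)[unique(S4Vectors::subjectHits(ov))]] <- TRUE
  }
  setNames(both & has_fp, genes)
}
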