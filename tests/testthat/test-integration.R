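# Cross-omic correlation summaries, activity scores and the exonic
# enrichment test.

make_pair_matrices <- function(acc, rna, prot, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_along(rna))
  list(
    acc = matrix(acc, 1, dimnames = list("e1", samples)),
    rna = matrix(rna, 1, dimnames = list("g1", samples)),
    prot = matrix(prot, 1, dimnames = list("g1", samples)),
    links = data.frame(peak_id = "e1", gene_id = "g1")
  )
}

test_that("sample-wise correlations match hand Pearson/Spearman values", {
  # Spearman of [1,2,3,4] vs [1,3,2,4]: 1 - 6*2/(4*15) = 0.8
  m <- make_pair_matrices(acc = 2 * c(1, 2, 3, 4) + 1,
                          rna = c(1, 2, 3, 4), prot = c(1, 3, 2, 4))
  out <- sample_wise_correlations(m$acc, m$rna, m$prot, m$links,
                                  min_samples = 4)
  expect_equal(out$r_elem_rna, 1)        # affine invariance of Pearson
  expect_equal(out$r_prot_rna, 0.8)
  # monotone transform of protein leaves Spearman at 1
  m2 <- make_pair_matrices(acc = rnorm(8), rna = 1:8, prot = exp(1:8 / 2))
  out2 <- sample_wise_correlations(m2$acc, m2$rna, m2$prot, m2$links)
  expect_equal(out2$r_prot_rna, 1)
})

test_that("spearman is invariant under strictly monotone maps", {
  set.seed(13)
  for (i in 1:5) {
    rna <- rnorm(12)
    prot <- rnorm(12)
    m1 <- make_pair_matrices(rnorm(12), rna, prot)
    base <- sample_wise_correlations(m1$acc, m1$rna, m1$prot, m1$links)
    m2 <- make_pair_matrices(m1$acc[1, ], rna, exp(2 * prot) + 5)
    mapped <- sample_wise_correlations(m2$acc, m2$rna, m2$prot, m2$links)
    expect_equal(mapped$r_prot_rna, base$r_prot_rna, tolerance = 1e-12)
  }
})

test_that("pairs with too few shared samples are skipped with a warning", {
  m <- make_pair_matrices(rnorm(4), rnorm(4), rnorm(4))
  expect_error(
    expect_warning(
      sample_wise_correlations(m$acc, m$rna, m$prot, m$links),
      "skipped"),
    "no pairs")
})

test_that("paired-correlation classification uses a strict 0.5 threshold", {
  pairs <- data.frame(
    element_id = c("e1", "e2", "e3"),
    gene_id = c("g1", "g2", "g3"),
    peak_class = "non_promoter",
    r_elem_rna = c(0.6, 0.5, 0.8),
    r_prot_rna = c(0.7, 0.9, 0.2))
  flags <- c(e1 = TRUE, e2 = TRUE, e3 = FALSE)
  out <- classify_paired(pairs, flags)
  diff_row <- out[out$category == "differential", ]
  bg_row <- out[out$category == "not_differential", ]
  # (0.6, 0.7) is high-paired; (0.5, 0.9) is not (strict inequality)
  expect_equal(diff_row$n_high, 1)
  expect_equal(diff_row$fraction_high, 0.5)
  expect_equal(bg_row$n_high, 0)
  expect_true(all(out$fraction_high >= 0 & out$fraction_high <= 1,
                  na.rm = TRUE))
  # empty category is flagged
  expect_warning(
    classify_paired(pairs[1:2, ], flags),
    "empty category")
})

test_that("coordinated differential genes enrich for high paired correlations", {
  b <- cached_bundle()
  norm <- cached_norm()
  links <- data.frame(
    peak_id = unname(b$truth$linked_peak[!is.na(b$truth$linked_peak)]),
    gene_id = names(b$truth$linked_peak)[!is.na(b$truth$linked_peak)])
  links$peak_class <- "non_promoter"
  pairs <- suppressWarnings(
    sample_wise_correlations(norm$atac, norm$rna, norm$protein, links))
  truth_diff <- setNames(
    pairs$gene_id %in% b$truth$coordinated_genes, pairs$element_id)
  out <- classify_paired(pairs, truth_diff)
  fr <- setNames(out$fraction_high, out$category)
  expect_gt(fr[["differential"]], fr[["not_differential"]])
})

test_that("gene-wise correlation and concordance behave on fixed inputs", {
  res <- gene_wise_correlation(c(1, -1, 2), c(0.5, -0.2, 1))
  expect_equal(res$spearman_rho, 1)
  expect_equal(res$concordance, 1)
  anti <- gene_wise_correlation(c(1, -1, 2), -c(1, -1, 2))
  expect_equal(anti$spearman_rho, -1)
  expect_equal(anti$concordance, 0)
  # zero fold change counts as non-concordant
  z <- gene_wise_correlation(c(1, 0, 2), c(1, 1, 2))
  expect_equal(z$concordance, 2 / 3)
  expect_error(gene_wise_correlation(c(1, 2), c(1, 2)), ">= 3")
})

test_that("NP activity scores sum differential non-promoter logFCs", {
  links <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                      gene_id = c("g1", "g1", "g1", "g2"),
                      peak_class = c("non_promoter", "non_promoter",
                                     "non_promoter", "non_promoter"))
  rec <- data.frame(feature_id = c("p1", "p2", "p3", "p4"),
                    comparison = "T_vs_N",
                    logFC = c(0.5, 1.2, -0.3, 2),
                    significant = c(TRUE, TRUE, TRUE, FALSE))
  out <- np_activity_scores(links, rec, "T_vs_N")
  expect_equal(out$score[out$gene_id == "g1"], 1.4)
  expect_equal(out$n_peaks[out$gene_id == "g1"], 3)
  # g2's only peak is not differential: score 0 with n_peaks 0
  expect_equal(out$score[out$gene_id == "g2"], 0)
  expect_equal(out$n_peaks[out$gene_id == "g2"], 0)
  # additivity over disjoint peak sets
  out_a <- np_activity_scores(links[1:2, ], rec, "T_vs_N", gene_ids = "g1")
  out_b <- np_activity_scores(links[3, , drop = FALSE], rec, "T_vs_N",
                              gene_ids = "g1")
  expect_equal(out_a$score + out_b$score,
               out$score[out$gene_id == "g1"])
})

test_that("exact binomial enrichment matches tail summation and Monte Carlo", {
  # k = n: (1/2)^3
  expect_equal(exonic_enrichment_test(3, 0, 0.5)$p, 0.125)
  # at the mode, the upper tail is >= 0.5
  expect_gte(exonic_enrichment_test(round(20 * 0.3), 20 - round(20 * 0.3),
                                    0.3)$p, 0.5)
  # term-by-term summation oracle on the cohort-scale worked counts
  k <- 126; n <- 748; p0 <- 0.11
  oracle <- sum(exp(lchoose(n, k:n) + (k:n) * log(p0) +
                      (n - k:n) * log(1 - p0)))
  expect_equal(exonic_enrichment_test(k, n - k, p0)$p, oracle,
               tolerance = 1e-10)
  # Monte-Carlo agreement within 3 SE on a small case
  set.seed(14)
  k2 <- 5; n2 <- 12; p02 <- 0.25
  p_exact <- exonic_enrichment_test(k2, n2 - k2, p02)$p
  draws <- rbinom(1e6, n2, p02)
  p_mc <- mean(draws >= k2)
  se <- sqrt(p_exact * (1 - p_exact) / 1e6)
  expect_lt(abs(p_exact - p_mc), 3 * se)
  expect_error(exonic_enrichment_test(0, 0, 0.5), "no exonic")
  expect_error(exonic_enrichment_test(1, 1, 1), "in \\(0, 1\\)")
})

test_that("mean exonic fraction reflects the annotation", {
  ann <- toy_annotation()
  # gA: 2000/10000, gB: 10000/10000
  expect_equal(mean_exonic_fraction(ann), mean(c(0.2, 1)))
  expect_equal(mean_exonic_fraction(ann, "gA"), 0.2)
  expect_equal(mean_exonic_fraction(ann, mode = "pooled_bp"),
               12000 / 20000)
})
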