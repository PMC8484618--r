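# Synthetic cohort generator: config validation, annotation geometry,
# determinism, planted couplings, footprints and the interaction network.

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(frac_linked_genes = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(rho_acc_rna = 1), "\\(-1, 1\\)")
  expect_error(simulation_config(states = c("A", "A")), "2 distinct states")
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(rho_coordinated = 0.9,
                                 gamma_acc_prot = 0.6), "must be < 1")
  expect_s3_class(simulation_config(), "sim_config")
})

test_that("annotation geometry is valid and deterministic", {
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  g <- ann$genes
  expect_equal(nrow(g), cfg$n_genes)
  expect_true(all(g$start >= 0 & g$end <= ann$chrom_sizes[g$chrom]))
  expect_setequal(unique(g$strand), c("+", "-"))
  expect_true(all(ifelse(g$strand == "+", g$tss == g$start,
                         g$tss == g$end - 1)))
  # non-overlap within chromosome
  for (ch in unique(g$chrom)) {
    sub <- g[g$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  # exons: within body, sorted, non-overlapping, >= 1 per gene
  ex <- ann$exons
  expect_true(all(ex$gene_id %in% g$gene_id))
  expect_setequal(unique(ex$gene_id), g$gene_id)
  for (gi in sample(g$gene_id, 10)) {
    e <- ex[ex$gene_id == gi, ]
    gg <- g[g$gene_id == gi, ]
    expect_true(all(e$start >= gg$start & e$end <= gg$end))
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
  expect_identical(simulate_annotation(cfg), ann)
})

test_that("annotation capacity errors when genes cannot fit", {
  cfg <- small_config()
  cfg$chromosome_length <- 5e4
  expect_error(simulate_annotation(cfg), "capacity")
})

test_that("the full bundle is reproducible from config + seed", {
  cfg <- small_config(seed = 77)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$cohort$atac_counts, b2$cohort$atac_counts)
  expect_identical(b1$cohort$rna_counts, b2$cohort$rna_counts)
  expect_identical(b1$cohort$peptides, b2$cohort$peptides)
  expect_identical(b1$truth$linked_pairs, b2$truth$linked_pairs)
  expect_identical(b1$footprints, b2$footprints)
  expect_identical(b1$edges, b2$edges)
})

test_that("uncoupled protein is uncorrelated with RNA; planted links correlate", {
  # rho_rna_prot = 0: per-gene protein-RNA correlation centred at 0
  cfg0 <- simulation_config(seed = 55, rho_rna_prot = 0,
                            rho_coordinated = 0, gamma_acc_prot = 0,
                            frac_differential_genes = 0)
  b0 <- simulate_cohort(cfg0)
  norm0 <- normalize_cohort(b0$cohort, b0$annotation)
  shared <- intersect(colnames(norm0$rna), colnames(norm0$protein))
  cors <- vapply(rownames(norm0$rna), function(g)
    suppressWarnings(cor(norm0$rna[g, shared], norm0$protein[g, shared],
                         use = "pairwise")), numeric(1))
  expect_lt(abs(median(cors, na.rm = TRUE)), 0.1)

  # planted links: accessibility-RNA correlation far above background
  cfg1 <- simulation_config(seed = 56, n_genes = 100, n_chromosomes = 3,
                            chromosome_length = 4e6, rho_acc_rna = 0.9)
  b1 <- simulate_cohort(cfg1)
  norm1 <- normalize_cohort(b1$cohort, b1$annotation)
  lp <- b1$truth$linked_pairs
  lp <- unique(lp[, c("peak_id", "gene_id")])
  r_planted <- vapply(seq_len(nrow(lp)), function(i)
    cor(norm1$atac[lp$peak_id[i], ], norm1$rna[lp$gene_id[i], ]),
    numeric(1))
  set.seed(1)
  bg_peaks <- sample(setdiff(rownames(norm1$atac), lp$peak_id), 50)
  bg_genes <- sample(rownames(norm1$rna), 50)
  r_bg <- vapply(1:50, function(i)
    cor(norm1$atac[bg_peaks[i], ], norm1$rna[bg_genes[i], ]), numeric(1))
  expect_gt(mean(r_planted), mean(r_bg) + 0.4)
  # configured coupling recovered within 0.1 at n = 54
  expect_lt(abs(mean(r_planted) - 0.9), 0.1)
})

test_that("footprint placement follows the planted truth", {
  cfg <- small_config(seed = 57, footprint_prob = 1)
  b <- simulate_cohort(cfg)
  fp <- b$footprints
  genes <- b$annotation$genes
  # every coordinated gene has >= 1 differential gene-body footprint in
  # some against-baseline contrast (a gene may shift only in the last state)
  diff_sites <- unique(rbind(
    differential_footprint_sites(fp, cfg$states[2], cfg$states[1]),
    differential_footprint_sites(fp, cfg$states[3], cfg$states[1])))
  for (g in b$truth$coordinated_genes) {
    gg <- genes[genes$gene_id == g, ]
    inside <- diff_sites$chrom == gg$chrom & diff_sites$start >= gg$start &
      diff_sites$end <= gg$end
    expect_true(any(inside))
  }
  # probability 0 and no background: no sites at all
  cfg0 <- small_config(seed = 57, footprint_prob = 0,
                       n_background_footprints = 0)
  ann0 <- simulate_annotation(cfg0)
  mo0 <- simulate_multiomics(cfg0, ann0)
  fp0 <- simulate_footprints(cfg0, ann0, mo0$truth, mo0$cohort$peaks)
  expect_equal(nrow(fp0), 0)
})

test_that("interaction network honours module density and is simple", {
  cfg <- small_config(seed = 58, module_size = 5, module_density = 1,
                      background_edge_prob = 0)
  b <- simulate_cohort(cfg)
  e <- b$edges
  expect_equal(nrow(e), 10)  # complete graph on 5 nodes
  expect_true(all(e$from %in% b$truth$planted_module))
  expect_true(all(e$to %in% b$truth$planted_module))
  expect_true(all(e$from != e$to))
  expect_equal(nrow(unique(e)), nrow(e))
  # with background edges: still simple and deduplicated
  b2 <- cached_bundle()
  e2 <- b2$edges
  key <- paste(pmin(e2$from, e2$to), pmax(e2$from, e2$to))
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(e2$from != e2$to))
})

test_that("planted truth is internally consistent", {
  b <- cached_bundle()
  tr <- b$truth
  expect_true(all(tr$coordinated_genes %in%
                    tr$differential_genes$gene_id))
  expect_true(all(tr$linked_pairs$peak_id %in% b$cohort$peaks$peak_id))
  expect_true(all(tr$planted_module %in% tr$gene_ids))
})

test_that("the cohort bundle round-trips through plain-text files", {
  b <- cached_bundle()
  dir <- withr::local_tempdir()
  write_cohort_bundle(b, dir)
  pk <- read_peaks_bed(file.path(dir, "peaks.bed"))
  expect_equal(pk, b$cohort$peaks[, names(pk)])
  ann <- read_genes_bed12(file.path(dir, "genes.bed12"),
                          b$annotation$chrom_sizes)
  expect_equal(ann$genes[, c("gene_id", "chrom", "start", "end", "strand",
                             "tss")],
               b$annotation$genes[, c("gene_id", "chrom", "start", "end",
                                      "strand", "tss")])
  expect_equal(ann$exons, b$annotation$exons, ignore_attr = TRUE)
  m <- read_matrix_tsv(file.path(dir, "rna_counts.tsv"))
  expect_equal(m, b$cohort$rna_counts)
  fp <- read_footprints_bed(file.path(dir, "footprints.bed"))
  expect_equal(fp, b$footprints[, names(fp)])
})
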