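# Normalization chains: log-CPM, quantile normalization, replicate
# averaging, gene-body RPKM and peptide-to-protein rollup.

test_that("log-CPM matches hand evaluation of the prior-count formula", {
  m <- matrix(c(0, 995, 1e6 - 995), ncol = 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  out <- log_cpm(m)
  # single column: scaled prior = 5, denominator 1e6 + 10
  expect_equal(out["a", 1], log2(5 / 1000010 * 1e6), tolerance = 1e-12)
  expect_equal(out["a", 1], 2.3219, tolerance = 1e-4)
  expect_equal(out["b", 1], log2(1000 / 1000010 * 1e6), tolerance = 1e-12)
  expect_equal(out["b", 1], 9.966, tolerance = 1e-3)
  expect_error(log_cpm(matrix(0, 2, 1)), "zero library size")
})

test_that("log-CPM agrees with the edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  m <- matrix(rnbinom(600, mu = 50, size = 2), nrow = 100)
  expect_equal(unname(log_cpm(m)), unname(edgeR::cpm(m, log = TRUE,
                                                     prior.count = 5)),
               tolerance = 1e-10)
})

test_that("log-CPM is strictly monotone in counts within a column", {
  set.seed(5)
  m <- matrix(sample.int(1000, 50), ncol = 1)
  out <- log_cpm(m)
  expect_identical(order(out), order(m))
  expect_equal(length(unique(out)), length(unique(m[, 1])))
})

test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 3, 2, 4), ncol = 2)
  out <- quantile_normalize(m)
  expect_equal(out, matrix(c(1.5, 3.5, 1.5, 3.5), ncol = 2))

  same <- matrix(rep(c(5, 1, 3), 3), ncol = 3)
  expect_equal(quantile_normalize(same), same)

  set.seed(6)
  r <- matrix(rnorm(200), ncol = 4)
  q <- quantile_normalize(r)
  expect_equal(apply(q, 2, sort), replicate(4, sort(q[, 1])),
               ignore_attr = TRUE)
  expect_equal(colMeans(q), rep(mean(q[, 1]), 4))
  # rank order preserved per column
  for (j in 1:4) expect_identical(order(q[, j]), order(r[, j]))
})

test_that("quantile normalization ties get the mean of tied reference quantiles", {
  m <- matrix(c(1, 1, 3,
                1, 2, 3), ncol = 2)
  out <- quantile_normalize(m)
  ref <- rowMeans(apply(m, 2, sort))  # 1, 1.5, 3
  expect_equal(out[, 2], ref)
  expect_equal(out[1:2, 1], rep(mean(ref[1:2]), 2))
  expect_equal(out[3, 1], ref[3])
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rnorm(300), ncol = 3)
  expect_equal(quantile_normalize(m), limma::normalizeQuantiles(m),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("replicate averaging is the arithmetic mean per biological sample", {
  m <- matrix(c(2, 4, 1, 2, 6), nrow = 1)
  expect_equal(as.numeric(average_replicates(m, c("a", "a", "b", "b", "b"))),
               c(3, 3))
  single <- matrix(1:3, ncol = 1)
  expect_equal(unname(average_replicates(single, "x")), single)
})

test_that("the full ATAC chain collapses duplicate replicates exactly", {
  set.seed(8)
  base <- matrix(rnbinom(120, mu = 40, size = 2), ncol = 3)
  dup <- base[, c(1, 1, 2, 2, 3, 3)]
  chain_dup <- normalize_atac(dup, c("a", "a", "b", "b", "c", "c"))
  chain_dedup <- normalize_atac(base, c("a", "b", "c"))
  expect_equal(chain_dup, chain_dedup, tolerance = 1e-12)
})

test_that("RNA transform is monotone and handles all-zero genes", {
  m <- matrix(c(0, 10, 100, 0, 20, 50), ncol = 2)
  out <- transform_rna(m)
  expect_true(all(diff(out[, 1]) > 0))
  # all-zero gene with equal library sizes: constant minimal value
  m2 <- rbind(c(0, 0), c(100, 100))
  out2 <- transform_rna(m2)
  expect_equal(out2[1, 1], out2[1, 2])
  expect_true(all(out2[1, ] < out2[2, ]))
})

test_that("gene-body RPKM matches hand arithmetic and scaling laws", {
  m <- matrix(c(100, 100), ncol = 1)
  r <- gene_body_rpkm(m, c(2000, 1000), library_sizes = 1e7,
                      quantile = FALSE)
  expect_equal(r[1, 1], 5)
  expect_equal(r[2, 1] / r[1, 1], 2)
  # doubling reads and library together leaves RPKM unchanged
  r2 <- gene_body_rpkm(2 * m, c(2000, 1000), library_sizes = 2e7,
                       quantile = FALSE)
  expect_equal(r2, r)
  expect_error(gene_body_rpkm(m, c(0, 1000)), "zero-length gene")
})

test_that("protein rollup computes reference-channel ratios per gene", {
  design <- data.frame(run_id = "r1", channel = c("s1", "ref"),
                       sample_id = c("A", NA), role = c("sample", "reference"))
  # totals balanced so no rescale: gene g1 ratio = 400/200 = 2
  pep <- data.frame(
    peptide_id = c("p1", "p2", "p3", "p1", "p2", "p3"),
    gene_id = c("g1", "g1", "g2", "g1", "g1", "g2"),
    run_id = "r1",
    channel = c("s1", "s1", "s1", "ref", "ref", "ref"),
    intensity = c(100, 300, 10, 50, 150, 210))
  out <- rollup_protein(pep, design)
  expect_equal(out["g1", "A"], 1)  # log2(2)
  expect_equal(out["g2", "A"], log2(10 / 210))
})

test_that("protein rollup rescales channels to the reference total", {
  design <- data.frame(run_id = "r1", channel = c("s1", "ref"),
                       sample_id = c("A", NA), role = c("sample", "reference"))
  pep <- data.frame(peptide_id = c("p1", "p2", "p1", "p2"),
                    gene_id = c("g1", "g2", "g1", "g2"),
                    run_id = "r1",
                    channel = c("s1", "s1", "ref", "ref"),
                    intensity = c(300, 200, 600, 400))
  # channel total 500 vs reference 1000: factor 2 on every sample peptide
  out <- rollup_protein(pep, design)
  expect_equal(out["g1", "A"], log2((300 * 2) / 600))
  expect_equal(out["g2", "A"], log2((200 * 2) / 400))
})

test_that("missing peptides are filled with the run minimum before summation", {
  design <- data.frame(run_id = "r1", channel = c("s1", "ref"),
                       sample_id = c("A", NA), role = c("sample", "reference"))
  pep <- data.frame(peptide_id = c("p1", "p2", "p1", "p2"),
                    gene_id = "g1", run_id = "r1",
                    channel = c("s1", "s1", "ref", "ref"),
                    intensity = c(NA, 90, 10, 100))
  # run minimum is 10; channel totals equal (100 and 110 -> rescale)
  out <- rollup_protein(pep, design)
  fac <- 110 / 100
  expect_equal(out["g1", "A"], log2((10 + 90) * fac / 110))
})

test_that("rollup is invariant to row order and to splitting a peptide", {
  design <- data.frame(run_id = "r1", channel = c("s1", "s2", "ref"),
                       sample_id = c("A", "B", NA),
                       role = c("sample", "sample", "reference"))
  set.seed(9)
  pep <- data.frame(
    peptide_id = rep(sprintf("p%d", 1:6), 3),
    gene_id = rep(rep(c("g1", "g2", "g3"), each = 2), 3),
    run_id = "r1",
    channel = rep(c("s1", "s2", "ref"), each = 6),
    intensity = runif(18, 50, 500))
  base <- rollup_protein(pep, design)
  shuffled <- rollup_protein(pep[sample.int(nrow(pep)), ], design)
  expect_equal(shuffled, base)
  # split p1/s1 into two rows with the same sum
  row1 <- which(pep$peptide_id == "p1" & pep$channel == "s1")
  extra <- pep[row1, ]
  extra$peptide_id <- "p1b"
  extra$gene_id <- "g1"
  extra$intensity <- pep$intensity[row1] * 0.4
  pep2 <- pep
  pep2$intensity[row1] <- pep$intensity[row1] * 0.6
  # note: also add the split rows to the other channels as missing-free?
  # splitting only affects the g1 sums it contributes to
  pep2 <- rbind(pep2, extra)
  split_out <- rollup_protein(pep2, design)
  expect_equal(split_out, base, tolerance = 1e-12)
})

test_that("genes absent from a run are NA, and technical replicates average", {
  design <- data.frame(
    run_id = c("r1", "r1", "r2", "r2"),
    channel = c("s1", "ref", "s1", "ref"),
    sample_id = c("A", NA, "A", NA),
    role = c("sample", "reference", "sample", "reference"))
  pep <- data.frame(
    peptide_id = c("p1", "p1", "p1", "p1", "p2", "p2"),
    gene_id = c("g1", "g1", "g1", "g1", "g2", "g2"),
    run_id = c("r1", "r1", "r2", "r2", "r2", "r2"),
    channel = c("s1", "ref", "s1", "ref", "s1", "ref"),
    intensity = c(200, 100, 400, 100, 50, 50))
  out <- rollup_protein(pep, design)
  # g1 measured in both runs: average of log2 ratios after rescale
  expect_false(is.na(out["g1", "A"]))
  # g2 only in run 2: value from run 2 alone, not zero
  expect_false(is.na(out["g2", "A"]))
  expect_error(rollup_protein(pep, design[design$role == "sample", ]),
               "no reference channel")
})
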