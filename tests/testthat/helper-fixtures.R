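# Shared fixtures: small configs and a cached default-size bundle so that
# expensive simulations run once per suite.

small_config <- function(seed = 42L, ...) {
  args <- list(seed = seed, n_patients = 8L, n_genes = 60L,
               n_chromosomes = 3L, chromosome_length = 2e6,
               n_background_footprints = 40L)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# enough samples/genes for power-dependent checks, still quick
medium_config <- function(seed = 42L, ...) {
  args <- list(seed = seed, n_patients = 15L, n_genes = 120L,
               n_chromosomes = 3L, chromosome_length = 4e6,
               n_background_footprints = 60L)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# cohort with no planted structure at all: no links, no couplings, no
# differential effects
null_config <- function(seed, n_genes = 500L, n_patients = 18L) {
  simulation_config(seed = seed, n_genes = n_genes, n_patients = n_patients,
                    frac_linked_genes = 0, frac_differential_genes = 0,
                    frac_coordinated = 0, rho_acc_rna = 0,
                    rho_promoter = 0, rho_rna_prot = 0,
                    rho_coordinated = 0, gamma_acc_prot = 0,
                    patient_var = 0)
}

.fixture_env <- new.env(parent = emptyenv())

cached_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- simulate_cohort(medium_config())
  .fixture_env$bundle
}

cached_norm <- function() {
  if (is.null(.fixture_env$norm)) {
    b <- cached_bundle()
    .fixture_env$norm <- normalize_cohort(b$cohort, b$annotation)
  }
  .fixture_env$norm
}

# hand-built two-gene annotation for geometry tests
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    start = c(20000L, 60000L), end = c(30000L, 70000L),
    strand = c("+", "-"),
    tss = c(20000L, 69999L),
    exonic_bp = c(2000L, 10000L),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1",
    start = c(20000L, 25000L, 60000L),
    end = c(21000L, 26000L, 70000L),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons,
                 chrom_sizes = c(chr1 = 100000L)),
            class = "gene_annotation")
}

# a vector with exact Pearson correlation r against x (Gram-Schmidt)
vector_with_cor <- function(x, r, noise) {
  xs <- (x - mean(x)) / sd(x)
  zs <- residuals(lm(noise ~ xs))
  zs <- zs / sd(zs)
  r * xs + sqrt(1 - r^2) * zs
}
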