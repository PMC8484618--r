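# Simulation configuration for the synthetic multi-omics cohort.

#' Configuration for the synthetic multi-omics cohort
#'
#' Defaults emulate a patient-matched three-state cancer cohort profiled
#' across all omic layers: 18 patients x 3 states = 54 matched samples, a
#' toy multi-chromosome genome, negative-binomial sequencing counts,
#' log-normal peptide intensities, and planted accessibility -> RNA ->
#' protein couplings.  Coupling is induced through a per-gene, per-sample
#' latent activity shared by the layers, so the configured correlations are
#' directly tunable; a patient random effect reflects the matched design.
#'
#' @param seed integer seed; identical config + seed reproduces the bundle.
#' @param n_patients patients; each contributes one sample per state.
#' @param states ordered state labels (>= 2).
#' @param n_genes number of genes on the toy genome.
#' @param n_chromosomes,chromosome_length genome geometry (bp).
#' @param peaks_per_gene mean number of accessible peaks per gene.
#' @param frac_linked_genes fraction of genes given a planted cis-linked
#'   peak whose accessibility tracks the gene's RNA.
#' @param frac_differential_genes fraction of genes with planted
#'   state-dependent differential effects.
#' @param frac_coordinated fraction of differential genes whose
#'   accessibility, RNA and protein effects co-vary (the rest split evenly
#'   into expression-only and element-only effects).
#' @param logfc_scale planted log2 fold change magnitude.
#' @param patient_var share of latent-activity variance attributable to a
#'   patient random effect shared across a patient's states (the cohort is
#'   patient-matched); 0 makes samples exchangeable.
#' @param rho_acc_rna target correlation of linked-peak accessibility with
#'   RNA (planted links).
#' @param rho_promoter coupling of a gene's promoter-peak accessibility
#'   with its RNA (promoter accessibility tracks expression more weakly
#'   than a dedicated enhancer).
#' @param rho_rna_prot baseline target protein-RNA correlation (all genes).
#' @param rho_coordinated elevated coupling (both layers) for coordinated
#'   differential genes.
#' @param gamma_acc_prot loading of protein on the linked peak's
#'   accessibility-specific component for coordinated genes; this plants a
#'   true "accessibility predicts protein beyond RNA" effect.
#' @param nb_dispersion negative-binomial dispersion of the count layers.
#'   This is measurement-level (technical) over-dispersion; biological
#'   sample-to-sample variation enters separately through the latent
#'   activity and state effects.
#' @param replicate_count ATAC technical replicates per sample.
#' @param frac_missing_peptides proportion of missing peptide measurements.
#' @param peptides_per_gene mean peptides per gene.
#' @param samples_per_run sample channels per proteomics run (plus one
#'   reference channel).
#' @param footprint_prob probability a coordinated gene receives a
#'   bound-in-tumor/unbound-in-normal footprint in its gene body.
#' @param n_background_footprints background footprint sites bound
#'   uniformly at random per state.
#' @param module_size,module_density planted dense module in the
#'   interaction network (genes drawn from coordinated genes).
#' @param background_edge_prob Erdos-Renyi probability of background
#'   interaction edges.
#' @return object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 18L,
                              states = c("Normal", "Tumor", "Met"),
                              n_genes = 500L,
                              n_chromosomes = 4L,
                              chromosome_length = 1e7,
                              peaks_per_gene = 2.5,
                              frac_linked_genes = 0.8,
                              frac_differential_genes = 0.2,
                              frac_coordinated = 0.5,
                              logfc_scale = 1.5,
                              patient_var = 0.3,
                              rho_acc_rna = 0.8,
                              rho_promoter = 0.5,
                              rho_rna_prot = 0.25,
                              rho_coordinated = 0.8,
                              gamma_acc_prot = 0.4,
                              nb_dispersion = 0.02,
                              replicate_count = 2L,
                              frac_missing_peptides = 0.05,
                              peptides_per_gene = 4,
                              samples_per_run = 9L,
                              footprint_prob = 0.9,
                              n_background_footprints = 200L,
                              module_size = 10L,
                              module_density = 0.8,
                              background_edge_prob = 0.01) {
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    states = as.character(states), n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length,
    peaks_per_gene = peaks_per_gene,
    frac_linked_genes = frac_linked_genes,
    frac_differential_genes = frac_differential_genes,
    frac_coordinated = frac_coordinated,
    logfc_scale = logfc_scale, patient_var = patient_var,
    rho_acc_rna = rho_acc_rna, rho_promoter = rho_promoter,
    rho_rna_prot = rho_rna_prot,
    rho_coordinated = rho_coordinated, gamma_acc_prot = gamma_acc_prot,
    nb_dispersion = nb_dispersion,
    replicate_count = as.integer(replicate_count),
    frac_missing_peptides = frac_missing_peptides,
    peptides_per_gene = peptides_per_gene,
    samples_per_run = as.integer(samples_per_run),
    footprint_prob = footprint_prob,
    n_background_footprints = as.integer(n_background_footprints),
    module_size = as.integer(module_size),
    module_density = module_density,
    background_edge_prob = background_edge_prob
  )
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
#' @noRd
validate_config <- function(cfg) {
  props <- c("frac_linked_genes", "frac_differential_genes",
             "frac_coordinated", "frac_missing_peptides", "footprint_prob",
             "module_density", "background_edge_prob")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      .stopf("config: %s must be in [0, 1]", p)
  counts <- c("n_patients", "n_genes", "n_chromosomes",
              "chromosome_length", "replicate_count", "samples_per_run")
  for (p in counts)
    if (cfg[[p]] <= 0) .stopf("config: %s must be positive", p)
  if (length(unique(cfg$states)) < 2)
    .stopf("config: need >= 2 distinct states")
  rhos <- c("rho_acc_rna", "rho_promoter", "rho_rna_prot",
            "rho_coordinated")
  for (p in rhos)
    if (abs(cfg[[p]]) >= 1) .stopf("config: %s must be in (-1, 1)", p)
  if (cfg$rho_coordinated^2 + cfg$gamma_acc_prot^2 >= 1)
    .stopf("config: rho_coordinated^2 + gamma_acc_prot^2 must be < 1")
  if (cfg$nb_dispersion <= 0) .stopf("config: nb_dispersion must be > 0")
  if (cfg$patient_var < 0 || cfg$patient_var >= 1)
    .stopf("config: patient_var must be in [0, 1)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients x %d states (%s); %d genes on %d x %.1f Mb\n",
              x$n_patients, length(x$states),
              paste(x$states, collapse = ", "),
              x$n_genes, x$n_chromosomes, x$chromosome_length / 1e6))
  cat(sprintf("  planted: %.0f%% linked (rho_acc_rna %.2f), %.0f%% differential (logFC %.1f), %.0f%% coordinated\n",
              100 * x$frac_linked_genes, x$rho_acc_rna,
              100 * x$frac_differential_genes, x$logfc_scale,
              100 * x$frac_coordinated))
  invisible(x)
}
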