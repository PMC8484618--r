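# Synthetic multi-omics cohort: negative-binomial ATAC and RNA counts,
# log-normal TMT-style peptide intensities, planted couplings and
# differential effects, with full ground truth.

#' Simulate the multi-omics cohort layers
#'
#' Generates raw ATAC peak counts (with technical replicates), gene-body
#' accessibility counts, RNA counts and a peptide-level intensity table
#' over a shared patient x state sample grid, plus the planted truth.
#'
#' The generative model: each gene has a per-sample latent activity
#' (patient random effect plus sample noise).  RNA log2-signal equals the
#' latent (scale 1); a planted linked peak loads on it with
#' `rho_acc_rna`; protein loads with `rho_rna_prot` (elevated to
#' `rho_coordinated` for coordinated genes, which additionally load on the
#' linked peak's accessibility-specific component with `gamma_acc_prot`,
#' planting a true accessibility-beyond-RNA effect).  Differential genes
#' shift layer means by `logfc_scale` in their shifted states: coordinated
#' genes at all layers, expression-only genes at RNA/protein, element-only
#' genes at the linked peak and gene-body accessibility.  Counts are
#' negative binomial around the exponentiated signals; peptide intensities
#' are log-normal around the gene-level protein signal with a reference
#' channel per run.
#'
#' @param config a [simulation_config()].
#' @param annotation output of [simulate_annotation()] for the same config.
#' @return list with elements `cohort` (class `omics_cohort`) and `truth`
#'   (class `planted_truth`).
#' @export
simulate_multiomics <- function(config, annotation) {
  validate_config(config)
  set.seed(config$seed + 1L)
  genes <- annotation$genes
  G <- nrow(genes)
  states <- config$states
  nS <- length(states)
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  sample_sheet <- data.frame(
    sample_id = paste(rep(patients, each = nS), rep(states, config$n_patients),
                      sep = "_"),
    patient = rep(patients, each = nS),
    state = rep(states, config$n_patients),
    stringsAsFactors = FALSE)
  S <- nrow(sample_sheet)

  ## ---- gene roles -------------------------------------------------------
  gene_ids <- genes$gene_id
  n_linked <- round(config$frac_linked_genes * G)
  linked_genes <- sort(sample(gene_ids, n_linked))
  n_diff <- round(config$frac_differential_genes * G)
  pool <- if (n_linked >= n_diff) linked_genes else gene_ids
  diff_genes <- sort(sample(pool, n_diff))
  n_coord <- round(config$frac_coordinated * n_diff)
  coordinated <- sort(sample(diff_genes, n_coord))
  rest <- setdiff(diff_genes, coordinated)
  expression_only <- rest[seq_len(floor(length(rest) / 2))]
  element_only <- setdiff(rest, expression_only)
  gene_class <- setNames(rep("background", G), gene_ids)
  gene_class[coordinated] <- "coordinated"
  gene_class[expression_only] <- "expression_only"
  gene_class[element_only] <- "element_only"

  ## ---- planted state effects -------------------------------------------
  # delta[g, s]: planted mean shift (log2) of gene g in state s.
  delta <- matrix(0, G, nS, dimnames = list(gene_ids, states))
  if (n_diff > 0) {
    sign <- sample(c(-1, 1), n_diff, replace = TRUE)
    prog <- runif(n_diff) < 0.7  # shifted in all non-baseline states
    for (i in seq_len(n_diff)) {
      shifted <- if (prog[i] || nS == 2) states[-1] else states[nS]
      delta[diff_genes[i], shifted] <- sign[i] * config$logfc_scale
    }
  }

  ## ---- latent activities -------------------------------------------------
  pat_idx <- match(sample_sheet$patient, patients)
  pv <- config$patient_var
  u <- matrix(rnorm(G * config$n_patients), G)
  latent <- sqrt(pv) * u[, pat_idx] + sqrt(1 - pv) * matrix(rnorm(G * S), G)
  state_idx <- match(sample_sheet$state, states)
  dimnames(latent) <- list(gene_ids, sample_sheet$sample_id)

  ## ---- peak set ----------------------------------------------------------
  total_peaks <- max(round(config$peaks_per_gene * G), n_linked)
  prom_genes <- gene_ids[runif(G) < 0.7]
  prom_pos <- genes$tss[match(prom_genes, gene_ids)] +
    sample(-50:50, length(prom_genes), replace = TRUE)
  link_pos <- integer(n_linked)
  if (n_linked > 0) {
    gi <- match(linked_genes, gene_ids)
    inside <- runif(n_linked) < 0.5
    link_pos <- ifelse(
      inside,
      genes$start[gi] + floor(runif(n_linked) * (genes$end[gi] - genes$start[gi])),
      genes$tss[gi] + sample(c(-1, 1), n_linked, TRUE) *
        floor(runif(n_linked, 5000, 50000)))
  }
  n_bg <- max(0L, total_peaks - length(prom_pos) - n_linked)
  bg_chrom <- sample(names(annotation$chrom_sizes), n_bg, replace = TRUE)
  bg_pos <- unname(floor(runif(n_bg) * annotation$chrom_sizes[bg_chrom]))
  summits <- data.frame(
    chrom = c(genes$chrom[match(prom_genes, gene_ids)],
              genes$chrom[match(linked_genes, gene_ids)],
              bg_chrom),
    pos = c(prom_pos, link_pos, bg_pos),
    stringsAsFactors = FALSE)
  summits$pos <- unname(pmin(pmax(summits$pos, 100L),
                             annotation$chrom_sizes[summits$chrom] - 101L))
  peaks <- merge_peak_regions(extend_summits(summits, annotation$chrom_sizes))
  K <- nrow(peaks)

  # map a summit to the merged peak containing it
  peak_at <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      hit <- which(peaks$chrom == chrom[i] & peaks$start <= pos[i] &
                     peaks$end > pos[i])
      peaks$peak_id[hit[1]]
    }, character(1))
  }
  linked_peak <- setNames(rep(NA_character_, G), gene_ids)
  if (n_linked > 0) {
    linked_peak[linked_genes] <- peak_at(
      genes$chrom[match(linked_genes, gene_ids)],
      summits$pos[length(prom_pos) + seq_len(n_linked)])
  }
  promoter_peak <- setNames(rep(NA_character_, G), gene_ids)
  if (length(prom_genes) > 0) {
    promoter_peak[prom_genes] <- peak_at(
      genes$chrom[match(prom_genes, gene_ids)],
      summits$pos[seq_along(prom_genes)])
  }

  ## ---- peak accessibility signals ----------------------------------------
  # accessibility has a narrower biological dynamic range than expression
  tau_atac <- 0.7
  mu_pk <- rnorm(K, 7, 1)
  pk_signal <- mu_pk + tau_atac * matrix(rnorm(K * S), K)  # background noise
  rownames(pk_signal) <- peaks$peak_id
  colnames(pk_signal) <- sample_sheet$sample_id
  eta_linked <- matrix(0, G, S, dimnames = dimnames(latent))
  rho1 <- config$rho_acc_rna
  rho_pr <- config$rho_promoter
  if (rho_pr != 0) {
    for (g in prom_genes) {
      pk <- promoter_peak[[g]]
      pk_signal[pk, ] <- mu_pk[match(pk, peaks$peak_id)] +
        tau_atac * (rho_pr * latent[g, ] + sqrt(1 - rho_pr^2) * rnorm(S))
    }
  }
  for (g in linked_genes) {
    pk <- linked_peak[[g]]
    eta <- rnorm(S)
    eta_linked[g, ] <- eta
    pk_signal[pk, ] <- mu_pk[match(pk, peaks$peak_id)] +
      tau_atac * (rho1 * latent[g, ] + sqrt(1 - rho1^2) * eta)
  }
  # element-level differential shifts (coordinated + element-only genes):
  # both the linked enhancer and the promoter peak open/close with state
  for (g in c(coordinated, element_only)) {
    for (pk in c(linked_peak[[g]], promoter_peak[[g]])) {
      if (is.na(pk)) next
      pk_signal[pk, ] <- pk_signal[pk, ] + delta[g, state_idx]
    }
  }

  ## ---- ATAC counts with technical replicates -----------------------------
  reps <- config$replicate_count
  atac_sheet <- data.frame(
    column_id = paste0(rep(sample_sheet$sample_id, each = reps), ".rep",
                       rep(seq_len(reps), S)),
    sample_id = rep(sample_sheet$sample_id, each = reps),
    patient = rep(sample_sheet$patient, each = reps),
    state = rep(sample_sheet$state, each = reps),
    replicate = rep(seq_len(reps), S),
    stringsAsFactors = FALSE)
  sf_atac <- exp(rnorm(nrow(atac_sheet), 0, 0.2))
  mu_mat <- 2^pk_signal[, rep(seq_len(S), each = reps), drop = FALSE]
  mu_mat <- sweep(mu_mat, 2, sf_atac, "*")
  atac_counts <- matrix(
    rnbinom(length(mu_mat), mu = mu_mat, size = 1 / config$nb_dispersion),
    nrow = K, dimnames = list(peaks$peak_id, atac_sheet$column_id))

  ## ---- gene-body accessibility counts ------------------------------------
  mu_acc <- log2((genes$end - genes$start) / 1000) + 5
  acc_signal <- mu_acc + tau_atac * matrix(rnorm(G * S), G)
  for (g in linked_genes) {
    gi <- match(g, gene_ids)
    acc_signal[gi, ] <- mu_acc[gi] +
      tau_atac * (rho1 * latent[g, ] + sqrt(1 - rho1^2) * rnorm(S))
  }
  for (g in c(coordinated, element_only)) {
    gi <- match(g, gene_ids)
    acc_signal[gi, ] <- acc_signal[gi, ] + delta[g, state_idx]
  }
  sf_acc <- exp(rnorm(S, 0, 0.2))
  mu_mat <- sweep(2^acc_signal, 2, sf_acc, "*")
  gene_acc_counts <- matrix(
    rnbinom(length(mu_mat), mu = mu_mat, size = 1 / config$nb_dispersion),
    nrow = G, dimnames = list(gene_ids, sample_sheet$sample_id))

  ## ---- RNA counts ---------------------------------------------------------
  mu_rna <- rnorm(G, 7, 1.2)
  rna_signal <- mu_rna + latent
  for (g in c(coordinated, expression_only)) {
    gi <- match(g, gene_ids)
    rna_signal[gi, ] <- rna_signal[gi, ] + delta[g, state_idx]
  }
  sf_rna <- exp(rnorm(S, 0, 0.2))
  mu_mat <- sweep(2^rna_signal, 2, sf_rna, "*")
  rna_counts <- matrix(
    rnbinom(length(mu_mat), mu = mu_mat, size = 1 / config$nb_dispersion),
    nrow = G, dimnames = list(gene_ids, sample_sheet$sample_id))

  ## ---- protein signal and peptide table ----------------------------------
  rho2 <- ifelse(gene_class == "coordinated", config$rho_coordinated,
                 config$rho_rna_prot)
  gamma <- ifelse(gene_class == "coordinated" & !is.na(linked_peak),
                  config$gamma_acc_prot, 0)
  resid_sd <- sqrt(pmax(1 - rho2^2 - gamma^2, 0))
  prot_signal <- rho2 * latent + gamma * eta_linked +
    resid_sd * matrix(rnorm(G * S), G)
  for (g in c(coordinated, expression_only)) {
    gi <- match(g, gene_ids)
    prot_signal[gi, ] <- prot_signal[gi, ] + delta[g, state_idx]
  }

  n_pep <- 1L + rpois(G, max(config$peptides_per_gene - 1, 0))
  pep_gene <- rep(gene_ids, n_pep)
  pep_ids <- sprintf("pep_%05d", seq_along(pep_gene))
  pep_base <- rnorm(length(pep_ids), 10, 1.5)

  spr <- config$samples_per_run
  run_of_sample <- ceiling(seq_len(S) / spr)
  runs <- sprintf("run_%02d", unique(run_of_sample))
  design <- do.call(rbind, lapply(unique(run_of_sample), function(r) {
    ids <- sample_sheet$sample_id[run_of_sample == r]
    data.frame(run_id = sprintf("run_%02d", r),
               channel = c(sprintf("ch%02d", seq_along(ids)), "ref"),
               sample_id = c(ids, NA_character_),
               role = c(rep("sample", length(ids)), "reference"),
               stringsAsFactors = FALSE)
  }))
  pep_rows <- lapply(unique(run_of_sample), function(r) {
    des <- design[design$run_id == sprintf("run_%02d", r), ]
    n_ch <- nrow(des)
    np <- length(pep_ids)
    sig <- matrix(0, np, n_ch)
    for (j in seq_len(n_ch)) {
      if (des$role[j] == "sample") {
        sig[, j] <- prot_signal[pep_gene, des$sample_id[j]]
      }
    }
    inten <- 2^(pep_base + sig + matrix(rnorm(np * n_ch, 0, 0.3), np))
    inten[runif(np * n_ch) < config$frac_missing_peptides] <- NA_real_
    data.frame(peptide_id = rep(pep_ids, n_ch),
               gene_id = rep(pep_gene, n_ch),
               run_id = des$run_id[1],
               channel = rep(des$channel, each = np),
               intensity = as.vector(inten),
               stringsAsFactors = FALSE)
  })
  peptides <- do.call(rbind, pep_rows)

  ## ---- planted truth ------------------------------------------------------
  lp <- linked_peak[!is.na(linked_peak)]
  linked_pairs <- if (length(lp) > 0) {
    data.frame(peak_id = unname(lp), gene_id = names(lp),
               state = rep(states, each = length(lp)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(peak_id = character(), gene_id = character(),
               state = character(), stringsAsFactors = FALSE)
  }
  diff_truth <- if (n_diff > 0) {
    do.call(rbind, lapply(diff_genes, function(g) {
      cls <- gene_class[[g]]
      cmp <- t(utils::combn(seq_len(nS), 2))
      data.frame(
        gene_id = g, class = cls,
        comparison = paste0(states[cmp[, 2]], "_vs_", states[cmp[, 1]]),
        rna_logFC = ifelse(cls %in% c("coordinated", "expression_only"),
                           delta[g, cmp[, 2]] - delta[g, cmp[, 1]], 0),
        protein_logFC = ifelse(cls %in% c("coordinated", "expression_only"),
                               delta[g, cmp[, 2]] - delta[g, cmp[, 1]], 0),
        atac_logFC = ifelse(cls %in% c("coordinated", "element_only"),
                            delta[g, cmp[, 2]] - delta[g, cmp[, 1]], 0),
        stringsAsFactors = FALSE)
    }))
  } else NULL
  module_pool <- if (length(coordinated) > 0) coordinated else gene_ids
  planted_module <- sort(sample(module_pool,
                                min(config$module_size, length(module_pool))))
  truth <- structure(list(
    linked_pairs = linked_pairs,
    linked_peak = linked_peak,
    promoter_peak = promoter_peak,
    differential_genes = diff_truth,
    gene_class = gene_class,
    coordinated_genes = coordinated,
    expression_only_genes = expression_only,
    element_only_genes = element_only,
    planted_module = planted_module,
    delta = delta,
    gene_ids = gene_ids
  ), class = "planted_truth")

  cohort <- structure(list(
    sample_sheet = sample_sheet,
    atac_sheet = atac_sheet,
    peaks = peaks,
    atac_counts = atac_counts,
    gene_acc_counts = gene_acc_counts,
    rna_counts = rna_counts,
    peptides = peptides,
    design = design,
    states = states
  ), class = "omics_cohort")

  list(cohort = cohort, truth = truth)
}

#' @export
print.omics_cohort <- function(x, ...) {
  cat(sprintf(
    "Multi-omics cohort: %d samples (%d states), %d peaks, %d genes, %d peptide rows\n",
    nrow(x$sample_sheet), length(x$states), nrow(x$peaks),
    nrow(x$rna_counts), nrow(x$peptides)))
  invisible(x)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(
    "Planted truth: %d linked pairs, %d differential genes (%d coordinated), module of %d\n",
    nrow(x$linked_pairs), sum(x$gene_class != "background"),
    length(x$coordinated_genes), length(x$planted_module)))
  invisible(x)
}
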