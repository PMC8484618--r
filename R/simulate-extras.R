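# Footprint calls and interaction-network simulation; full-bundle wrapper.

#' Simulate TF footprint calls
#'
#' Emits pre-computed per-site, per-state bound/unbound calls (footprinting
#' internals are out of scope; calls are consumed, never derived from
#' reads).  Each coordinated gene receives, with probability
#' `config$footprint_prob`, a site inside its gene body bound in the gene's
#' shifted states and unbound elsewhere; background sites are bound
#' uniformly at random in every state.
#'
#' @param config a [simulation_config()].
#' @param annotation matching [simulate_annotation()] output.
#' @param truth `planted_truth` from [simulate_multiomics()].
#' @param peaks peak set of the cohort; background sites (and planted sites
#'   where possible) are placed inside peak intervals, where footprints are
#'   detectable.
#' @return data.frame with columns `motif_id`, `chrom`, `start`, `end`,
#'   `state`, `bound`, `planted`.
#' @export
simulate_footprints <- function(config, annotation, truth, peaks) {
  validate_config(config)
  set.seed(config$seed + 2L)
  states <- config$states
  genes <- annotation$genes
  motifs <- sprintf("motif_%02d", 1:20)
  rows <- list()

  for (g in truth$coordinated_genes) {
    if (runif(1) >= config$footprint_prob) next
    gi <- match(g, genes$gene_id)
    # site fully inside the gene body, and inside the linked peak when the
    # peak/body overlap can hold it (footprints live in accessible peaks)
    width <- 20L
    lo <- genes$start[gi]; hi <- genes$end[gi]
    pk <- truth$linked_peak[[g]]
    if (!is.na(pk)) {
      pki <- match(pk, peaks$peak_id)
      olo <- max(lo, peaks$start[pki])
      ohi <- min(hi, peaks$end[pki])
      if (ohi - olo >= width) { lo <- olo; hi <- ohi }
    }
    pos <- lo + floor(runif(1) * max(hi - lo - width, 1))
    shifted <- states[truth$delta[g, ] != 0]
    rows[[length(rows) + 1]] <- data.frame(
      motif_id = sample(motifs, 1), chrom = genes$chrom[gi],
      start = pos, end = pos + width, state = states,
      bound = states %in% shifted, planted = TRUE,
      stringsAsFactors = FALSE)
  }
  n_bg <- config$n_background_footprints
  if (n_bg > 0) {
    pki <- sample.int(nrow(peaks), n_bg, replace = TRUE)
    pos <- peaks$start[pki] +
      floor(runif(n_bg) * pmax(peaks$end[pki] - peaks$start[pki] - 20, 1))
    for (i in seq_len(n_bg)) {
      rows[[length(rows) + 1]] <- data.frame(
        motif_id = sample(motifs, 1), chrom = peaks$chrom[pki[i]],
        start = pos[i], end = pos[i] + 20L, state = states,
        bound = runif(length(states)) < 0.5, planted = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(motif_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      state = character(), bound = logical(),
                      planted = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a protein-protein interaction edge list
#'
#' The planted module receives dense within-module edges
#' (`config$module_density`); background edges are Erdos-Renyi over all
#' gene pairs at `config$background_edge_prob`.  Undirected, deduplicated,
#' no self-loops.
#'
#' @inheritParams simulate_footprints
#' @return data.frame with columns `from`, `to`.
#' @export
simulate_interaction_network <- function(config, truth) {
  validate_config(config)
  set.seed(config$seed + 3L)
  genes <- truth$gene_ids
  mod <- truth$planted_module
  edges <- list()
  if (length(mod) >= 2) {
    pairs <- t(utils::combn(mod, 2))
    keep <- runif(nrow(pairs)) < config$module_density
    if (any(keep))
      edges$module <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                                 stringsAsFactors = FALSE)
  }
  if (config$background_edge_prob > 0 && length(genes) >= 2) {
    n <- length(genes)
    n_pairs <- n * (n - 1) / 2
    n_draw <- rbinom(1, n_pairs, config$background_edge_prob)
    if (n_draw > 0) {
      idx <- sample(n_pairs, n_draw)
      # map linear upper-triangle index (column-major, i < j) to (i, j)
      j <- ceiling((sqrt(8 * idx + 1) + 1) / 2)
      i <- idx - (j - 1) * (j - 2) / 2
      edges$bg <- data.frame(from = genes[i], to = genes[j],
                             stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  e <- do.call(rbind, edges)
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  e <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  e <- e[e$from != e$to, ]
  rownames(e) <- NULL
  e
}

#' Simulate the full cohort bundle
#'
#' Annotation, multi-omics layers, footprint calls and interaction network
#' in one reproducible object.
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `annotation`, `cohort`, `truth`,
#'   `footprints`, `edges`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  annotation <- simulate_annotation(config)
  mo <- simulate_multiomics(config, annotation)
  footprints <- simulate_footprints(config, annotation, mo$truth,
                                    mo$cohort$peaks)
  edges <- simulate_interaction_network(config, mo$truth)
  list(config = config, annotation = annotation, cohort = mo$cohort,
       truth = mo$truth, footprints = footprints, edges = edges)
}
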