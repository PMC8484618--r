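# Differential-footprint set logic, gene-body vs distal location tests,
# and permutation enrichment of protein-protein interaction networks.

#' Differential footprint sites between two states
#'
#' Sites (per motif) bound in `state_on` AND unbound in `state_off`.
#' A site lacking an explicit call in either state is excluded: absence of
#' a call is not evidence of unbound.
#'
#' @param calls data.frame with columns `motif_id`, `chrom`, `start`,
#'   `end`, `state`, `bound`.
#' @param state_on,state_off state labels.
#' @return data.frame of sites (`motif_id`, `chrom`, `start`, `end`).
#' @export
differential_footprint_sites <- function(calls, state_on, state_off) {
  key <- paste(calls$motif_id, calls$chrom, calls$start, calls$end, sep = "|")
  on <- calls[calls$state == state_on, ]
  off <- calls[calls$state == state_off, ]
  key_on <- paste(on$motif_id, on$chrom, on$start, on$end, sep = "|")
  key_off <- paste(off$motif_id, off$chrom, off$start, off$end, sep = "|")
  common <- intersect(key_on, key_off)
  sel <- on[match(common, key_on), ]
  off_bound <- off$bound[match(common, key_off)]
  out <- sel[sel$bound & !off_bound,
             c("motif_id", "chrom", "start", "end"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-body vs distal location test for footprinted NP elements
#'
#' Splits non-promoter links into footprinted (peak overlaps a differential
#' footprint site) vs background, builds the 2x2 table against gene-body vs
#' distal location, and reports the two-sided Fisher exact p.
#'
#' @param links link table with `peak_id`, `location` (from
#'   [link_peaks_to_genes()]).
#' @param peaks peak data.frame (`peak_id`, `chrom`, `start`, `end`).
#' @param sites differential footprint sites (`chrom`, `start`, `end`).
#' @return list with `contingency`, `fisher_p`, `odds_ratio`.
#' @export
footprint_location_test <- function(links, peaks, sites) {
  pk <- peaks[match(unique(links$peak_id), peaks$peak_id), ]
  fp_peaks <- if (nrow(sites) > 0) {
    pk$peak_id[IRanges::overlapsAny(.bed_to_gr(pk), .bed_to_gr(sites),
                                          ignore.strand = TRUE)]
  } else character(0)
  footprinted <- links$peak_id %in% fp_peaks
  if (all(footprinted) || !any(footprinted))
    .stopf("footprint_location_test: empty footprinted or background set")
  tab <- table(
    set = factor(ifelse(footprinted, "footprinted", "background"),
                 levels = c("footprinted", "background")),
    location = factor(links$location, levels = c("gene_body", "distal"))
  )
  ft <- fisher.test(tab)
  list(contingency = tab, fisher_p = ft$p.value,
       odds_ratio = unname(ft$estimate))
}

#' Induced protein-protein interaction subnetwork
#'
#' Induced subgraph of the (deduplicated, undirected) global edge list on
#' the intersection of `gene_set` with the network nodes.
#'
#' @param gene_set character vector of gene ids.
#' @param edges data.frame with columns `from`, `to`.
#' @return list with `nodes`, `edges` (data.frame), `E_obs`.
#' @export
build_ppi_subnetwork <- function(gene_set, edges) {
  g <- .ppi_graph(edges)
  nodes <- intersect(unique(gene_set), igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, nodes)
  el <- igraph::as_data_frame(sub, what = "edges")
  list(nodes = nodes, edges = el, E_obs = igraph::ecount(sub))
}

.ppi_graph <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Permutation p-value for interaction enrichment of a gene set
#'
#' Each permutation draws a uniform random gene set of the same size from
#' the background (the detected proteome overlapped with the network) and
#' counts induced edges; a Gaussian is fitted to the permuted counts and
#' the one-sided upper-tail p computed from the z-score of the observed
#' count.  The empirical-quantile p is reported alongside (the Gaussian
#' approximation can be poor for small sets).  `mode = "rewire"` uses a
#' degree-preserving edge-rewiring null instead of uniform node draws.
#'
#' @param gene_set character vector of gene ids.
#' @param edges global edge list (`from`, `to`).
#' @param background_genes background universe (must contain at least
#'   `length(gene_set)` genes).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param mode `"uniform"` (default) or `"rewire"`.
#' @return object of class `network_permutation`: list with `E_obs`,
#'   `mu_null`, `sigma_null`, `z`, `p`, `p_empirical`, `n_perm`,
#'   `degenerate`.
#' @export
permuted_network_pvalue <- function(gene_set, edges, background_genes,
                                    n_perm = 1000L, seed = 1L,
                                    mode = c("uniform", "rewire")) {
  mode <- match.arg(mode)
  set.seed(seed)
  g <- .ppi_graph(edges)
  gene_set <- unique(gene_set)
  background_genes <- unique(background_genes)
  if (length(gene_set) > length(background_genes))
    .stopf("gene set larger than background")
  obs_nodes <- intersect(gene_set, igraph::V(g)$name)
  E_obs <- igraph::ecount(igraph::induced_subgraph(g, obs_nodes))
  k <- length(gene_set)
  null_counts <- if (mode == "uniform") {
    vapply(seq_len(n_perm), function(i) {
      s <- sample(background_genes, k)
      igraph::ecount(igraph::induced_subgraph(
        g, intersect(s, igraph::V(g)$name)))
    }, numeric(1))
  } else {
    vapply(seq_len(n_perm), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(
        niter = igraph::ecount(g) * 10))
      igraph::ecount(igraph::induced_subgraph(gr, obs_nodes))
    }, numeric(1))
  }
  mu <- mean(null_counts)
  sigma <- sd(null_counts)
  degenerate <- !is.finite(sigma) || sigma == 0
  z <- if (degenerate) NA_real_ else (E_obs - mu) / sigma
  structure(list(
    E_obs = E_obs, mu_null = mu, sigma_null = sigma, z = z,
    p = if (degenerate) NA_real_ else pnorm(z, lower.tail = FALSE),
    p_empirical = (1 + sum(null_counts >= E_obs)) / (n_perm + 1),
    n_perm = n_perm, degenerate = degenerate, mode = mode
  ), class = "network_permutation")
}

#' @export
print.network_permutation <- function(x, ...) {
  cat(sprintf(
    "Network permutation (%s null, %d perms): E_obs = %d, null %.2f +/- %.2f, z = %.2f, p = %.3g (empirical %.3g)\n",
    x$mode, x$n_perm, x$E_obs, x$mu_null, x$sigma_null,
    ifelse(is.na(x$z), NaN, x$z), x$p, x$p_empirical))
  invisible(x)
}
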