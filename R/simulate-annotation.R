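# Toy genome annotation: non-overlapping multi-exon gene models on a
# multi-chromosome genome.

#' Simulate a toy genome annotation
#'
#' Genes are placed without overlap along each chromosome with random
#' intergenic gaps; each gene has >= 1 exon, alternating exon/intron
#' structure, both strands are represented, and the first TSS is the gene
#' start on + and `end - 1` on -.
#'
#' @param config a [simulation_config()].
#' @return object of class `gene_annotation`: list with `genes`
#'   (data.frame: gene_id, chrom, start, end, strand, tss, exonic_bp),
#'   `exons` (data.frame: gene_id, chrom, start, end) and `chrom_sizes`
#'   (named vector).
#' @export
simulate_annotation <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_sizes <- setNames(rep(config$chromosome_length, length(chroms)),
                          chroms)

  n_per <- diff(floor(seq(0, config$n_genes, length.out =
                            length(chroms) + 1)))
  gene_rows <- list(); exon_rows <- list(); gid <- 0L
  for (ci in seq_along(chroms)) {
    n <- n_per[ci]
    if (n == 0) next
    len <- pmin(pmax(round(rlnorm(n, log(8000), 0.5)), 1000L), 50000L)
    if (sum(len) > chrom_sizes[ci])
      .stopf("genome capacity exceeded: %d genes x mean length %.0f bp > %s (%.0f bp)",
             n, mean(len), chroms[ci], chrom_sizes[ci])
    free <- chrom_sizes[ci] - sum(len)
    gaps <- as.numeric(stats::rmultinom(1, size = free, prob = rep(1, n + 1)))
    starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, len[-n]))
    starts <- as.integer(starts)
    strand <- rep(c("+", "-"), length.out = n)[sample.int(n)]
    for (k in seq_len(n)) {
      gid <- gid + 1L
      id <- sprintf("gene_%04d", gid)
      g_start <- starts[k]; g_end <- starts[k] + len[k]
      ex <- .simulate_exons(g_start, g_end)
      gene_rows[[gid]] <- data.frame(
        gene_id = id, chrom = chroms[ci], start = g_start, end = g_end,
        strand = strand[k],
        tss = if (strand[k] == "+") g_start else g_end - 1L,
        exonic_bp = sum(ex$end - ex$start), stringsAsFactors = FALSE)
      exon_rows[[gid]] <- data.frame(gene_id = id, chrom = chroms[ci],
                                     start = ex$start, end = ex$end,
                                     stringsAsFactors = FALSE)
    }
  }
  structure(list(
    genes = do.call(rbind, gene_rows),
    exons = do.call(rbind, exon_rows),
    chrom_sizes = chrom_sizes
  ), class = "gene_annotation")
}

# Alternating exon/intron structure covering [start, end); first and last
# segments are exons.  Introns are drawn longer than exons on average.
.simulate_exons <- function(start, end) {
  len <- end - start
  k <- 1L + rpois(1, 2)
  if (k == 1 || len < (2 * k - 1) * 60) {
    return(data.frame(start = start, end = end))
  }
  n_seg <- 2L * k - 1L
  w <- c(rexp(k) + 0.2, rexp(k - 1) * 4 + 0.2)  # exons then introns
  ord <- integer(n_seg)
  ord[seq(1, n_seg, by = 2)] <- seq_len(k)
  ord[seq(2, n_seg, by = 2)] <- k + seq_len(k - 1)
  w <- w[ord]
  seg <- pmax(30L, as.integer(floor(w / sum(w) * len)))
  seg[n_seg] <- len - sum(seg[-n_seg])
  if (seg[n_seg] < 30) return(data.frame(start = start, end = end))
  bounds <- start + cumsum(c(0L, seg))
  idx <- seq(1, n_seg, by = 2)
  data.frame(start = bounds[idx], end = bounds[idx + 1])
}

#' Intron intervals of a gene model
#'
#' Gene body minus exons.
#'
#' @param annotation a `gene_annotation`.
#' @param gene_id single gene id.
#' @return data.frame with columns `start`, `end` (possibly 0 rows).
#' @export
gene_introns <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$start), ]
  if (nrow(ex) <= 1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("Toy annotation: %d genes on %d chromosomes (%.1f Mb total)\n",
              nrow(x$genes), length(x$chrom_sizes),
              sum(x$chrom_sizes) / 1e6))
  invisible(x)
}
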