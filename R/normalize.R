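# Per-layer normalization chains: ATAC peak counts (log-CPM -> quantile ->
# replicate average), RNA transform, gene-body accessibility RPKM, and
# peptide-to-protein rollup against a reference channel.

#' Log2 counts per million with a library-scaled pseudo-count
#'
#' For column j with library size \eqn{L_j} and scaled prior
#' \eqn{p_j = prior \times L_j / mean(L)}, each count c becomes
#' \deqn{log2( (c + p_j) / (L_j + 2 p_j) \times 10^6 ).}
#' This matches the log-CPM convention of count-based differential packages
#' (prior count 5 by default).
#'
#' @param counts non-negative feature x sample count matrix.
#' @param prior pseudo-count before library scaling (default 5).
#' @param lib_size optional explicit library sizes; defaults to column sums.
#' @return matrix of log2-CPM values, dimnames preserved.
#' @export
log_cpm <- function(counts, prior = 5, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stopf("log_cpm expects non-negative counts")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) .stopf("zero library size")
  pj <- prior * lib_size / mean(lib_size)
  out <- log2(sweep(sweep(counts, 2, pj, "+"), 2, lib_size + 2 * pj, "/") * 1e6)
  dimnames(out) <- dimnames(counts)
  out
}

#' Quantile normalization
#'
#' Every column is mapped onto the common reference distribution given by
#' the row-wise mean of the column-sorted inputs; tied values within a
#' column receive the mean of their tied reference quantiles, which makes
#' the result deterministic and independent of input order.
#'
#' @param x numeric matrix (>= 2 columns).
#' @return matrix of the same shape, dimnames preserved.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) .stopf("quantile_normalize needs >= 2 columns")
  if (any(!is.finite(x))) .stopf("quantile_normalize expects finite values")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    o <- order(col)
    sorted <- col[o]
    grp <- cumsum(c(1L, diff(sorted) != 0))
    v <- ave(ref, grp, FUN = mean)
    res <- numeric(length(col))
    res[o] <- v
    res
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Average technical replicate columns
#'
#' Collapses a log-scale matrix to one column per biological sample by the
#' arithmetic (log2-average) mean of its replicate columns.
#'
#' @param x matrix whose columns are technical replicates.
#' @param groups character/factor of length `ncol(x)` giving the biological
#'   sample of each column.
#' @return matrix with one column per level of `groups` (in order of first
#'   appearance).
#' @export
average_replicates <- function(x, groups) {
  x <- as.matrix(x)
  if (length(groups) != ncol(x))
    .stopf("groups must have one entry per column")
  groups <- as.character(groups)
  lv <- unique(groups)
  cols_of <- lapply(lv, function(g) which(groups == g))
  if (any(lengths(cols_of) == 0)) .stopf("replicate group has no columns")
  out <- matrix(0, nrow(x), length(lv),
                dimnames = list(rownames(x), lv))
  for (j in seq_along(lv))
    out[, j] <- rowMeans(x[, cols_of[[j]], drop = FALSE])
  out
}

#' Transform raw RNA counts for correlation analysis
#'
#' Applies [log_cpm()] with prior count 5.  This log transform stands in
#' for a variance-stabilizing transform: the downstream linkage statistics
#' depend only on approximate linearity of the transformed counts.
#'
#' @inheritParams log_cpm
#' @return matrix of transformed values.
#' @export
transform_rna <- function(counts, prior = 5) {
  log_cpm(counts, prior = prior)
}

#' Full ATAC peak-count normalization chain
#'
#' log-CPM (prior 5), quantile normalization across all replicate columns,
#' then log2-averaging of technical replicates.
#'
#' @param counts raw peak x replicate count matrix.
#' @param groups biological sample of each column (see
#'   [average_replicates()]).
#' @param prior pseudo-count for [log_cpm()].
#' @return normalized peak x biological-sample matrix.
#' @export
normalize_atac <- function(counts, groups, prior = 5) {
  average_replicates(quantile_normalize(log_cpm(counts, prior = prior)),
                     groups)
}

#' Gene-body accessibility RPKM
#'
#' Reads per kilobase of gene body per million library reads:
#' `reads / (gene_length_kb * library_size_millions)`, followed by quantile
#' normalization across the cohort.  Counts are expected to already exclude
#' promoter-peak bp; the denominator uses the full gene-body length.
#'
#' @param counts gene x sample matrix of ATAC reads in gene bodies
#'   (promoter-peak bp excluded upstream).
#' @param gene_lengths gene-body lengths in bp, aligned with rows.
#' @param library_sizes per-sample total read counts; defaults to column
#'   sums of `counts`.
#' @param quantile apply quantile normalization (default TRUE).
#' @return gene x sample matrix of (normalized) RPKM.
#' @export
gene_body_rpkm <- function(counts, gene_lengths,
                           library_sizes = colSums(counts),
                           quantile = TRUE) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    .stopf("gene_lengths must align with rows of counts")
  if (any(gene_lengths <= 0)) .stopf("zero-length gene")
  if (any(library_sizes <= 0)) .stopf("zero library size")
  rpkm <- sweep(sweep(counts, 1, gene_lengths / 1e3, "/"),
                2, library_sizes / 1e6, "/")
  if (quantile && ncol(rpkm) >= 2) rpkm <- quantile_normalize(rpkm)
  rpkm
}

#' Peptide-to-protein rollup with reference-channel ratios
#'
#' Per run: (1) missing peptide intensities are set to the minimum observed
#' intensity in that run (across all peptides and channels); (2) each
#' channel is rescaled so its total equals the total summed abundance of
#' the run's reference channel(s); (3) per gene, unique peptide intensities
#' are summed in the sample channel and in the reference channel(s) and the
#' sample/reference ratio taken (weighting the ratio toward intense
#' peptides); (4) ratios are log2 transformed; (5) technical replicates
#' (the same biological sample measured in several runs/channels) are
#' averaged.  A gene with no detected peptide in a run is absent (NA) for
#' that run's samples, not zero.
#'
#' @param peptides data.frame with columns `peptide_id`, `gene_id`,
#'   `run_id`, `channel`, `intensity` (NA = missing measurement).
#' @param design data.frame with columns `run_id`, `channel`, `sample_id`,
#'   `role` (`"sample"` or `"reference"`).
#' @return gene x sample matrix of log2 sample/reference ratios.
#' @export
rollup_protein <- function(peptides, design) {
  need <- c("peptide_id", "gene_id", "run_id", "channel", "intensity")
  stopifnot(all(need %in% names(peptides)))
  stopifnot(all(c("run_id", "channel", "sample_id", "role") %in% names(design)))
  runs <- unique(peptides$run_id)
  genes <- sort(unique(peptides$gene_id))
  samples <- unique(design$sample_id[design$role == "sample"])

  # accumulate per (gene, sample) log2 ratios across runs, then average
  acc_sum <- matrix(0, length(genes), length(samples),
                    dimnames = list(genes, samples))
  acc_n <- matrix(0L, length(genes), length(samples),
                  dimnames = list(genes, samples))

  for (run in runs) {
    sub <- peptides[peptides$run_id == run, , drop = FALSE]
    des <- design[design$run_id == run, , drop = FALSE]
    ref_channels <- des$channel[des$role == "reference"]
    if (length(ref_channels) == 0)
      .stopf("run '%s' has no reference channel", run)
    if (all(is.na(sub$intensity)))
      .stopf("run '%s' has no observed intensities", run)
    run_min <- min(sub$intensity, na.rm = TRUE)
    sub$intensity[is.na(sub$intensity)] <- run_min

    totals <- tapply(sub$intensity, sub$channel, sum)
    ref_total <- sum(totals[as.character(ref_channels)], na.rm = TRUE)
    factor <- ref_total / totals[as.character(sub$channel)]
    sub$intensity <- sub$intensity * as.numeric(factor)

    is_ref <- sub$channel %in% ref_channels
    ref_sum <- tapply(sub$intensity[is_ref], sub$gene_id[is_ref], sum)

    smp <- des[des$role == "sample", , drop = FALSE]
    for (i in seq_len(nrow(smp))) {
      in_ch <- sub$channel == smp$channel[i] & !is_ref
      if (!any(in_ch)) next
      g_sum <- tapply(sub$intensity[in_ch], sub$gene_id[in_ch], sum)
      g_ids <- names(g_sum)
      ref_vals <- ref_sum[g_ids]
      ok <- !is.na(ref_vals) & ref_vals > 0
      if (!any(ok)) next
      lr <- log2(g_sum[ok] / ref_vals[ok])
      acc_sum[g_ids[ok], smp$sample_id[i]] <-
        acc_sum[g_ids[ok], smp$sample_id[i]] + lr
      acc_n[g_ids[ok], smp$sample_id[i]] <-
        acc_n[g_ids[ok], smp$sample_id[i]] + 1L
    }
  }
  out <- acc_sum / acc_n
  out[acc_n == 0] <- NA_real_
  out
}
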