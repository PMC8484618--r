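# Peak-to-gene linkage: per-state Pearson correlation of cis-peak
# accessibility with transformed RNA, tested against a per-gene, per-state
# Gaussian null built from random trans-chromosome peaks.

#' Candidate cis peaks for a gene
#'
#' Peaks whose interval overlaps the window `[tss - window, tss + window)`
#' on the gene's chromosome (500 kb total by default: 250 kb each side of
#' the first TSS).
#'
#' @param gene one row of a gene-model data.frame (`chrom`, `tss`).
#' @param peaks peak data.frame (`peak_id`, `chrom`, `start`, `end`).
#' @param window bp on each side of the TSS (default 250000).
#' @return character vector of peak ids.
#' @export
candidate_cis_peaks <- function(gene, peaks, window = 250000L) {
  lo <- gene$tss - window
  hi <- gene$tss + window
  sel <- peaks$chrom == gene$chrom & peaks$start < hi & peaks$end > lo
  peaks$peak_id[sel]
}

#' Build the trans-peak Gaussian null for one gene and state
#'
#' Samples `n_sample` trans peaks (without replacement when enough are
#' available, otherwise with replacement), computes the Pearson correlation
#' of each with the gene's transformed RNA across the state's samples, and
#' fits a Gaussian (mean, n-1 sd) to the null correlations.
#' Constant-accessibility peaks are skipped.
#'
#' @param gene_rna numeric vector: the gene's transformed RNA within one
#'   state.
#' @param trans_peaks accessibility matrix (peaks x samples) for peaks on
#'   other chromosomes, columns aligned with `gene_rna`.
#' @param n_sample number of null correlations (default 10000).
#' @param seed optional seed for the sampling.
#' @return object of class `gaussian_null`: list with `mu`, `sigma`,
#'   `n_null`, `n_available`.
#' @export
build_trans_null <- function(gene_rna, trans_peaks, n_sample = 10000L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trans_peaks <- as.matrix(trans_peaks)
  if (length(gene_rna) < 3) .stopf("need >= 3 samples in state")
  r <- suppressWarnings(as.vector(cor(gene_rna, t(trans_peaks))))
  r <- sort(r[!is.na(r)])  # order-invariant sampling pool
  if (length(r) == 0) .stopf("all trans peaks constant")
  idx <- if (length(r) >= n_sample) sample.int(length(r), n_sample)
         else sample.int(length(r), n_sample, replace = TRUE)
  vals <- r[idx]
  sigma <- sd(vals)
  if (!is.finite(sigma) || sigma == 0) .stopf("degenerate null: sigma = 0")
  structure(list(mu = mean(vals), sigma = sigma, n_null = n_sample,
                 n_available = length(r)), class = "gaussian_null")
}

#' Gaussian-null p-value for an observed correlation
#'
#' One-sided upper-tail \eqn{p = 1 - \Phi((r - \mu)/\sigma)} by default
#' (activating links); `alternative = "two.sided"` doubles the smaller
#' tail.
#'
#' @param r observed Pearson correlation(s).
#' @param null a `gaussian_null` (or any list with `mu`, `sigma`).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return p-value(s).
#' @export
gaussian_null_p <- function(r, null, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(null$sigma) || null$sigma <= 0) .stopf("null sigma must be > 0")
  z <- (r - null$mu) / null$sigma
  if (alternative == "greater") pnorm(z, lower.tail = FALSE)
  else 2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Link peaks to genes via per-state correlation against trans-peak nulls
#'
#' For each state with >= 3 samples, the Pearson correlation of every
#' candidate cis peak (window around the first TSS) with the gene's
#' transformed RNA is tested against that gene x state trans-peak Gaussian
#' null; BH adjustment is applied within state across all tested pairs, and
#' pairs at `q < fdr` form the per-state link set (the union over states is
#' the reported link set).  Links are annotated with peak class, distance
#' to the gene body, gene-body/distal location and exon/intron assignment
#' of the summit.
#'
#' @param peak_mat normalized peak accessibility (peaks x samples).
#' @param rna_mat transformed RNA (genes x samples), same sample columns.
#' @param peaks peak data.frame (`peak_id`, `chrom`, `start`, `end`,
#'   `summit`).
#' @param annotation a `gene_annotation`.
#' @param sample_sheet data.frame with `sample_id`, `state`.
#' @param window cis window per side (default 250000).
#' @param n_null trans-peak null sample size (default 10000).
#' @param fdr link FDR (default 0.05).
#' @param seed seed for trans-peak sampling.
#' @param alternative passed to [gaussian_null_p()].
#' @return data.frame of all tested pairs with columns `peak_id`,
#'   `gene_id`, `state`, `r`, `p`, `q`, `significant`, `peak_class`,
#'   `distance`, `location`, `exon_intron`.  Significant links are
#'   `significant == TRUE`.
#' @export
link_peaks_to_genes <- function(peak_mat, rna_mat, peaks, annotation,
                                sample_sheet, window = 250000L,
                                n_null = 10000L, fdr = 0.05, seed = 1L,
                                alternative = "greater") {
  set.seed(seed)
  genes <- annotation$genes
  stopifnot(identical(colnames(peak_mat), colnames(rna_mat)))
  ss <- sample_sheet[match(colnames(peak_mat), sample_sheet$sample_id), ]

  # candidate cis pairs via interval overlap of peaks with TSS windows
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$tss - window),
                    end = genes$tss + window)
  hits <- GenomicRanges::findOverlaps(.bed_to_gr(peaks), .bed_to_gr(win),
                                      ignore.strand = TRUE)
  cand <- data.frame(peak = S4Vectors::queryHits(hits),
                     gene = S4Vectors::subjectHits(hits))
  if (nrow(cand) == 0)
    .stopf("no candidate cis peak-gene pairs")

  states <- unique(ss$state)
  res <- list()
  for (st in states) {
    cols <- which(ss$state == st)
    if (length(cols) < 3) {
      .warnf("state '%s' skipped: < 3 samples", st)
      next
    }
    P <- t(peak_mat[, cols, drop = FALSE])
    R <- t(rna_mat[, cols, drop = FALSE])
    C <- suppressWarnings(cor(P, R))  # peaks x genes

    r_obs <- C[cbind(cand$peak, cand$gene)]
    p_obs <- rep(NA_real_, nrow(cand))
    peak_ok <- !apply(is.na(C), 1, all)

    for (gi in sort(unique(cand$gene))) {
      trans <- which(peaks$chrom != genes$chrom[gi] & peak_ok)
      pool <- C[trans, gi]
      pool <- sort(pool[!is.na(pool)])  # order-invariant sampling pool
      rows <- which(cand$gene == gi)
      if (length(pool) == 0) next
      idx <- if (length(pool) >= n_null) sample.int(length(pool), n_null)
             else sample.int(length(pool), n_null, replace = TRUE)
      vals <- pool[idx]
      mu <- mean(vals); sigma <- sd(vals)
      if (!is.finite(sigma) || sigma == 0) next
      null <- list(mu = mu, sigma = sigma)
      p_obs[rows] <- gaussian_null_p(r_obs[rows], null,
                                     alternative = alternative)
    }
    tested <- !is.na(r_obs) & !is.na(p_obs)
    q <- rep(NA_real_, nrow(cand))
    q[tested] <- bh_adjust(p_obs[tested])
    res[[st]] <- data.frame(
      peak_id = peaks$peak_id[cand$peak],
      gene_id = genes$gene_id[cand$gene],
      state = st, r = r_obs, p = p_obs, q = q,
      significant = !is.na(q) & q < fdr,
      stringsAsFactors = FALSE)[tested, ]
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0) .stopf("no testable peak-gene pairs")

  out$peak_class <- classify_peaks(
    peaks[match(out$peak_id, peaks$peak_id), ], genes)
  pk <- peaks[match(out$peak_id, peaks$peak_id), ]
  gn <- genes[match(out$gene_id, genes$gene_id), ]
  d <- distance_to_gene_body(pk$start, pk$end, gn$start, gn$end)
  out$distance <- d$distance
  out$location <- ifelse(d$in_gene_body, "gene_body", "distal")
  ex_by_gene <- split(annotation$exons[, c("start", "end")],
                      annotation$exons$gene_id)
  out$exon_intron <- vapply(seq_len(nrow(out)), function(i) {
    assign_exon_intron(pk$summit[i], gn[i, ], ex_by_gene[[gn$gene_id[i]]])
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Significant links from a tested-pair table
#'
#' @param tested output of [link_peaks_to_genes()].
#' @return the subset with `significant == TRUE`.
#' @export
significant_links <- function(tested) {
  tested[tested$significant, , drop = FALSE]
}
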