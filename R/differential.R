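# Two-group differential statistics on normalized log-scale matrices, with
# per-layer FDR thresholds and derived per-gene differential flags.

#' Layer-specific FDR thresholds for differential calls
#'
#' Peak accessibility is called at FDR 0.01 (a union peak set is noisy, so
#' a stringent threshold mitigates false positives); RNA, protein and
#' gene-accessibility layers at FDR 0.1.
#'
#' @export
default_fdr_thresholds <- c(atac_peak = 0.01, rna = 0.1, protein = 0.1,
                            gene_accessibility = 0.1)

#' Welch two-sample t-test on log-scale values
#'
#' `logFC` is `mean(group2) - mean(group1)`.  When both groups have zero
#' variance, p is 1 for equal means and 0 otherwise.
#'
#' @param values numeric vector of per-sample measurements (NAs dropped
#'   per group).
#' @param groups two-level factor/character aligned with `values`; the
#'   second level (order of first appearance unless a factor) is the
#'   numerator of the fold change.
#' @return list with `logFC`, `t`, `df`, `p`.
#' @export
two_group_test <- function(values, groups) {
  lv <- if (is.factor(groups)) levels(droplevels(groups))
        else unique(groups)
  groups <- as.character(groups)
  if (length(lv) != 2) .stopf("two_group_test needs exactly two groups")
  x1 <- values[groups == lv[1] & !is.na(values)]
  x2 <- values[groups == lv[2] & !is.na(values)]
  if (length(x1) < 2 || length(x2) < 2)
    .stopf("each group needs n >= 2")
  res <- .welch_rows(matrix(c(x1, x2), nrow = 1),
                     seq_along(x1), length(x1) + seq_along(x2))
  list(logFC = res$logFC[1], t = res$t[1], df = res$df[1], p = res$p[1])
}

# Vectorized Welch test over matrix rows; cols1/cols2 index the two groups.
# NA-tolerant: per-row group sizes reflect observed values.
.welch_rows <- function(x, cols1, cols2) {
  x1 <- x[, cols1, drop = FALSE]
  x2 <- x[, cols2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  logFC <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  t <- logFC / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  # degenerate rows: zero variance in both groups
  degen <- se2 == 0
  p[degen & logFC == 0] <- 1
  t[degen & logFC == 0] <- 0
  p[degen & logFC != 0] <- 0
  t[degen & logFC != 0] <- Inf * sign(logFC[degen & logFC != 0])
  small <- n1 < 2 | n2 < 2
  p[small] <- NA_real_
  t[small] <- NA_real_
  list(logFC = logFC, t = t, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement; NA p-values are
#' propagated and excluded from the number of tests.
#'
#' @param p numeric vector of p-values (NAs allowed).
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Differential calls for all pairwise state comparisons
#'
#' For each ordered pair of states (later state vs earlier, in the order of
#' `states`), a Welch test per feature with BH adjustment within that
#' comparison; `significant` flags q below the layer threshold.
#'
#' @param x normalized log-scale feature x sample matrix (columns named by
#'   sample id).
#' @param sample_sheet data.frame with columns `sample_id`, `state` (and
#'   optionally more) covering the columns of `x`.
#' @param layer one of `names(default_fdr_thresholds)`, or any label when
#'   `threshold` is given explicitly.
#' @param threshold FDR threshold; defaults to the layer's entry in
#'   [default_fdr_thresholds].
#' @param states state order; defaults to order of first appearance.
#' @return data.frame with columns `feature_id`, `comparison`, `logFC`,
#'   `t`, `p`, `q`, `significant`.
#' @export
call_differential <- function(x, sample_sheet, layer = "rna",
                              threshold = NULL, states = NULL) {
  if (is.null(threshold)) {
    if (!layer %in% names(default_fdr_thresholds))
      .stopf("unknown layer '%s'; supply threshold explicitly", layer)
    threshold <- default_fdr_thresholds[[layer]]
  }
  x <- as.matrix(x)
  ss <- sample_sheet[match(colnames(x), sample_sheet$sample_id), ]
  if (any(is.na(ss$sample_id)))
    .stopf("columns of x missing from sample_sheet")
  if (is.null(states)) states <- unique(ss$state)
  if (length(states) < 2) .stopf("need >= 2 states")
  out <- list()
  for (i in seq_len(length(states) - 1)) {
    for (j in seq(i + 1, length(states))) {
      s1 <- states[i]; s2 <- states[j]
      cols1 <- which(ss$state == s1)
      cols2 <- which(ss$state == s2)
      cmp <- paste0(s2, "_vs_", s1)
      if (length(cols1) < 2 || length(cols2) < 2) {
        .warnf("comparison %s skipped: a state has < 2 samples", cmp)
        next
      }
      w <- .welch_rows(x, cols1, cols2)
      q <- bh_adjust(w$p)
      out[[cmp]] <- data.frame(
        feature_id = rownames(x), comparison = cmp,
        logFC = w$logFC, t = w$t, p = w$p, q = q,
        significant = !is.na(q) & q < threshold,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-gene differential-expression flags
#'
#' A gene is differentially expressed when it is significant in any
#' pairwise comparison at the RNA or the protein layer.
#'
#' @param rna_records,protein_records outputs of [call_differential()] for
#'   the RNA and protein layers (either may be NULL).
#' @return named logical vector over the union of feature ids.
#' @export
differential_gene_flags <- function(rna_records, protein_records = NULL) {
  recs <- rbind(rna_records, protein_records)
  tapply(recs$significant, recs$feature_id, any)[
    unique(recs$feature_id)]
}

#' Per-feature differential flags from call records
#'
#' @param records output of [call_differential()].
#' @param comparison optional single comparison to restrict to.
#' @return named logical vector (any significant comparison).
#' @export
differential_flags <- function(records, comparison = NULL) {
  if (!is.null(comparison))
    records <- records[records$comparison == comparison, ]
  tapply(records$significant, records$feature_id, any)[
    unique(records$feature_id)]
}
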