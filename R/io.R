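# Plain-text readers/writers for the cohort bundle: BED6(+) peaks and
# footprints, BED12 gene models, TSV matrices and sample sheets.

#' Write a numeric matrix as TSV (feature column first)
#'
#' @param x matrix with row and column names.
#' @param path output file.
#' @param id_col name of the feature-id column (default `feature_id`).
#' @export
write_matrix_tsv <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path input file.
#' @return numeric matrix with rownames from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write peaks as BED6 plus a summit-offset column
#'
#' Columns: chrom, start, end, name, score (0), strand (.), summit offset
#' relative to start.
#'
#' @param peaks peak data.frame (`peak_id`, `chrom`, `start`, `end`,
#'   `summit`).
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   0L, ".", peaks$summit - peaks$start)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read peaks from BED6 + summit-offset
#'
#' @param path input file.
#' @return peak data.frame (`peak_id`, `chrom`, `start`, `end`, `summit`).
#' @export
read_peaks_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(peak_id = df$V4, chrom = df$V1, start = df$V2, end = df$V3,
             summit = df$V2 + df$V7, stringsAsFactors = FALSE)
}

#' Write gene models as BED12
#'
#' Exons become blocks; thickStart/thickEnd span the body; score 0.
#'
#' @param annotation a `gene_annotation`.
#' @param path output file.
#' @export
write_genes_bed12 <- function(annotation, path) {
  g <- annotation$genes
  ex <- annotation$exons
  rows <- lapply(seq_len(nrow(g)), function(i) {
    e <- ex[ex$gene_id == g$gene_id[i], ]
    e <- e[order(e$start), ]
    data.frame(
      g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0L, g$strand[i],
      g$start[i], g$end[i], "0",
      nrow(e),
      paste0(paste(e$end - e$start, collapse = ","), ","),
      paste0(paste(e$start - g$start[i], collapse = ","), ","),
      stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read gene models from BED12
#'
#' @param path input file.
#' @param chrom_sizes optional named vector to attach.
#' @return a `gene_annotation`.
#' @export
read_genes_bed12 <- function(path, chrom_sizes = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = df$V4, chrom = df$V1, start = df$V2, end = df$V3,
    strand = df$V6,
    tss = ifelse(df$V6 == "+", df$V2, df$V3 - 1L),
    stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    sizes <- as.integer(strsplit(df$V11[i], ",")[[1]])
    starts <- as.integer(strsplit(df$V12[i], ",")[[1]])
    data.frame(gene_id = df$V4[i], chrom = df$V1[i],
               start = df$V2[i] + starts, end = df$V2[i] + starts + sizes,
               stringsAsFactors = FALSE)
  }))
  genes$exonic_bp <- tapply(exons$end - exons$start, exons$gene_id,
                            sum)[genes$gene_id]
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
  }
  structure(list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
            class = "gene_annotation")
}

#' Write footprint calls as BED6 plus motif/state/bound columns
#'
#' @param footprints data.frame from [simulate_footprints()].
#' @param path output file.
#' @export
write_footprints_bed <- function(footprints, path) {
  df <- data.frame(footprints$chrom, footprints$start, footprints$end,
                   footprints$motif_id, 0L, ".",
                   footprints$state, as.integer(footprints$bound))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read footprint calls written by [write_footprints_bed()]
#'
#' @param path input file.
#' @return data.frame (`motif_id`, `chrom`, `start`, `end`, `state`,
#'   `bound`).
#' @export
read_footprints_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(motif_id = df$V4, chrom = df$V1, start = df$V2, end = df$V3,
             state = df$V7, bound = df$V8 == 1, stringsAsFactors = FALSE)
}

#' Write the full synthetic cohort bundle to a directory
#'
#' Emits peaks (BED6+summit), genes (BED12), chromosome sizes, count
#' matrices (TSV), sample sheets, the peptide table and proteomics design,
#' footprints (BED6+motif/state/bound), interaction edges, and the planted
#' truth as TSV tables.
#'
#' @param bundle output of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_peaks_bed(bundle$cohort$peaks, p("peaks.bed"))
  write_genes_bed12(bundle$annotation, p("genes.bed12"))
  write.table(data.frame(names(bundle$annotation$chrom_sizes),
                         unname(bundle$annotation$chrom_sizes)),
              p("chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_matrix_tsv(bundle$cohort$atac_counts, p("atac_counts.tsv"),
                   "peak_id")
  write_matrix_tsv(bundle$cohort$rna_counts, p("rna_counts.tsv"), "gene_id")
  write_matrix_tsv(bundle$cohort$gene_acc_counts,
                   p("gene_accessibility_counts.tsv"), "gene_id")
  write.table(bundle$cohort$sample_sheet, p("samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$cohort$atac_sheet, p("atac_replicates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$cohort$peptides, p("peptides.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$cohort$design, p("proteomics_design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_footprints_bed(bundle$footprints, p("footprints.bed"))
  write.table(bundle$edges, p("ppi_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$truth$linked_pairs, p("truth_linked_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$truth$differential_genes))
    write.table(bundle$truth$differential_genes,
                p("truth_differential_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(bundle$truth$gene_class),
                         class = unname(bundle$truth$gene_class)),
              p("truth_gene_class.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = bundle$truth$planted_module),
              p("truth_module.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
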