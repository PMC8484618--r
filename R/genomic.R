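# Genomic geometry: peak-set construction from summits, promoter
# classification, distances, exon/intron assignment, contact-domain
# containment.  All coordinates are 0-based half-open (BED convention).

#' Extend peak summits to fixed-width intervals
#'
#' Each summit is extended by `flank` bp on either side, producing a
#' `2 * flank` wide interval clamped to the chromosome bounds (intervals at
#' a chromosome edge are shorter).
#'
#' @param summits data.frame with columns `chrom` and `pos` (0-based summit
#'   coordinate).
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param flank bp added on each side of the summit (default 100, giving
#'   200 bp peaks).
#' @return data.frame with columns `chrom`, `start`, `end`, `summit`.
#' @export
#' @examples
#' extend_summits(data.frame(chrom = "chr1", pos = 1000),
#'                c(chr1 = 1e6))
extend_summits <- function(summits, chrom_sizes, flank = 100L) {
  stopifnot(is.data.frame(summits), all(c("chrom", "pos") %in% names(summits)))
  unknown <- setdiff(unique(summits$chrom), names(chrom_sizes))
  if (length(unknown) > 0)
    .stopf("unknown chromosome(s): %s", paste(unknown, collapse = ", "))
  size <- unname(chrom_sizes[summits$chrom])
  if (any(summits$pos < 0 | summits$pos >= size))
    .stopf("summit position outside chromosome bounds")
  data.frame(
    chrom = summits$chrom,
    start = pmax(0, summits$pos - flank),
    end = pmin(size, summits$pos + flank),
    summit = summits$pos,
    stringsAsFactors = FALSE
  )
}

#' Merge overlapping peak intervals into a disjoint peak set
#'
#' Overlapping (book-ended intervals are kept separate) summit regions are
#' unioned into maximal disjoint intervals; each merged peak records its
#' member summits.  The result is the complete peak set used for counting.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `summit`.
#' @return data.frame with columns `peak_id`, `chrom`, `start`, `end`,
#'   `summit` (the member summit closest to the merged midpoint; midpoint
#'   itself when no summits were supplied) and `n_summits`.
#' @export
merge_peak_regions <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) {
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      summit = integer(), n_summits = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- .bed_to_gr(intervals)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 0L)
  # deterministic output order regardless of input chromosome order
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red))
  red <- red[ord]
  revmap <- S4Vectors::mcols(red)$revmap
  start0 <- GenomicRanges::start(red) - 1L
  end0 <- GenomicRanges::end(red)
  mid <- (start0 + end0) %/% 2L
  has_summit <- "summit" %in% names(intervals)
  summit <- vapply(seq_along(red), function(i) {
    if (!has_summit) return(as.numeric(mid[i]))
    s <- intervals$summit[revmap[[i]]]
    as.numeric(s[which.min(abs(s - mid[i]))])
  }, numeric(1))
  data.frame(
    peak_id = sprintf("peak_%05d", seq_along(red)),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = start0,
    end = end0,
    summit = summit,
    n_summits = lengths(revmap),
    stringsAsFactors = FALSE
  )
}

#' Promoter windows of gene models
#'
#' The promoter window spans -1000/+100 bp around the first TSS in
#' transcription orientation: on the + strand the genomic interval
#' `[tss - 1000, tss + 101)`, on the - strand `[tss - 100, tss + 1001)`,
#' clamped at zero.
#'
#' @param genes data.frame of gene models with columns `gene_id`, `chrom`,
#'   `strand`, `tss`.
#' @param upstream,downstream window extent in transcription orientation.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_windows <- function(genes, upstream = 1000L, downstream = 100L) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream + 1L, genes$tss + upstream + 1L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0L, as.integer(start)), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Classify peaks as promoter or non-promoter elements
#'
#' A peak is a promoter element when it overlaps (default) or has its
#' summit inside any gene's strand-aware -1000/+100 TSS window; otherwise
#' it is a non-promoter (NP) element.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` and, for
#'   `mode = "summit"`, `summit`.
#' @param genes gene-model data.frame (see [promoter_windows()]).
#' @param mode `"overlap"` (any overlap with the window) or `"summit"`
#'   (summit contained in the window).
#' @return character vector, one of `"promoter"`/`"non_promoter"` per peak.
#' @export
classify_peaks <- function(peaks, genes, mode = c("overlap", "summit")) {
  mode <- match.arg(mode)
  win <- promoter_windows(genes)
  if (mode == "summit") {
    query <- .bed_to_gr(data.frame(chrom = peaks$chrom, start = peaks$summit,
                                   end = peaks$summit + 1L))
  } else {
    query <- .bed_to_gr(peaks)
  }
  hits <- IRanges::overlapsAny(query, .bed_to_gr(win),
                                     ignore.strand = TRUE)
  ifelse(hits, "promoter", "non_promoter")
}

#' Distance from a peak to a gene body
#'
#' Returns 0 with `in_gene_body = TRUE` when the peak interval overlaps the
#' gene body; otherwise the bp gap between nearest edges.  Peak and gene
#' must share a chromosome.
#'
#' @param peak_start,peak_end peak interval (0-based half-open).
#' @param gene_start,gene_end gene body interval.
#' @param peak_chrom,gene_chrom chromosome labels (vectors recycled).
#' @return data.frame with columns `distance` and `in_gene_body`.
#' @export
distance_to_gene_body <- function(peak_start, peak_end, gene_start, gene_end,
                                  peak_chrom = NULL, gene_chrom = NULL) {
  if (!is.null(peak_chrom) && !is.null(gene_chrom) &&
      any(peak_chrom != gene_chrom))
    .stopf("distance_to_gene_body: peak and gene on different chromosomes")
  gap <- pmax(gene_start - peak_end, peak_start - gene_end, 0)
  overlap <- peak_start < gene_end & gene_start < peak_end
  data.frame(distance = gap, in_gene_body = overlap)
}

#' Assign a peak summit to exon, intron or outside a gene
#'
#' Classification is by summit position: exonic when the summit falls in an
#' exon, intronic when inside the gene body but in no exon, outside
#' otherwise.
#'
#' @param summit summit coordinate(s), 0-based.
#' @param gene one row of a gene-model data.frame (`start`, `end`).
#' @param exons data.frame of that gene's exons (`start`, `end`).
#' @return character vector in `{"exonic", "intronic", "outside"}`.
#' @export
assign_exon_intron <- function(summit, gene, exons) {
  vapply(summit, function(s) {
    if (s < gene$start || s >= gene$end) return("outside")
    inside_exon <- any(s >= exons$start & s < exons$end)
    if (inside_exon) "exonic" else "intronic"
  }, character(1))
}

#' Containment of intervals in contact domains
#'
#' TRUE iff the interval is fully contained in at least one contact domain
#' (partial overlap does not count).
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param domains data.frame with `chrom`, `start`, `end`.
#' @return logical vector, one flag per interval.
#' @export
contact_domain_containment <- function(intervals, domains) {
  if (nrow(domains) == 0) return(rep(FALSE, nrow(intervals)))
  hits <- GenomicRanges::findOverlaps(.bed_to_gr(intervals),
                                      .bed_to_gr(domains),
                                      type = "within", ignore.strand = TRUE)
  seq_len(nrow(intervals)) %in% S4Vectors::queryHits(hits)
}
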