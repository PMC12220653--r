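# Genome-architecture metrics: assembly length statistics (N50,
# quartiles), GC content, intergenic distances with overlap exclusion,
# and Spearman correlation of metrics against mis-annotation counts.

#' N50 of a set of sequence lengths
#'
#' Length of the shortest sequence in the smallest prefix of the
#' descending-sorted lengths whose cumulative sum reaches half the total.
#'
#' @param lengths Positive integer vector.
#' @return The N50 in bases.
#' @export
calc_n50 <- function(lengths) {
  if (!length(lengths) || any(lengths <= 0))
    cs_data_error("calc_n50: lengths must be a non-empty positive vector")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Assembly length statistics
#'
#' @param genome A [Biostrings::DNAStringSet] or a numeric vector of
#'   sequence lengths.
#' @return list: n_sequences, total_length, min_length, mean_length,
#'   max_length, q1, median, q3, n50.
#' @export
assembly_stats <- function(genome) {
  lens <- if (is.numeric(genome)) genome else Biostrings::width(genome)
  if (!length(lens)) cs_data_error("assembly_stats: empty genome")
  q <- quantile(lens, c(0.25, 0.5, 0.75), names = FALSE)
  list(n_sequences = length(lens), total_length = sum(lens),
       min_length = min(lens), mean_length = mean(lens),
       max_length = max(lens), q1 = q[1], median = q[2], q3 = q[3],
       n50 = calc_n50(lens))
}

#' Mean GC content of a genome
#'
#' Per-sequence GC% is (G+C)/(A+C+G+T) x 100 with ambiguous bases
#' excluded from the denominator; sequences with no unambiguous base are
#' excluded with a warning. By default the per-sequence values are
#' averaged without length weighting (mirroring per-sequence tabulation
#' tools); `pooled = TRUE` instead computes GC over all bases at once.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param pooled Pool bases across sequences instead of averaging
#'   per-sequence percentages.
#' @return GC percentage in \[0, 100\].
#' @export
mean_gc <- function(genome, pooled = FALSE) {
  freq <- letterFrequency(genome, c("A", "C", "G", "T"))
  tot <- rowSums(freq)
  gc <- rowSums(freq[, c("C", "G"), drop = FALSE])
  if (any(tot == 0)) {
    warning(sprintf("%d sequence(s) with no unambiguous base excluded from GC",
                    sum(tot == 0)), call. = FALSE)
    gc <- gc[tot > 0]; tot <- tot[tot > 0]
  }
  if (!length(tot)) cs_data_error("mean_gc: no sequence with unambiguous bases")
  if (pooled) 100 * sum(gc) / sum(tot) else mean(100 * gc / tot)
}

#' Intergenic distances with overlap exclusion
#'
#' Genes whose span overlaps any other gene's span (any strand, >= 1
#' shared base) are excluded first; the remaining genes are sorted by
#' start within each sequence and one distance is reported per adjacent
#' pair: `next.start - prev.end` in 0-based half-open coordinates, i.e.
#' the number of bases strictly between the two genes (0 for abutting
#' genes). Distances are strand-agnostic.
#'
#' @param anno An [annotation_set()].
#' @return list(distances = integer vector, n_genes, n_excluded,
#'   prop_overlapping, mean_intergenic, median_intergenic).
#' @export
intergenic_distances <- function(anno) {
  g <- as.data.table(anno$genes)
  n <- nrow(g)
  if (!n)
    return(list(distances = integer(), n_genes = 0L, n_excluded = 0L,
                prop_overlapping = NA_real_, mean_intergenic = NA_real_,
                median_intergenic = NA_real_))
  setorder(g, seq_id, start, end)
  # overlap with any other gene on the same sequence (half-open spans)
  overlapping <- logical(n)
  for (sid in unique(g$seq_id)) {
    idx <- which(g$seq_id == sid)
    if (length(idx) < 2L) next
    ir <- IRanges(g$start[idx] + 1L, g$end[idx])
    ov <- findOverlaps(ir, ir)
    hit <- queryHits(ov) != subjectHits(ov)
    overlapping[idx[unique(queryHits(ov)[hit])]] <- TRUE
  }
  kept <- g[!overlapping]
  dists <- kept[, if (.N >= 2L) .(d = start[-1L] - end[-.N]) else NULL, by = seq_id]$d
  dists <- as.integer(if (is.null(dists)) integer() else dists)
  list(distances = dists, n_genes = n, n_excluded = sum(overlapping),
       prop_overlapping = sum(overlapping) / n,
       mean_intergenic = if (length(dists)) mean(dists) else NA_real_,
       median_intergenic = if (length(dists)) median(dists) else NA_real_)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midrank-averaged values, via
#' `stats::cor(method = "spearman")`, with explicit guards for the
#' degenerate inputs the correlation matrix must reject.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Coefficient in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) cs_data_error("spearman_cor: unequal lengths")
  if (length(x) < 3L) cs_data_error("spearman_cor: need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    cs_data_error("spearman_cor: constant vector has no rank correlation")
  cor(x, y, method = "spearman")
}

#' Full genome statistics for one assembly + annotation
#'
#' Combines [assembly_stats()], [mean_gc()] and [intergenic_distances()]
#' into the metric row used by [correlation_matrix()].
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param anno An [annotation_set()].
#' @return One-row data.table of the metrics.
#' @export
genome_stats <- function(genome, anno) {
  a <- assembly_stats(genome)
  ig <- intergenic_distances(anno)
  data.table(n_sequences = a$n_sequences, total_length = a$total_length,
             min_length = a$min_length, mean_length = a$mean_length,
             max_length = a$max_length, q1 = a$q1, median_length = a$median,
             q3 = a$q3, n50 = a$n50, mean_gc = mean_gc(genome),
             mean_intergenic = ig$mean_intergenic,
             median_intergenic = ig$median_intergenic,
             prop_overlapping_genes = ig$prop_overlapping)
}

#' Spearman correlation matrix of genome metrics
#'
#' @param stats data.frame with one row per genome and numeric metric
#'   columns (typically [genome_stats()] rows plus a mis-annotation
#'   count column). At least 3 genomes are required; constant columns are
#'   dropped with a warning.
#' @return Symmetric matrix of Spearman coefficients with unit diagonal.
#' @export
correlation_matrix <- function(stats) {
  m <- as.matrix(as.data.frame(stats))
  if (!is.numeric(m)) cs_data_error("correlation_matrix: non-numeric columns present")
  if (nrow(m) < 3L) cs_data_error("correlation_matrix: need at least 3 genomes")
  const <- apply(m, 2L, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(m)[const], collapse = ", ")), call. = FALSE)
    m <- m[, !const, drop = FALSE]
  }
  r <- cor(m, method = "spearman")
  diag(r) <- 1
  r
}
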