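# Reference <-> alternate gene correspondence. Links are formed from
# same-strand CDS-footprint overlap (>= 1 shared base); full gene spans are
# deliberately not used because the audit concerns coding regions, and no
# minimum overlap fraction is imposed because a chimera component may
# overlap an alternate model only partially.

# Union of CDS intervals per gene: data.table(gene_id, seq_id, strand,
# start, end) with 0-based half-open, merged intervals.
cds_footprint <- function(anno) {
  cds <- merge(anno$cds, anno$transcripts, by = "transcript_id")
  cds <- merge(cds, anno$genes[, .(gene_id, seq_id, strand)], by = "gene_id")
  if (!nrow(cds))
    return(data.table(gene_id = character(), seq_id = character(),
                      strand = character(), start = integer(), end = integer()))
  setorder(cds, gene_id, start, end)
  cds[, grp := cumsum(start > shift(cummax(end), fill = -1L)), by = gene_id]
  cds[, .(seq_id = seq_id[1L], strand = strand[1L],
          start = min(start), end = max(end)), by = .(gene_id, grp)][, grp := NULL][]
}

#' Link reference genes to overlapping alternate genes
#'
#' For every reference gene, finds the alternate-annotation genes whose
#' CDS footprint overlaps the reference gene's CDS footprint on the same
#' strand by at least one base. Reference genes with no link are omitted
#' (their count is logged); an alternate gene may participate in several
#' links. This plays the role of an annotation-comparison tool's
#' transcript matching, reduced to the gene-level mapping the filter
#' cascade needs.
#'
#' @param ref,alt Longest-isoform [annotation_set()]s.
#' @return data.table of class `gene_links` with one row per (reference,
#'   alternate) pair: ref_gene_id, alt_gene_id, overlap_bases, alt_start;
#'   within a reference gene, rows are ordered by alternate gene start.
#' @export
link_annotations <- function(ref, alt) {
  fr <- cds_footprint(ref)
  fa <- cds_footprint(alt)
  empty <- data.table(ref_gene_id = character(), alt_gene_id = character(),
                      overlap_bases = integer(), alt_start = integer())
  if (!nrow(fr) || !nrow(fa)) {
    setattr(empty, "class", c("gene_links", class(empty)))
    return(empty)
  }
  # 1-based inclusive coordinates for foverlaps; half-open abutting
  # intervals then share no row.
  fr1 <- copy(fr)[, `:=`(s = start + 1L, e = end)]
  fa1 <- copy(fa)[, `:=`(s = start + 1L, e = end)]
  setkey(fa1, seq_id, strand, s, e)
  ov <- foverlaps(fr1, fa1, by.x = c("seq_id", "strand", "s", "e"), nomatch = NULL)
  if (!nrow(ov)) {
    cs_log(sprintf("link_annotations: %d reference gene(s) with no alternate link",
                   length(unique(fr$gene_id))))
    setattr(empty, "class", c("gene_links", class(empty)))
    return(empty)
  }
  ov[, shared := pmin(e, i.e) - pmax(s, i.s) + 1L]
  pairs <- ov[, .(overlap_bases = sum(shared)), by = .(ref_gene_id = i.gene_id,
                                                       alt_gene_id = gene_id)]
  alt_starts <- alt$genes[, .(alt_gene_id = gene_id, alt_start = start)]
  pairs <- merge(pairs, alt_starts, by = "alt_gene_id")
  setorder(pairs, ref_gene_id, alt_start, alt_gene_id)
  setcolorder(pairs, c("ref_gene_id", "alt_gene_id", "overlap_bases", "alt_start"))
  n_unlinked <- length(unique(fr$gene_id)) - length(unique(pairs$ref_gene_id))
  if (n_unlinked > 0)
    cs_log(sprintf("link_annotations: %d reference gene(s) with no alternate link",
                   n_unlinked))
  setattr(pairs, "class", c("gene_links", class(pairs)))
  pairs[]
}

#' Read an externally produced linking table
#'
#' For users who computed the reference/alternate gene correspondence with
#' an external tool: a headered TSV with columns `ref_gene_id` and
#' `alt_gene_id` substitutes for [link_annotations()].
#'
#' @param path Path to the TSV.
#' @return A `gene_links` data.table (overlap_bases is `NA` for imported links).
#' @export
read_gene_links <- function(path) {
  lk <- fread(path, sep = "\t", header = TRUE)
  if (!all(c("ref_gene_id", "alt_gene_id") %in% names(lk)))
    cs_data_error("link TSV must have columns ref_gene_id, alt_gene_id")
  lk <- lk[, .(ref_gene_id = as.character(ref_gene_id),
               alt_gene_id = as.character(alt_gene_id),
               overlap_bases = NA_integer_, alt_start = NA_integer_)]
  setattr(lk, "class", c("gene_links", class(lk)))
  lk[]
}
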