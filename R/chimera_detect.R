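# The chimera filter cascade. A reference gene is a candidate chimeric
# mis-annotation when (1) its own hits against a trusted protein database
# show median query coverage below 60% while the hits of its linked
# alternate gene model(s), pooled, show median query coverage above 70%;
# (2) the alternate models' database targets are a subset of the reference
# gene's targets; and (3) the reference gene's hit coordinates, shrunk to
# suppress alignment-boundary noise, form at least two distinct clusters
# along the protein while the unshrunk hits cover more than half of it.

#' Filter configuration for the chimera scan
#'
#' Thresholds follow the expected signature of a chimera of two
#' similar-sized genes: each component alignment covers about 50% of the
#' fused protein, with a 10% buffer for size variation, giving the <60%
#' reference-side cutoff; the alternate side must exceed 70% to ensure the
#' split models match known proteins strongly. All coverage comparisons
#' are strict inequalities.
#'
#' @param ref_median_cov_max Reference gene's median query coverage must be
#'   strictly below this fraction (default 0.60).
#' @param alt_median_cov_min Pooled alternate median query coverage must be
#'   strictly above this fraction (default 0.70).
#' @param shrink_fraction Total fraction of each hit interval removed
#'   before clustering, split evenly between the two ends (default 0.10).
#' @param min_clusters Minimum number of distinct hit clusters for
#'   retention (default 2).
#' @param min_total_query_cov Union of unshrunk hit intervals must cover
#'   strictly more than this fraction of the protein (default 0.50).
#' @param max_e_value Hits above this e-value are discarded before the
#'   cascade (default 1e-5; permissive, since the detection search itself
#'   is run at high sensitivity).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(ref_median_cov_max = 0.60, alt_median_cov_min = 0.70,
                          shrink_fraction = 0.10, min_clusters = 2L,
                          min_total_query_cov = 0.50, max_e_value = 1e-5) {
  cfg <- list(ref_median_cov_max = ref_median_cov_max,
              alt_median_cov_min = alt_median_cov_min,
              shrink_fraction = shrink_fraction,
              min_clusters = as.integer(min_clusters),
              min_total_query_cov = min_total_query_cov,
              max_e_value = max_e_value)
  fr <- c(cfg$ref_median_cov_max, cfg$alt_median_cov_min, cfg$min_total_query_cov)
  if (any(fr <= 0 | fr > 1) || cfg$shrink_fraction < 0 || cfg$shrink_fraction >= 1)
    cs_usage_error("filter_config: coverage fractions must lie in (0,1]")
  if (cfg$min_clusters < 1L) cs_usage_error("filter_config: min_clusters must be >= 1")
  structure(cfg, class = "filter_config")
}

#' Coverage filter (reference low, alternate high)
#'
#' @param ref_hits Hits of the reference gene's protein.
#' @param alt_hits_pooled Pooled hits of all linked alternate genes.
#' @param cfg A [filter_config()].
#' @return list(pass, ref_median_cov, alt_pooled_median_cov); genes with no
#'   reference or no alternate hits fail with `NA` for the missing median.
#' @export
coverage_filter <- function(ref_hits, alt_hits_pooled, cfg = filter_config()) {
  if (!nrow(ref_hits) || !nrow(alt_hits_pooled))
    return(list(pass = FALSE,
                ref_median_cov = if (nrow(ref_hits)) median(ref_hits$q_cov) else NA_real_,
                alt_pooled_median_cov = if (nrow(alt_hits_pooled)) median(alt_hits_pooled$q_cov) else NA_real_))
  rm <- median(ref_hits$q_cov)
  am <- median(alt_hits_pooled$q_cov)
  list(pass = rm < cfg$ref_median_cov_max && am > cfg$alt_median_cov_min,
       ref_median_cov = rm, alt_pooled_median_cov = am)
}

#' Subset filter on database targets
#'
#' Retains a gene only when the set of database targets hit by its
#' alternate models is a subset of the targets hit by the reference gene
#' -- evidence that the split models re-partition the same homology rather
#' than picking up unrelated proteins. An empty alternate target set fails.
#'
#' @param ref_hits,alt_hits_pooled Hit tables as in [coverage_filter()].
#' @return TRUE/FALSE.
#' @export
subset_filter <- function(ref_hits, alt_hits_pooled) {
  at <- unique(alt_hits_pooled$target_id)
  if (!length(at)) return(FALSE)
  all(at %in% unique(ref_hits$target_id))
}

#' Shrink hit intervals symmetrically
#'
#' Removes `floor(L * shrink_fraction / 2)` residues from each end of each
#' 1-based inclusive interval of length `L`, damping spurious cluster
#' merges caused by slightly overlapping alignment boundaries. An interval
#' that would vanish collapses to its single midpoint residue.
#'
#' @param start,end Integer vectors of interval ends (1-based inclusive).
#' @param shrink_fraction Total fraction removed (default 0.10).
#' @return data.table(start, end) of the shrunk intervals.
#' @export
shrink_interval <- function(start, end, shrink_fraction = 0.10) {
  L <- end - start + 1L
  d <- floor(L * shrink_fraction / 2)
  ns <- start + d
  ne <- end - d
  collapse <- ns > ne
  mid <- (start + end) %/% 2L
  ns[collapse] <- mid[collapse]
  ne[collapse] <- mid[collapse]
  data.table(start = as.integer(ns), end = as.integer(ne))
}

#' Cluster intervals by transitive overlap
#'
#' Two intervals belong to one cluster iff they are connected by a chain
#' of pairwise-overlapping intervals (>= 1 shared residue in closed
#' coordinates); abutting intervals such as `[1,10]` and `[11,20]` do not
#' merge.
#'
#' @param start,end Integer vectors (1-based inclusive), same query.
#' @return list(clusters = data.table(cluster, span_start, span_end,
#'   n_intervals) sorted by span start, membership = integer vector
#'   assigning each input interval to a cluster).
#' @export
cluster_intervals <- function(start, end) {
  if (!length(start))
    return(list(clusters = data.table(cluster = integer(), span_start = integer(),
                                      span_end = integer(), n_intervals = integer()),
                membership = integer()))
  ir <- IRanges(start = start, end = end)
  red <- reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- mcols(red)$revmap
  membership <- integer(length(start))
  for (i in seq_along(revmap)) membership[revmap[[i]]] <- i
  clusters <- data.table(cluster = seq_along(red),
                         span_start = IRanges::start(red),
                         span_end = IRanges::end(red),
                         n_intervals = lengths(revmap))
  setorder(clusters, span_start)
  list(clusters = clusters, membership = membership)
}

#' Spatial clustering filter
#'
#' Clusters the shrunk hit intervals of a reference gene; the gene passes
#' when at least `min_clusters` distinct clusters exist and the union of
#' the original (unshrunk) hit intervals covers strictly more than
#' `min_total_query_cov` of the protein. Shrinking is purely a clustering
#' de-noising step, so total coverage uses the unshrunk intervals.
#'
#' @param ref_hits Hit table of the reference gene.
#' @param ref_protein_len Length of the reference protein (residues).
#' @param cfg A [filter_config()].
#' @return list(pass, cluster_count, total_query_cov).
#' @export
clustering_filter <- function(ref_hits, ref_protein_len, cfg = filter_config()) {
  if (!nrow(ref_hits))
    return(list(pass = FALSE, cluster_count = 0L, total_query_cov = 0))
  shr <- shrink_interval(ref_hits$q_start, ref_hits$q_end, cfg$shrink_fraction)
  cl <- cluster_intervals(shr$start, shr$end)
  union_w <- sum(width(reduce(IRanges(ref_hits$q_start, ref_hits$q_end))))
  cov <- union_w / ref_protein_len
  list(pass = nrow(cl$clusters) >= cfg$min_clusters && cov > cfg$min_total_query_cov,
       cluster_count = nrow(cl$clusters), total_query_cov = cov)
}

#' Scan a reference annotation for candidate chimeric genes
#'
#' Applies the filter cascade (coverage -> subset -> clustering) to every
#' reference gene with at least one database hit. `failed_filter` records
#' the first failed stage; genes lacking reference hits are skipped and
#' only counted in the run summary attribute.
#'
#' @param ref,alt Longest-isoform [annotation_set()]s.
#' @param ref_hits,alt_hits [hit_table()]s whose query IDs are the protein
#'   IDs emitted by [extract_proteins()] (equal to gene IDs).
#' @param links Optional `gene_links` table; computed with
#'   [link_annotations()] when `NULL`.
#' @param cfg A [filter_config()].
#' @return data.table of class `chimera_calls`, one row per assessed
#'   reference gene: ref_gene_id, seq_id, strand, n_ref_hits,
#'   ref_median_cov, linked_alt_genes, alt_pooled_median_cov, subset_ok,
#'   cluster_count, total_query_cov, verdict, failed_filter. A `summary`
#'   attribute carries the assessed/skipped/candidate counts.
#' @export
scan_chimeras <- function(ref, alt, ref_hits, alt_hits, links = NULL,
                          cfg = filter_config()) {
  stopifnot(inherits(ref, "AnnotationSet"), inherits(alt, "AnnotationSet"))
  if (is.null(links)) links <- link_annotations(ref, alt)
  stray <- setdiff(unique(ref_hits$query_id), ref$genes$gene_id)
  if (length(stray))
    cs_data_error(sprintf("hit query IDs absent from reference annotation: %s",
                          paste(head(stray, 5), collapse = ", ")))
  stray_a <- setdiff(unique(alt_hits$query_id), alt$genes$gene_id)
  if (length(stray_a))
    cs_data_error(sprintf("hit query IDs absent from alternate annotation: %s",
                          paste(head(stray_a, 5), collapse = ", ")))

  ref_hits <- ref_hits[e_value <= cfg$max_e_value]
  alt_hits <- alt_hits[e_value <= cfg$max_e_value]

  assessed_ids <- intersect(ref$genes$gene_id, unique(ref_hits$query_id))
  n_skipped <- nrow(ref$genes) - length(assessed_ids)
  rows <- vector("list", length(assessed_ids))
  for (i in seq_along(assessed_ids)) {
    gid <- assessed_ids[i]
    g <- ref$genes[gene_id == gid]
    rh <- ref_hits[query_id == gid]
    alt_ids <- links[ref_gene_id == gid, alt_gene_id]
    ah <- alt_hits[query_id %in% alt_ids]
    cov <- coverage_filter(rh, ah, cfg)
    sub_ok <- subset_filter(rh, ah)
    clu <- clustering_filter(rh, rh$q_len[1L], cfg)
    failed <- if (!cov$pass) "coverage" else if (!sub_ok) "subset"
              else if (!clu$pass) "clustering" else "none"
    rows[[i]] <- data.table(
      ref_gene_id = gid, seq_id = g$seq_id, strand = g$strand,
      n_ref_hits = nrow(rh), ref_median_cov = cov$ref_median_cov,
      linked_alt_genes = paste(alt_ids, collapse = ","),
      alt_pooled_median_cov = cov$alt_pooled_median_cov,
      subset_ok = sub_ok, cluster_count = clu$cluster_count,
      total_query_cov = clu$total_query_cov,
      verdict = if (failed == "none") "candidate" else "rejected",
      failed_filter = failed)
  }
  calls <- rbindlist(rows)
  if (!nrow(calls))
    calls <- data.table(ref_gene_id = character(), seq_id = character(),
                        strand = character(), n_ref_hits = integer(),
                        ref_median_cov = numeric(), linked_alt_genes = character(),
                        alt_pooled_median_cov = numeric(), subset_ok = logical(),
                        cluster_count = integer(), total_query_cov = numeric(),
                        verdict = character(), failed_filter = character())
  rej <- table(factor(calls$failed_filter[calls$verdict == "rejected"],
                      levels = c("coverage", "subset", "clustering")))
  setattr(calls, "summary",
          list(n_genes = nrow(ref$genes), assessed = nrow(calls),
               skipped_no_hits = n_skipped,
               candidates = sum(calls$verdict == "candidate"),
               rejected = as.list(rej)))
  setattr(calls, "class", c("chimera_calls", class(calls)))
  calls[]
}

#' Write chimera calls as TSV
#'
#' @param calls Result of [scan_chimeras()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chimera_calls <- function(calls, path) {
  out <- as.data.table(calls)[, .(ref_gene_id, seq_id, strand, n_ref_hits,
                                  ref_median_cov, linked_alt_genes,
                                  alt_pooled_median_cov, subset_ok,
                                  cluster_count, total_query_cov, verdict,
                                  failed_filter)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
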