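# Database-level screens for the chimera signature: a 2D query/target
# coverage histogram over filtered hits (a fused gene hit by its components
# sits at target coverage ~1 and query coverage ~1/k), and a per-hit log2
# length-ratio audit of a query protein against a database.

#' Screen filter for database-level hit tables
#'
#' Defaults mirror a high-sensitivity database-vs-database search
#' post-filtered for confident alignments: e-value at most 1e-10,
#' alignment length at least 100 residues, bit score strictly above 200,
#' and (optionally) a case-insensitive substring that the query's FASTA
#' header must contain -- "uncharacterized protein" selects the poorly
#' annotated entries where chimeras hide.
#'
#' @param max_e_value Maximum e-value (inclusive; default 1e-10).
#' @param min_aln_len Minimum alignment length (inclusive; default 100).
#' @param min_bit_score Bit score must be strictly greater (default 200).
#' @param name_pattern Case-insensitive substring required in the query
#'   header, or `NULL` to disable (default "uncharacterized protein").
#' @return A list of class `screen_filter`.
#' @export
screen_filter <- function(max_e_value = 1e-10, min_aln_len = 100,
                          min_bit_score = 200,
                          name_pattern = "uncharacterized protein") {
  if (max_e_value <= 0 || min_aln_len <= 0 || min_bit_score <= 0)
    cs_usage_error("screen_filter: thresholds must be positive")
  structure(list(max_e_value = max_e_value, min_aln_len = min_aln_len,
                 min_bit_score = min_bit_score, name_pattern = name_pattern),
            class = "screen_filter")
}

#' Apply the screen filter to a hit table
#'
#' @param hits A [hit_table()].
#' @param headers Named character vector mapping query IDs to their full
#'   FASTA header lines; required when the filter carries a
#'   `name_pattern`. Hits whose query lacks a header are dropped with a
#'   warning.
#' @param f A [screen_filter()].
#' @return The filtered [hit_table()] (idempotent).
#' @export
apply_screen_filter <- function(hits, headers = NULL, f = screen_filter()) {
  h <- hits[e_value <= f$max_e_value & aln_len >= f$min_aln_len &
              bit_score > f$min_bit_score]
  if (!is.null(f$name_pattern)) {
    if (is.null(headers))
      cs_usage_error("apply_screen_filter: name_pattern set but no headers supplied")
    hd <- headers[h$query_id]
    missing_hdr <- is.na(hd)
    if (any(missing_hdr)) {
      warning(sprintf("%d hit(s) dropped: query header unavailable for name filtering",
                      sum(missing_hdr)), call. = FALSE)
      h <- h[!missing_hdr]
      hd <- hd[!missing_hdr]
    }
    h <- h[grepl(f$name_pattern, hd, fixed = FALSE, ignore.case = TRUE)]
  }
  setattr(h, "class", c("HitTable", setdiff(class(h), "HitTable")))
  h[]
}

#' Query/target coverage signature of a hit table
#'
#' Bins each hit's (query coverage, target coverage) pair on a square
#' grid over (0, 1] and summarises per-query mean coverages. Self-hits
#' (query equal to target) carry no mis-annotation signal and are
#' excluded.
#'
#' @param hits A [hit_table()] (already screen-filtered, typically).
#' @param n_bins Number of equal-width bins per axis (default 50).
#' @return list(histogram = data.table(bin_q, bin_t, count) of non-empty
#'   bins, per_query = data.table(query_id, n_hits, mean_q_cov,
#'   mean_t_cov), n_hits, n_bins). Histogram counts sum to `n_hits`.
#' @export
coverage_signature <- function(hits, n_bins = 50L) {
  h <- hits[query_id != target_id]
  if (!nrow(h))
    return(list(histogram = data.table(bin_q = integer(), bin_t = integer(),
                                       count = integer()),
                per_query = data.table(query_id = character(), n_hits = integer(),
                                       mean_q_cov = numeric(), mean_t_cov = numeric()),
                n_hits = 0L, n_bins = as.integer(n_bins)))
  bin_of <- function(x) pmin(pmax(ceiling(x * n_bins), 1L), as.integer(n_bins))
  hist <- h[, .(count = .N), by = .(bin_q = bin_of(q_cov), bin_t = bin_of(t_cov))]
  setorder(hist, bin_q, bin_t)
  per_query <- h[, .(n_hits = .N, mean_q_cov = mean(q_cov),
                     mean_t_cov = mean(t_cov)), by = query_id]
  setorder(per_query, query_id)
  list(histogram = hist, per_query = per_query, n_hits = nrow(h),
       n_bins = as.integer(n_bins))
}

#' Length-ratio audit of queries against a database
#'
#' For every high-confidence hit (e-value strictly below `max_e_value`,
#' self-hits excluded) reports `log2(q_len / t_len)`: a chimeric query
#' composed of k similar-length genes hit by its single-gene homologs
#' shows ratios near log2(k). Optional corrected lengths (e.g. the
#' lengths of split alternate models) are reported as companion markers
#' `log2(q_len / corrected_length)`.
#'
#' @param hits A [hit_table()].
#' @param max_e_value Strict e-value cutoff (default 1e-30).
#' @param corrected_lengths Optional named integer vector, query_id ->
#'   corrected residue count.
#' @param bin_width Histogram bin width on the log2 axis (default 0.1).
#' @return list(ratios = data.table(query_id, target_id, q_len, t_len,
#'   log2_ratio), histogram = data.table(bin_lo, bin_hi, count),
#'   corrected = data.table(query_id, marker) or NULL).
#' @export
length_ratio_audit <- function(hits, max_e_value = 1e-30,
                               corrected_lengths = NULL, bin_width = 0.1) {
  h <- hits[e_value < max_e_value & query_id != target_id]
  ratios <- h[, .(query_id, target_id, q_len, t_len,
                  log2_ratio = log2(q_len / t_len))]
  if (nrow(ratios)) {
    lo <- floor(min(ratios$log2_ratio) / bin_width) * bin_width
    hi <- ceiling(max(ratios$log2_ratio) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    bins <- cut(ratios$log2_ratio, breaks = breaks, include.lowest = TRUE)
    tab <- table(bins)
    histogram <- data.table(bin_lo = head(breaks, -1L), bin_hi = tail(breaks, -1L),
                            count = as.integer(tab))
  } else {
    histogram <- data.table(bin_lo = numeric(), bin_hi = numeric(), count = integer())
  }
  corrected <- NULL
  if (!is.null(corrected_lengths)) {
    ql <- unique(ratios[, .(query_id, q_len)])
    ql <- ql[query_id %in% names(corrected_lengths)]
    corrected <- ql[, .(query_id,
                        marker = log2(q_len / unname(corrected_lengths[query_id])))]
  }
  list(ratios = ratios, histogram = histogram, corrected = corrected)
}
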