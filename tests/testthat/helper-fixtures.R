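# Shared fixture builders and independent brute-force oracles.

suppressMessages(library(data.table))

# Minimal hit table: one row per q_cov value, one shared query of length
# q_len, distinct targets fully covered. Extra fields overridable.
mk_hits <- function(q_covs, q_len = 1000L, query_id = "q1",
                    target_ids = sprintf("T%02d", seq_along(q_covs)),
                    e_value = 0, bit_score = 500, q_start = NULL) {
  spans <- as.integer(round(q_covs * q_len))
  if (is.null(q_start)) q_start <- rep(1L, length(q_covs))
  hit_table(data.table(
    query_id = query_id, target_id = target_ids, pident = 100,
    aln_len = spans, mismatch = 0L, gapopen = 0L,
    q_start = q_start, q_end = q_start + spans - 1L,
    t_start = 1L, t_end = spans, e_value = e_value, bit_score = bit_score,
    q_len = q_len, t_len = spans))
}

# Hit with explicit query-interval coordinates (for clustering tests).
mk_interval_hits <- function(starts, ends, q_len = 600L, query_id = "q1") {
  hit_table(data.table(
    query_id = query_id, target_id = sprintf("T%02d", seq_along(starts)),
    pident = 100, aln_len = ends - starts + 1L, mismatch = 0L, gapopen = 0L,
    q_start = as.integer(starts), q_end = as.integer(ends),
    t_start = 1L, t_end = ends - starts + 1L, e_value = 0, bit_score = 500,
    q_len = q_len, t_len = as.integer(ends - starts + 1L)))
}

# A tiny two-gene annotation written as GFF3 text (1-based inclusive).
write_tmp_gff3 <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

# Brute-force transitive-overlap clustering (label propagation), the
# independent oracle for cluster_intervals().
brute_clusters <- function(s, e) {
  n <- length(s)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && s[i] <= e[j] && s[j] <= e[i]) {
        m <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  spans <- data.table(comp = comp, s = s, e = e)[, .(span_start = min(s), span_end = max(e)),
                                                 by = comp]
  setorder(spans, span_start)
  list(count = length(unique(comp)), spans = spans[, .(span_start, span_end)])
}

# Brute-force N50: descending prefix scan.
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= sum(lengths) / 2) return(x)
  }
}

# Midrank Pearson, the independent route for Spearman.
midrank_pearson <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Deterministic random protein.
rand_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
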