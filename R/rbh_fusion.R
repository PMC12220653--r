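# Reciprocal best hits between two annotations' proteomes and the log2
# length-ratio classification of fusion / split gene-model differences.

rbh_categories <- c("2:1 split", "3:1 split", "4:1 split",
                    "1:2 fusion", "1:3 fusion", "1:4 fusion",
                    "1:1 match", "other")

# Closed log2-ratio intervals per category; ratios falling in the gaps are
# "other" (no snapping to the nearest interval).
rbh_intervals <- data.table(
  category = c("2:1 split", "3:1 split", "4:1 split",
               "1:2 fusion", "1:3 fusion", "1:4 fusion", "1:1 match"),
  lo = c(0.8, 1.4, 1.9, -1.2, -1.7, -2.1, -0.3),
  hi = c(1.2, 1.7, 2.1, -0.8, -1.4, -1.9, 0.3))

#' Classify a protein length ratio as split / fusion / match
#'
#' Computes `r = log2(len_q / len_t)` and assigns the category whose
#' closed interval contains it: 2:1 split for r in \[0.8, 1.2\], 3:1 split
#' \[1.4, 1.7\], 4:1 split \[1.9, 2.1\], 1:2 fusion \[-1.2, -0.8\],
#' 1:3 fusion \[-1.7, -1.4\], 1:4 fusion \[-2.1, -1.9\], 1:1 match
#' \[-0.3, 0.3\]; anything else is "other". Endpoints are inclusive.
#'
#' @param len_q,len_t Positive residue counts (vectorised).
#' @return Character vector of categories.
#' @export
classify_ratio <- function(len_q, len_t) {
  if (any(len_q < 1) || any(len_t < 1))
    cs_data_error("classify_ratio: lengths must be >= 1")
  classify_log2_ratio(log2(len_q / len_t))
}

#' @rdname classify_ratio
#' @param r log2 length ratio(s).
#' @export
classify_log2_ratio <- function(r) {
  out <- rep("other", length(r))
  for (i in seq_len(nrow(rbh_intervals)))
    out[r >= rbh_intervals$lo[i] & r <= rbh_intervals$hi[i]] <- rbh_intervals$category[i]
  out
}

# Best hit per query: maximal bit score, ties by smaller e-value then
# lexicographically smallest target ID.
best_hit_per_query <- function(hits) {
  h <- as.data.table(hits)
  if (!nrow(h))
    return(data.table(query_id = character(), target_id = character()))
  setorder(h, query_id, -bit_score, e_value, target_id)
  h[, .SD[1L], by = query_id][, .(query_id, target_id)]
}

#' Reciprocal best hits between two protein sets
#'
#' A pair (a, b) is emitted when b is a's best hit in the a-vs-b table and
#' a is b's best hit in the b-vs-a table. "Best" means highest bit score,
#' ties broken by smaller e-value then lexicographic target ID. Lengths
#' are taken from the tables' `q_len`/`t_len` columns unless supplied.
#'
#' @param hits_ab Hit table of annotation A's proteins vs annotation B's.
#' @param hits_ba Hit table of the reverse search.
#' @param lengths_a,lengths_b Optional named integer vectors overriding
#'   the lengths recorded in the hit tables.
#' @return data.table of class `rbh_pairs`: id_a, id_b, len_a, len_b,
#'   log2_ratio (log2(len_a / len_b)), category.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 lengths_a = NULL, lengths_b = NULL) {
  ba <- best_hit_per_query(hits_ab)
  bb <- best_hit_per_query(hits_ba)
  setnames(bb, c("query_id", "target_id"), c("target_id", "query_id"))
  pairs <- merge(ba, bb, by = c("query_id", "target_id"))
  setnames(pairs, c("query_id", "target_id"), c("id_a", "id_b"))
  if (is.null(lengths_a)) {
    la <- unique(as.data.table(hits_ab)[, .(id_a = query_id, len_a = q_len)])
  } else la <- data.table(id_a = names(lengths_a), len_a = unname(lengths_a))
  if (is.null(lengths_b)) {
    lb <- unique(as.data.table(hits_ab)[, .(id_b = target_id, len_b = t_len)])
  } else lb <- data.table(id_b = names(lengths_b), len_b = unname(lengths_b))
  pairs <- merge(merge(pairs, la, by = "id_a"), lb, by = "id_b")
  if (anyNA(pairs$len_a) || anyNA(pairs$len_b))
    cs_data_error("reciprocal_best_hits: missing protein lengths")
  pairs[, log2_ratio := log2(len_a / len_b)]
  pairs[, category := classify_log2_ratio(log2_ratio)]
  setorder(pairs, id_a)
  setcolorder(pairs, c("id_a", "id_b", "len_a", "len_b", "log2_ratio", "category"))
  setattr(pairs, "class", c("rbh_pairs", class(pairs)))
  pairs[]
}

#' Tabulate RBH categories
#'
#' @param pairs Result of [reciprocal_best_hits()].
#' @return data.table(category, n) covering all categories (zero-filled);
#'   counts sum to the number of pairs.
#' @export
tabulate_categories <- function(pairs) {
  tab <- table(factor(pairs$category, levels = rbh_categories))
  data.table(category = names(tab), n = as.integer(tab))
}
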