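# Homology hit tables in the BLAST/MMseqs2 tabular ("m8") dialects, query /
# target coverage arithmetic, and an exact-substring search oracle used to
# build idealized hit tables for simulated data.

m8_cols <- c("query_id", "target_id", "pident", "aln_len", "mismatch",
             "gapopen", "q_start", "q_end", "t_start", "t_end",
             "e_value", "bit_score")

#' Construct a hit table
#'
#' Validates coordinates and fills in `q_cov` / `t_cov` (aligned span over
#' full sequence length, 1-based inclusive arithmetic) when absent.
#'
#' @param hits data.frame with the 12 m8 columns plus `q_len`, `t_len`
#'   (and optionally precomputed `q_cov`, `t_cov`).
#' @return A `data.table` of class `HitTable`, input order preserved.
#' @export
hit_table <- function(hits) {
  h <- as.data.table(hits)
  needed <- c(m8_cols, "q_len", "t_len")
  miss <- setdiff(needed, names(h))
  if (length(miss))
    cs_data_error(paste("hit table missing columns:", paste(miss, collapse = ", ")))
  if (!"q_cov" %in% names(h)) h[, q_cov := (q_end - q_start + 1) / q_len]
  if (!"t_cov" %in% names(h)) h[, t_cov := (t_end - t_start + 1) / t_len]
  for (col in c("pident", "e_value", "bit_score", "q_cov", "t_cov"))
    set(h, j = col, value = as.numeric(h[[col]]))
  bad <- with(h, q_start < 1 | q_start > q_end | q_end > q_len |
                t_start < 1 | t_start > t_end | t_end > t_len)
  if (any(bad))
    cs_data_error(sprintf("%d hit(s) violate coordinate invariants", sum(bad)))
  setattr(h, "class", c("HitTable", class(h)))
  h[]
}

empty_hit_table <- function() {
  hit_table(data.table(query_id = character(), target_id = character(),
                       pident = numeric(), aln_len = integer(),
                       mismatch = integer(), gapopen = integer(),
                       q_start = integer(), q_end = integer(),
                       t_start = integer(), t_end = integer(),
                       e_value = numeric(), bit_score = numeric(),
                       q_len = integer(), t_len = integer()))
}

#' Read a tabular homology hit file
#'
#' Supports three tab-separated dialects: the 12 standard m8 columns
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), m8 extended with `qlen,tlen`, and m8 extended with
#' `qcov,tcov`. With `dialect = "auto"` a 14-column file is taken as the
#' coverage dialect when both extra columns lie in (0, 1], else as the
#' length dialect. The plain 12-column dialect requires sequence lengths,
#' either as named integer vectors or FASTA paths. Rows whose coordinates
#' fall outside `[1, len]` are rejected with their line numbers logged.
#'
#' @param path Path to the hit file (no header row).
#' @param dialect `"auto"`, `"m8"`, `"m8+len"` or `"m8+cov"`.
#' @param q_lengths,t_lengths Named integer vectors (id -> residues) or
#'   paths to protein FASTA files; required for the 12-column and
#'   coverage dialects.
#' @return A [hit_table()].
#' @export
read_hits <- function(path, dialect = c("auto", "m8", "m8+len", "m8+cov"),
                      q_lengths = NULL, t_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) cs_data_error(sprintf("hit file not found: %s", path))
  h <- fread(path, sep = "\t", header = FALSE)
  if (!nrow(h)) return(empty_hit_table())
  nc <- ncol(h)
  if (nc == 12L) {
    if (dialect %in% c("m8+len", "m8+cov"))
      cs_data_error(sprintf("dialect '%s' declared but file has 12 columns", dialect))
    dialect <- "m8"
  } else if (nc == 14L) {
    if (dialect == "m8")
      cs_data_error("dialect 'm8' declared but file has 14 columns")
    if (dialect == "auto") {
      extra_cov <- all(h[[13L]] > 0 & h[[13L]] <= 1) && all(h[[14L]] > 0 & h[[14L]] <= 1)
      dialect <- if (extra_cov) "m8+cov" else "m8+len"
    }
  } else cs_data_error(sprintf("expected 12 or 14 tab-separated columns, found %d", nc))

  setnames(h, 1:12, m8_cols)
  if (dialect == "m8+len") setnames(h, 13:14, c("q_len", "t_len"))
  if (dialect == "m8+cov") setnames(h, 13:14, c("q_cov", "t_cov"))
  if (dialect %in% c("m8", "m8+cov")) {
    resolve <- function(x, what) {
      if (is.null(x))
        cs_data_error(sprintf("%s lengths required for dialect '%s' (supply a FASTA or named vector)",
                              what, dialect))
      if (is.character(x) && length(x) == 1L && file.exists(x)) {
        p <- read_protein_fasta(x)
        x <- setNames(p$length, p$protein_id)
      }
      x
    }
    ql <- resolve(q_lengths, "query")
    tl <- resolve(t_lengths, "target")
    h[, q_len := unname(ql[query_id])]
    h[, t_len := unname(tl[target_id])]
    if (anyNA(h$q_len) || anyNA(h$t_len))
      cs_data_error("sequence length unavailable for some hit IDs")
  }
  ok <- with(h, q_start >= 1 & q_start <= q_end & q_end <= q_len &
               t_start >= 1 & t_start <= t_end & t_end <= t_len)
  if (any(!ok)) {
    cs_log(sprintf("read_hits: rejected %d row(s) with out-of-range coordinates (lines %s)",
                   sum(!ok), paste(which(!ok), collapse = ",")))
    h <- h[ok]
  }
  hit_table(h)
}

#' Write a hit table in an m8 dialect
#'
#' @param hits A [hit_table()].
#' @param path Output path.
#' @param dialect `"m8"`, `"m8+len"` or `"m8+cov"`.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, dialect = c("m8+len", "m8", "m8+cov")) {
  dialect <- match.arg(dialect)
  num <- function(x) sprintf("%.17g", x)
  base <- cbind(hits$query_id, hits$target_id, num(hits$pident), hits$aln_len,
                hits$mismatch, hits$gapopen, hits$q_start, hits$q_end,
                hits$t_start, hits$t_end, num(hits$e_value), num(hits$bit_score))
  extra <- switch(dialect,
                  "m8" = NULL,
                  "m8+len" = cbind(hits$q_len, hits$t_len),
                  "m8+cov" = cbind(num(hits$q_cov), num(hits$t_cov)))
  rows <- apply(cbind(base, extra), 1L, paste, collapse = "\t")
  writeLines(if (nrow(hits)) rows else character(), path)
  invisible(path)
}

#' Median query coverage of a set of hits
#'
#' The per-gene summary underlying the coverage filter: median of the
#' hits' query-coverage fractions (even counts average the two central
#' values).
#'
#' @param hits A [hit_table()] (or data.frame with a `q_cov` column); all
#'   hits are expected to share one query.
#' @return Median coverage fraction in (0, 1].
#' @export
median_query_coverage <- function(hits) {
  if (!nrow(hits))
    cs_data_error("median_query_coverage: empty hit list (no-hit genes must be handled by the caller)")
  if (length(unique(hits$query_id)) > 1L)
    cs_data_error("median_query_coverage: hits span multiple queries")
  median(hits$q_cov)
}

#' Exact-substring search oracle
#'
#' A deliberately simple stand-in for a homology search, used with
#' simulated proteins: it reports one hit per occurrence of a complete
#' target inside a query (and, when the target is longer, of the complete
#' query inside the target), with 100% identity, e-value 0 and bit score
#' 2 x alignment length. Simulated component proteins are constructed to
#' be mutually non-matching, so on such data the oracle reproduces the
#' ideal hit model exactly.
#'
#' @param queries,targets data.tables with `protein_id` and `sequence`
#'   columns (e.g. from [extract_proteins()] or [read_protein_fasta()]),
#'   or named character vectors.
#' @return A [hit_table()].
#' @export
oracle_search <- function(queries, targets) {
  as_named <- function(x) {
    if (is.character(x)) return(x)
    setNames(x$sequence, x$protein_id)
  }
  q <- as_named(queries); t <- as_named(targets)
  out <- list()
  for (qi in seq_along(q)) for (ti in seq_along(t)) {
    qs <- q[[qi]]; ts <- t[[ti]]
    if (nchar(ts) <= nchar(qs)) {
      pos <- gregexpr(ts, qs, fixed = TRUE)[[1]]
      if (pos[1] == -1L) next
      L <- nchar(ts)
      out[[length(out) + 1L]] <- data.table(
        query_id = names(q)[qi], target_id = names(t)[ti], pident = 100,
        aln_len = L, mismatch = 0L, gapopen = 0L,
        q_start = as.integer(pos), q_end = as.integer(pos) + L - 1L,
        t_start = 1L, t_end = L, e_value = 0, bit_score = 2 * L,
        q_len = nchar(qs), t_len = nchar(ts))
    } else {
      pos <- gregexpr(qs, ts, fixed = TRUE)[[1]]
      if (pos[1] == -1L) next
      L <- nchar(qs)
      out[[length(out) + 1L]] <- data.table(
        query_id = names(q)[qi], target_id = names(t)[ti], pident = 100,
        aln_len = L, mismatch = 0L, gapopen = 0L,
        q_start = 1L, q_end = L,
        t_start = as.integer(pos), t_end = as.integer(pos) + L - 1L,
        e_value = 0, bit_score = 2 * L, q_len = nchar(qs), t_len = nchar(ts))
    }
  }
  if (!length(out)) return(empty_hit_table())
  hit_table(rbindlist(out))
}
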