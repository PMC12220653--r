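# GFF3 / FASTA ingestion, longest-isoform selection and CDS translation.
#
# Internal coordinates are 0-based half-open throughout; GFF3 (1-based
# inclusive) is converted at the I/O boundary. An AnnotationSet holds three
# linked tables rather than nested objects so interval work stays vectorised.

#' Construct an annotation set
#'
#' An `AnnotationSet` bundles three `data.table`s: `genes` (gene_id, seq_id,
#' strand, start, end), `transcripts` (transcript_id, gene_id) and `cds`
#' (transcript_id, start, end, phase). All coordinates are 0-based half-open.
#'
#' @param genes,transcripts,cds data.tables with the columns above.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(genes, transcripts, cds) {
  genes <- as.data.table(genes)
  transcripts <- as.data.table(transcripts)
  cds <- as.data.table(cds)
  if (anyDuplicated(genes$gene_id))
    cs_structural_error("duplicate gene IDs in annotation")
  if (any(genes$start >= genes$end))
    cs_structural_error("gene with start >= end")
  if (!all(genes$strand %in% c("+", "-")))
    cs_structural_error("gene strand must be '+' or '-'")
  structure(list(genes = genes, transcripts = transcripts, cds = cds),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d genes, %d transcripts, %d CDS segments on %d sequence(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$cds),
              length(unique(x$genes$seq_id))))
  invisible(x)
}

# Decode GFF3 percent-escapes in attribute values.
gff3_unescape <- function(x) {
  needs <- grepl("%", x, fixed = TRUE)
  x[needs] <- vapply(x[needs], utils::URLdecode, character(1))
  x
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

# Parse one attribute column into a named character vector; errors carry the
# 1-based file line number.
parse_gff3_attributes <- function(attr, line_no) {
  parts <- strsplit(attr, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  eq <- regexpr("=", parts, fixed = TRUE)
  if (any(eq < 0))
    cs_parse_error(sprintf("malformed attribute (no '=') on line %d: '%s'",
                           line_no, parts[which(eq < 0)[1]]))
  setNames(gff3_unescape(substring(parts, eq + 1L)), substring(parts, 1L, eq - 1L))
}

#' Parse a GFF3 annotation file
#'
#' Reads gene / mRNA (or transcript) / CDS features linked through their
#' `ID` and `Parent` attributes. Coordinates are converted from GFF3
#' 1-based inclusive to internal 0-based half-open. Features on unknown
#' strand (`.`) are rejected; a CDS whose Parent cannot be resolved to a
#' transcript (and through it a gene) is a structural error.
#'
#' @param path Path to a GFF3 file.
#' @return An [annotation_set()].
#' @export
parse_gff3 <- function(path) {
  if (!file.exists(path)) cs_data_error(sprintf("GFF3 file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) lines <- head(lines, fasta_at[1] - 1L)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(annotation_set(
      data.table(gene_id = character(), seq_id = character(), strand = character(),
                 start = integer(), end = integer()),
      data.table(transcript_id = character(), gene_id = character()),
      data.table(transcript_id = character(), start = integer(), end = integer(),
                 phase = integer())))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    cs_parse_error(sprintf("expected 9 tab-separated columns on line %d, found %d",
                           line_no[which(nf != 9L)[1]], nf[which(nf != 9L)[1]]))
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  type <- m[, 3L]
  of_interest <- type %in% c("gene", "mRNA", "transcript", "CDS")
  m <- m[of_interest, , drop = FALSE]
  line_no <- line_no[of_interest]
  type <- type[of_interest]

  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(start1) | is.na(end1) | start1 > end1 | start1 < 1L
  if (any(bad))
    cs_parse_error(sprintf("invalid coordinates on line %d", line_no[which(bad)[1]]))
  strand <- m[, 7L]
  if (any(!strand %in% c("+", "-")))
    cs_parse_error(sprintf("unknown strand '%s' on line %d (only '+'/'-' supported)",
                           strand[which(!strand %in% c("+", "-"))[1]],
                           line_no[which(!strand %in% c("+", "-"))[1]]))

  attrs <- mapply(parse_gff3_attributes, m[, 9L], line_no, SIMPLIFY = FALSE)
  get_attr <- function(key) vapply(attrs, function(a) {
    v <- a[key]
    if (is.na(v)) NA_character_ else unname(v)
  }, character(1))
  ids <- get_attr("ID")
  parents <- get_attr("Parent")

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_cds <- type == "CDS"

  if (any(is_gene & is.na(ids)))
    cs_parse_error(sprintf("gene without ID attribute on line %d",
                           line_no[which(is_gene & is.na(ids))[1]]))
  if (any(is_tx & (is.na(ids) | is.na(parents))))
    cs_parse_error(sprintf("transcript missing ID or Parent on line %d",
                           line_no[which(is_tx & (is.na(ids) | is.na(parents)))[1]]))
  if (any(is_cds & is.na(parents)))
    cs_structural_error(sprintf("CDS without Parent on line %d",
                                line_no[which(is_cds & is.na(parents))[1]]))

  genes <- data.table(gene_id = ids[is_gene], seq_id = m[is_gene, 1L],
                      strand = strand[is_gene],
                      start = start1[is_gene] - 1L, end = end1[is_gene])
  # A multi-parent transcript (comma-separated Parent) is out of scope.
  transcripts <- data.table(transcript_id = ids[is_tx],
                            gene_id = parents[is_tx],
                            seq_id = m[is_tx, 1L], strand = strand[is_tx])
  orphan_tx <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(orphan_tx))
    cs_structural_error(sprintf("transcript Parent '%s' does not name a gene", orphan_tx[1]))

  phase <- suppressWarnings(as.integer(m[is_cds, 8L]))
  if (any(is.na(phase) | !phase %in% 0:2))
    cs_parse_error(sprintf("CDS with missing/invalid phase on line %d",
                           line_no[is_cds][which(is.na(phase) | !phase %in% 0:2)[1]]))
  cds <- data.table(transcript_id = parents[is_cds],
                    start = start1[is_cds] - 1L, end = end1[is_cds],
                    phase = phase)
  orphan_cds <- setdiff(cds$transcript_id, transcripts$transcript_id)
  if (length(orphan_cds))
    cs_structural_error(sprintf("CDS Parent '%s' has no resolvable gene ancestor",
                                paste(orphan_cds, collapse = ", ")))
  strand_chk <- merge(transcripts, genes[, .(gene_id, gstrand = strand)], by = "gene_id")
  if (any(strand_chk$strand != strand_chk$gstrand))
    cs_structural_error("transcript strand differs from its gene's strand")
  setorder(cds, transcript_id, start)
  annotation_set(genes, transcripts[, .(transcript_id, gene_id)], cds)
}

#' Write an annotation set as GFF3
#'
#' Inverse of [parse_gff3()]: coordinates are converted back to 1-based
#' inclusive; gene, mRNA and CDS rows are emitted with ID/Parent links.
#'
#' @param anno An [annotation_set()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(anno, path, source = "chimeraScreen") {
  stopifnot(inherits(anno, "AnnotationSet"))
  out <- c("##gff-version 3")
  tx <- merge(anno$transcripts,
              anno$genes[, .(gene_id, seq_id, strand)], by = "gene_id")
  cds <- merge(anno$cds, tx[, .(transcript_id, seq_id, strand)], by = "transcript_id")
  gl <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                anno$genes$seq_id, source, anno$genes$start + 1L, anno$genes$end,
                anno$genes$strand, gff3_escape(anno$genes$gene_id))
  # transcript span = hull of its CDS (adequate for coding-only models)
  span <- cds[, .(start = min(start), end = max(end)), by = transcript_id]
  tx <- merge(tx, span, by = "transcript_id", all.x = TRUE)
  tx[is.na(start), `:=`(start = 0L, end = 1L)]
  tl <- sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                tx$seq_id, source, tx$start + 1L, tx$end, tx$strand,
                gff3_escape(tx$transcript_id), gff3_escape(tx$gene_id))
  cl <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds.%s;Parent=%s",
                cds$seq_id, source, cds$start + 1L, cds$end, cds$strand,
                cds$phase, gff3_escape(cds$transcript_id),
                gff3_escape(cds$transcript_id))
  # order: gene, its transcripts, their CDS — grouped by gene then coordinate
  ord_g <- order(anno$genes$seq_id, anno$genes$start, anno$genes$gene_id)
  blocks <- lapply(ord_g, function(i) {
    gid <- anno$genes$gene_id[i]
    ti <- which(tx$gene_id == gid)
    ci <- which(cds$transcript_id %in% tx$transcript_id[ti])
    c(gl[i], tl[ti], cl[ci][order(cds$start[ci])])
  })
  writeLines(c(out, unlist(blocks)), path)
  invisible(path)
}

# Translated protein length implied by a transcript's CDS rows: coding bases
# after discounting the 5' phase offset, in codons. A trailing stop codon, if
# present, is trimmed at translation and does not affect the ordering used
# for isoform selection.
transcript_coding_aa <- function(cds, transcripts, genes) {
  tx <- merge(transcripts, genes[, .(gene_id, strand)], by = "gene_id")
  agg <- cds[, .(total = sum(end - start),
                 first_plus = phase[which.min(start)],
                 first_minus = phase[which.max(start)]), by = transcript_id]
  agg <- merge(agg, tx, by = "transcript_id")
  agg[, first_phase := fifelse(strand == "+", first_plus, first_minus)]
  agg[, aa := (total - first_phase) %/% 3L]
  agg[, .(transcript_id, gene_id, aa)]
}

#' Keep the longest isoform of every gene
#'
#' Retains, per gene, the transcript whose translated protein is longest
#' (measured in codons of its CDS after the 5' phase offset). Ties are
#' broken by the lexicographically smallest transcript ID so the choice is
#' deterministic. Genes with no coding transcript are dropped, with a count
#' reported through the package log.
#'
#' @param anno An [annotation_set()].
#' @return An [annotation_set()] with exactly one transcript per gene.
#' @export
select_longest_isoform <- function(anno) {
  stopifnot(inherits(anno, "AnnotationSet"))
  aa <- transcript_coding_aa(anno$cds, anno$transcripts, anno$genes)
  aa <- aa[aa > 0L]
  setorder(aa, gene_id, -aa, transcript_id)
  keep <- aa[, .SD[1L], by = gene_id]
  n_dropped <- nrow(anno$genes) - nrow(keep)
  if (n_dropped > 0)
    cs_log(sprintf("select_longest_isoform: dropped %d gene(s) with no coding transcript",
                   n_dropped))
  annotation_set(anno$genes[gene_id %in% keep$gene_id],
                 anno$transcripts[transcript_id %in% keep$transcript_id],
                 anno$cds[transcript_id %in% keep$transcript_id])
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that upper-cases
#' residues and keeps only the first whitespace-delimited token of each
#' header as the sequence ID.
#'
#' @param path Path to a nucleotide FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence ID.
#' @export
read_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) cs_data_error("duplicate sequence IDs in genome FASTA")
  DNAStringSet(toupper(g))
}

#' Extract and translate longest-isoform proteins
#'
#' For every gene (which must carry exactly one transcript; run
#' [select_longest_isoform()] first) the CDS segments are concatenated in
#' transcription order -- reverse-complemented for `-` strand genes -- the
#' 5' phase offset of the first segment is discarded, and the result is
#' translated with the standard genetic code. A single trailing stop codon
#' is removed; codons containing `N` translate to `X`; an internal stop
#' triggers a warning and flags the record, with `*` retained in the
#' sequence.
#'
#' @param anno A longest-isoform [annotation_set()].
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param source Provenance label stored with each record
#'   (`"reference"`, `"alternate"` or `"database"`).
#' @return data.table with columns protein_id (equal to gene_id), gene_id,
#'   transcript_id, sequence, length, internal_stop, source.
#' @export
extract_proteins <- function(anno, genome, source = "reference") {
  stopifnot(inherits(anno, "AnnotationSet"))
  ntx <- anno$transcripts[, .N, by = gene_id]
  if (any(ntx$N != 1L))
    cs_data_error(sprintf("gene '%s' has %d transcripts; run select_longest_isoform() first",
                          ntx$gene_id[ntx$N != 1L][1], max(ntx$N)))
  tx <- merge(anno$transcripts, anno$genes, by = "gene_id")
  seqs <- as.character(genome)
  res <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i]
    cds <- anno$cds[transcript_id == t$transcript_id][order(start)]
    if (!nrow(cds)) next
    if (!t$seq_id %in% names(seqs))
      cs_data_error(sprintf("sequence '%s' (gene %s) absent from genome", t$seq_id, t$gene_id))
    chrom <- seqs[[t$seq_id]]
    if (any(cds$start < 0L) || any(cds$end > nchar(chrom)))
      cs_data_error(sprintf("CDS of %s outside genome bounds", t$transcript_id))
    pieces <- substring(chrom, cds$start + 1L, cds$end)
    spliced <- paste(pieces, collapse = "")
    first_phase <- if (t$strand == "+") cds$phase[1L] else cds$phase[nrow(cds)]
    if (t$strand == "-")
      spliced <- as.character(reverseComplement(DNAString(spliced)))
    if (first_phase > 0L) spliced <- substring(spliced, first_phase + 1L)
    if (nchar(spliced) %% 3L != 0L)
      cs_data_error(sprintf("CDS length of transcript '%s' not divisible by 3 after phase",
                            t$transcript_id))
    aa <- suppressWarnings(as.character(
      translate(DNAString(spliced), if.fuzzy.codon = "solve")))
    if (endsWith(aa, "*")) aa <- substring(aa, 1L, nchar(aa) - 1L)
    internal_stop <- grepl("*", aa, fixed = TRUE)
    if (internal_stop)
      warning(sprintf("internal stop codon in translation of %s", t$transcript_id),
              call. = FALSE)
    res[[i]] <- data.table(protein_id = t$gene_id, gene_id = t$gene_id,
                           transcript_id = t$transcript_id, sequence = aa,
                           length = nchar(aa), internal_stop = internal_stop,
                           source = source)
  }
  out <- rbindlist(res)
  if (!nrow(out))
    out <- data.table(protein_id = character(), gene_id = character(),
                      transcript_id = character(), sequence = character(),
                      length = integer(), internal_stop = logical(),
                      source = character())
  out
}

#' Write protein records as FASTA
#'
#' Headers take the form `>protein_id gene_id=... length=...`; sequences
#' are wrapped at 60 columns. Duplicate protein IDs or zero-length records
#' abort before anything is written.
#'
#' @param proteins data.table as returned by [extract_proteins()] (columns
#'   protein_id, gene_id, sequence, length required).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  proteins <- as.data.table(proteins)
  if (anyDuplicated(proteins$protein_id))
    cs_data_error("duplicate protein_id among records to write")
  if (nrow(proteins) && any(proteins$length == 0L | !nzchar(proteins$sequence)))
    cs_data_error("refusing to write zero-length protein record")
  if (nrow(proteins) && any(grepl("\\s", proteins$sequence)))
    cs_data_error("whitespace in protein sequence")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(sprintf(">%s gene_id=%s length=%d", proteins$protein_id[i],
                       proteins$gene_id[i], proteins$length[i]), con)
    s <- proteins$sequence[i]
    writeLines(substring(s, seq(1L, nchar(s), 60L),
                         pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a protein FASTA into a record table
#'
#' @param path Path to a protein FASTA file.
#' @param source Provenance label (default `"database"`).
#' @return data.table with protein_id, header, sequence, length, source.
#' @export
read_protein_fasta <- function(path, source = "database") {
  aa <- readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) cs_data_error("duplicate protein IDs in FASTA")
  data.table(protein_id = ids, header = headers, sequence = as.character(aa),
             length = nchar(as.character(aa)), source = source)
}
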