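# Seeded simulator of genomes with planted chimeric gene models.
#
# A planted chimera is built by concatenating complete component gene
# structures, keeping the DNA between components inside the fused model as
# an intron-like spacer: the fused protein is then the exact concatenation
# of the component proteins, so every coverage quantity downstream is
# analytic (a component hit covers exactly len_i / sum(len) of the fused
# query). Component proteins within a chimera are drawn from disjoint
# residue alphabets so the exact-substring oracle produces no cross-hits.

sim_aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one fixed unambiguous codon per amino acid (standard code)
sim_codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Simulation configuration
#'
#' Defaults plant 5 chimeras among 50 genes, with component counts drawn
#' in proportion to the composition observed in real annotation audits
#' (2-, 3-, 4-, 5- and 6-component fusions at weights 499:81:12:6:2, i.e.
#' two-gene fusions dominating). Gene lengths of 150-500 aa, 1-5 exons
#' per gene and intergenic gaps of 200-2000 bp are typical of compact
#' invertebrate genomes.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the configuration.
#' @param n_sequences Number of genome sequences.
#' @param n_genes Total reference genes.
#' @param gene_length_range Protein length range per gene component (aa).
#' @param exons_per_gene_range Exon count range per gene component.
#' @param intergenic_gap_range Gap between genes, and between the
#'   components inside a fused model (bp).
#' @param gc_target GC fraction of non-coding DNA.
#' @param n_chimeras Number of planted chimeric reference genes.
#' @param component_count_weights Named non-negative weights for component
#'   counts k = 2..6.
#' @param coverage_noise_sd Standard deviation of additive Gaussian noise
#'   applied to reference-hit query coverage via coordinate jitter
#'   (0 disables; see [perturb_hits()]).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_sequences = 2L, n_genes = 50L,
                              gene_length_range = c(150L, 500L),
                              exons_per_gene_range = c(1L, 5L),
                              intergenic_gap_range = c(200L, 2000L),
                              gc_target = 0.40, n_chimeras = 5L,
                              component_count_weights = c(`2` = 499, `3` = 81,
                                                          `4` = 12, `5` = 6,
                                                          `6` = 2),
                              coverage_noise_sd = 0) {
  cfg <- list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              exons_per_gene_range = as.integer(exons_per_gene_range),
              intergenic_gap_range = as.integer(intergenic_gap_range),
              gc_target = gc_target, n_chimeras = as.integer(n_chimeras),
              component_count_weights = component_count_weights,
              coverage_noise_sd = coverage_noise_sd)
  if (cfg$n_chimeras > cfg$n_genes)
    cs_usage_error("simulation_config: n_chimeras must not exceed n_genes")
  if (any(component_count_weights < 0) || all(component_count_weights == 0))
    cs_usage_error("simulation_config: weights must be non-negative, not all zero")
  if (!all(names(component_count_weights) %in% as.character(2:6)))
    cs_usage_error("simulation_config: component counts must be in 2..6")
  structure(cfg, class = "simulation_config")
}

sim_random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

sim_rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else sample(range[1]:range[2], n, replace = TRUE)
}

revcomp_chr <- function(x) as.character(reverseComplement(DNAString(x)))

# Split a coding sequence into exon pieces (transcription order) and
# record each piece's GFF3 phase.
sim_exonize <- function(coding, n_exons) {
  nc <- nchar(coding)
  n_exons <- min(n_exons, nc)
  cuts <- if (n_exons > 1L) sort(sample(seq_len(nc - 1L), n_exons - 1L)) else integer()
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nc)
  pieces <- substring(coding, starts, ends)
  cum <- c(0L, cumsum(nchar(pieces)))[seq_along(pieces)]
  phases <- (3L - (cum %% 3L)) %% 3L
  list(pieces = pieces, phases = phases)
}

# Lay out one gene (k >= 1 components in transcription order) as a
# nucleotide string plus CDS segments with offsets relative to the gene
# region start. Returns per-segment component index so the alternate
# annotation can split the model back into its parts.
sim_layout_gene <- function(components, strand, cfg) {
  k <- length(components)
  intron_range <- c(60L, 400L)
  comp_genome_order <- if (strand == "+") seq_len(k) else rev(seq_len(k))
  chunks <- character()
  segs <- list()
  offset <- 0L
  for (ci in comp_genome_order) {
    comp <- components[[ci]]
    e <- length(comp$pieces)
    piece_order <- if (strand == "+") seq_len(e) else rev(seq_len(e))
    for (j in seq_along(piece_order)) {
      pj <- piece_order[j]
      nt <- if (strand == "+") comp$pieces[pj] else revcomp_chr(comp$pieces[pj])
      segs[[length(segs) + 1L]] <- data.table(start = offset,
                                              end = offset + nchar(nt),
                                              phase = comp$phases[pj],
                                              component = ci)
      chunks <- c(chunks, nt)
      offset <- offset + nchar(nt)
      if (j < e) {
        intron <- sim_random_dna(sim_rint(1L, intron_range), cfg$gc_target)
        chunks <- c(chunks, intron)
        offset <- offset + nchar(intron)
      }
    }
    if (which(comp_genome_order == ci) < k) {
      spacer <- sim_random_dna(sim_rint(1L, cfg$intergenic_gap_range), cfg$gc_target)
      chunks <- c(chunks, spacer)
      offset <- offset + nchar(spacer)
    }
  }
  list(nt = paste(chunks, collapse = ""), segs = rbindlist(segs))
}

#' Simulate a genome with planted chimeric gene models
#'
#' Generates a bundle of: genome FASTA, reference annotation (chimeras as
#' single fused genes), alternate annotation (chimeras as their split
#' component genes; ordinary genes identical in both), a protein database
#' holding every component protein, idealized hit tables for both
#' annotations, and a truth table. Under the ideal hit model a component
#' protein hits the fused reference gene with query coverage
#' `len_i / len_fused` and target coverage 1, on disjoint query spans in
#' transcription order; every alternate model hits its component protein
#' full-length both ways; ordinary genes hit their own database homolog
#' full-length. The bundle is byte-identical for a fixed configuration.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Optional directory; when given, the bundle files
#'   (genome.fasta, reference.gff3, alternate.gff3, proteins.fasta,
#'   ref_hits.m8, alt_hits.m8, truth.tsv, manifest.json) are written.
#' @return Invisible list: config, genome (DNAStringSet), ref / alt
#'   ([annotation_set()]s), proteins (database records), ref_hits /
#'   alt_hits ([hit_table()]s), truth (data.table), paths (when written).
#' @export
simulate_bundle <- function(cfg = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)

  n <- cfg$n_genes
  chim_idx <- sort(sample.int(n, cfg$n_chimeras))
  w <- cfg$component_count_weights
  ks <- rep(1L, n)
  ks[chim_idx] <- as.integer(sample(names(w), cfg$n_chimeras, replace = TRUE,
                                    prob = w / sum(w)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seq_of_gene <- ((seq_len(n) - 1L) %% cfg$n_sequences) + 1L

  genes <- list(); transcripts <- list(); cds <- list()
  a_genes <- list(); a_transcripts <- list(); a_cds <- list()
  db <- list(); truth <- list(); rhits <- list(); ahits <- list()
  seq_chunks <- rep(list(character()), cfg$n_sequences)
  cursor <- integer(cfg$n_sequences)
  sp_counter <- 0L

  for (i in seq_len(n)) {
    k <- ks[i]
    sq <- seq_of_gene[i]
    seq_id <- sprintf("ctg%02d", sq)
    gid <- sprintf("rg%03d", i)
    strand <- strands[i]

    # component proteins (transcription order); disjoint alphabets inside
    # a chimera so components never match each other
    if (k > 1L) {
      perm <- sample(sim_aa_alphabet)
      groups <- split(perm, cut(seq_along(perm), k, labels = FALSE))
    } else groups <- list(sim_aa_alphabet)
    lens <- sim_rint(k, cfg$gene_length_range)
    prots <- vapply(seq_len(k), function(j)
      paste(sample(groups[[j]], lens[j], replace = TRUE), collapse = ""),
      character(1))

    components <- lapply(seq_len(k), function(j) {
      coding <- paste(sim_codons[strsplit(prots[j], "")[[1]]], collapse = "")
      if (j == k) coding <- paste0(coding, "TAA")  # stop only after the last part
      sim_exonize(coding, sim_rint(1L, cfg$exons_per_gene_range))
    })
    lay <- sim_layout_gene(components, strand, cfg)

    gap <- sim_random_dna(sim_rint(1L, cfg$intergenic_gap_range), cfg$gc_target)
    gstart <- cursor[sq] + nchar(gap)
    seq_chunks[[sq]] <- c(seq_chunks[[sq]], gap, lay$nt)
    cursor[sq] <- gstart + nchar(lay$nt)

    segs <- copy(lay$segs)[, `:=`(start = start + gstart, end = end + gstart)]
    tid <- paste0(gid, ".t1")
    genes[[i]] <- data.table(gene_id = gid, seq_id = seq_id, strand = strand,
                             start = gstart, end = gstart + nchar(lay$nt))
    transcripts[[i]] <- data.table(transcript_id = tid, gene_id = gid)
    cds[[i]] <- segs[, .(transcript_id = tid, start, end, phase)]

    sp_ids <- sprintf("SP%05d", sp_counter + seq_len(k))
    sp_counter <- sp_counter + k
    db[[i]] <- data.table(protein_id = sp_ids, gene_id = gid,
                          sequence = prots, length = nchar(prots))

    # alternate annotation: one gene per component
    for (j in seq_len(k)) {
      agid <- sprintf("ag%03d.%d", i, j)
      atid <- paste0(agid, ".t1")
      csub <- segs[component == j]
      a_genes[[length(a_genes) + 1L]] <- data.table(
        gene_id = agid, seq_id = seq_id, strand = strand,
        start = min(csub$start), end = max(csub$end))
      a_transcripts[[length(a_transcripts) + 1L]] <- data.table(
        transcript_id = atid, gene_id = agid)
      a_cds[[length(a_cds) + 1L]] <- csub[, .(transcript_id = atid, start, end, phase)]
      ahits[[length(ahits) + 1L]] <- data.table(
        query_id = agid, target_id = sp_ids[j], pident = 100,
        aln_len = lens[j], mismatch = 0L, gapopen = 0L,
        q_start = 1L, q_end = lens[j], t_start = 1L, t_end = lens[j],
        e_value = 0, bit_score = 2 * lens[j], q_len = lens[j], t_len = lens[j])
    }

    fused_len <- sum(lens)
    cum <- c(0L, cumsum(lens))
    rhits[[i]] <- data.table(
      query_id = gid, target_id = sp_ids, pident = 100, aln_len = lens,
      mismatch = 0L, gapopen = 0L,
      q_start = cum[seq_len(k)] + 1L, q_end = cum[seq_len(k) + 1L],
      t_start = 1L, t_end = lens, e_value = 0, bit_score = 2 * lens,
      q_len = fused_len, t_len = lens)

    truth[[i]] <- data.table(ref_gene_id = gid, is_chimera = k >= 2L,
                             component_count = k,
                             component_protein_ids = paste(sp_ids, collapse = ","))
  }

  # trailing intergenic DNA per sequence
  for (sq in seq_len(cfg$n_sequences))
    seq_chunks[[sq]] <- c(seq_chunks[[sq]],
                          sim_random_dna(sim_rint(1L, cfg$intergenic_gap_range),
                                         cfg$gc_target))
  genome <- DNAStringSet(vapply(seq_chunks, paste, character(1), collapse = ""))
  names(genome) <- sprintf("ctg%02d", seq_len(cfg$n_sequences))

  ref <- annotation_set(rbindlist(genes), rbindlist(transcripts), rbindlist(cds))
  alt <- annotation_set(rbindlist(a_genes), rbindlist(a_transcripts), rbindlist(a_cds))
  ref_hits <- hit_table(rbindlist(rhits))
  alt_hits <- hit_table(rbindlist(ahits))
  if (cfg$coverage_noise_sd > 0)
    ref_hits <- perturb_hits(ref_hits, cfg$coverage_noise_sd)

  bundle <- list(config = cfg, genome = genome, ref = ref, alt = alt,
                 proteins = rbindlist(db), ref_hits = ref_hits,
                 alt_hits = alt_hits, truth = rbindlist(truth))
  if (!is.null(out_dir)) bundle$paths <- write_bundle(bundle, out_dir)
  invisible(bundle)
}

#' Write a simulated bundle to disk
#'
#' @param bundle Result of [simulate_bundle()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths (plus a manifest JSON
#'   with the configuration echo and md5 checksums).
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  writeXStringSet(bundle$genome, p("genome.fasta"), width = 60L)
  write_gff3(bundle$ref, p("reference.gff3"))
  write_gff3(bundle$alt, p("alternate.gff3"))
  write_protein_fasta(bundle$proteins, p("proteins.fasta"))
  write_hits(bundle$ref_hits, p("ref_hits.m8"), dialect = "m8+len")
  write_hits(bundle$alt_hits, p("alt_hits.m8"), dialect = "m8+len")
  fwrite(bundle$truth, p("truth.tsv"), sep = "\t")
  paths <- c(genome = p("genome.fasta"), ref_gff = p("reference.gff3"),
             alt_gff = p("alternate.gff3"), proteins = p("proteins.fasta"),
             ref_hits = p("ref_hits.m8"), alt_hits = p("alt_hits.m8"),
             truth = p("truth.tsv"))
  manifest <- list(config = unclass(bundle$config),
                   checksums = as.list(md5sum(unname(paths))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  c(paths, manifest = p("manifest.json"))
}

#' Jitter hit coordinates to perturb query coverage
#'
#' Adds seeded Gaussian noise (sd = `sd`, in coverage units) to each hit's
#' query coverage by symmetrically expanding or contracting the query
#' span; coordinates are clamped so every hit still satisfies the hit
#' invariants. With `sd = 0` the table is returned unchanged.
#'
#' @param hits A [hit_table()].
#' @param sd Coverage noise standard deviation.
#' @param seed Optional seed applied before drawing the noise.
#' @return A perturbed [hit_table()].
#' @export
perturb_hits <- function(hits, sd, seed = NULL) {
  if (sd == 0 || !nrow(hits)) return(hits)
  if (!is.null(seed)) set.seed(seed)
  h <- copy(as.data.table(hits))
  delta <- round(rnorm(nrow(h), 0, sd) * h$q_len)
  d1 <- delta %/% 2L
  d2 <- delta - d1
  h[, q_start := pmax(1L, as.integer(q_start - d1))]
  h[, q_end := pmin(q_len, as.integer(q_end + d2))]
  h[q_end < q_start, q_end := q_start]
  h[, aln_len := as.integer(q_end - q_start + 1L)]
  h[, bit_score := 2 * aln_len]
  h[, q_cov := (q_end - q_start + 1) / q_len]
  hit_table(h)
}
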