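test_that("GFF3 parsing converts coordinates and builds the gene/transcript/CDS hierarchy", {
  f <- write_tmp_gff3(c(
    "chr1\t.\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t101\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\t.\tCDS\t101\t130\t.\t+\t0\tID=c1;Parent=g1.t1",
    "chr1\t.\tCDS\t151\t200\t.\t+\t0\tID=c2;Parent=g1.t1",
    "chr1\t.\tmRNA\t101\t160\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\t.\tCDS\t101\t160\t.\t+\t0\tID=c3;Parent=g1.t2"))
  a <- parse_gff3(f)
  expect_equal(nrow(a$genes), 1L)
  expect_equal(nrow(a$transcripts), 2L)
  expect_equal(nrow(a$cds), 3L)
  # 1-based inclusive [101, 200] -> 0-based half-open [100, 200)
  expect_equal(a$genes$start, 100L)
  expect_equal(a$genes$end, 200L)
})

test_that("GFF3 parsing rejects malformed and structurally broken input", {
  bad_attr <- write_tmp_gff3("chr1\t.\tgene\t1\t10\t.\t+\t.\tIDnoequals")
  expect_error(parse_gff3(bad_attr), "line 2", class = "cs_parse_error")
  orphan <- write_tmp_gff3(c(
    "chr1\t.\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t1\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\t.\tCDS\t1\t30\t.\t+\t0\tID=c1;Parent=ghost"))
  expect_error(parse_gff3(orphan), "ghost", class = "cs_structural_error")
  dot_strand <- write_tmp_gff3("chr1\t.\tgene\t1\t10\t.\t.\t.\tID=g1")
  expect_error(parse_gff3(dot_strand), "strand", class = "cs_parse_error")
})

test_that("GFF3 round trip preserves gene, transcript and CDS coordinate sets", {
  b <- simulate_bundle(simulation_config(seed = 11, n_genes = 12, n_chimeras = 3))
  f <- tempfile(fileext = ".gff3")
  write_gff3(b$ref, f)
  a2 <- parse_gff3(f)
  key <- function(a) list(
    genes = data.table::setorder(a$genes[, .(gene_id, seq_id, strand, start, end)], gene_id),
    tx = data.table::setorder(a$transcripts[, .(transcript_id, gene_id)], transcript_id),
    cds = data.table::setorder(a$cds[, .(transcript_id, start, end, phase)],
                               transcript_id, start))
  expect_equal(key(a2)$tx, key(b$ref)$tx)
  expect_equal(key(a2)$cds, key(b$ref)$cds)
  expect_equal(key(a2)$genes[, .(gene_id, seq_id, strand)],
               key(b$ref)$genes[, .(gene_id, seq_id, strand)])
})

test_that("longest-isoform selection maximizes protein length, breaks ties lexicographically, and is idempotent", {
  f <- write_tmp_gff3(c(
    "chr1\t.\tgene\t1\t2000\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t1\t2000\t.\t+\t.\tID=g1.short;Parent=g1",
    "chr1\t.\tCDS\t1\t750\t.\t+\t0\tID=c1;Parent=g1.short",
    "chr1\t.\tmRNA\t1\t2000\t.\t+\t.\tID=g1.long;Parent=g1",
    "chr1\t.\tCDS\t1\t1200\t.\t+\t0\tID=c2;Parent=g1.long",
    "chr1\t.\tgene\t3001\t4000\t.\t+\t.\tID=g2",
    "chr1\t.\tmRNA\t3001\t4000\t.\t+\t.\tID=g2.tB;Parent=g2",
    "chr1\t.\tCDS\t3001\t3900\t.\t+\t0\tID=c3;Parent=g2.tB",
    "chr1\t.\tmRNA\t3001\t4000\t.\t+\t.\tID=g2.tA;Parent=g2",
    "chr1\t.\tCDS\t3001\t3900\t.\t+\t0\tID=c4;Parent=g2.tA"))
  a <- select_longest_isoform(parse_gff3(f))
  expect_equal(sort(a$transcripts$transcript_id), c("g1.long", "g2.tA"))
  a2 <- select_longest_isoform(a)
  expect_equal(a2$transcripts, a$transcripts)
  expect_equal(a2$cds, a$cds)
})

mk_single_gene <- function(cds_lines, strand = "+", span = c(1, 100)) {
  f <- write_tmp_gff3(c(
    sprintf("chr1\t.\tgene\t%d\t%d\t.\t%s\t.\tID=g1", span[1], span[2], strand),
    sprintf("chr1\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=g1.t1;Parent=g1", span[1], span[2], strand),
    cds_lines))
  parse_gff3(f)
}

test_that("CDS translation follows strand, trims the stop, and maps N codons to X", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATAGCCCCTATTTCATCCCATGAANTAG"))
  plus <- mk_single_gene("chr1\t.\tCDS\t1\t9\t.\t+\t0\tID=c;Parent=g1.t1", span = c(1, 9))
  expect_equal(extract_proteins(plus, genome)$sequence, "MK")
  # genome[13..21] = CTATTTCAT; reverse complement ATGAAATAG -> MK
  minus <- mk_single_gene("chr1\t.\tCDS\t13\t21\t.\t-\t0\tID=c;Parent=g1.t1",
                          strand = "-", span = c(13, 21))
  expect_equal(extract_proteins(minus, genome)$sequence, "MK")
  fuzzy <- mk_single_gene("chr1\t.\tCDS\t25\t33\t.\t+\t0\tID=c;Parent=g1.t1", span = c(25, 33))
  expect_equal(extract_proteins(fuzzy, genome)$sequence, "MX")
})

test_that("reverse-strand translation equals plus-strand translation of the explicit reverse complement", {
  set.seed(42)
  prot <- rand_protein(60)
  codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
              H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
              P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
              W = "TGG", Y = "TAT")
  coding <- paste0(paste(codons[strsplit(prot, "")[[1]]], collapse = ""), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
  genome_plus <- Biostrings::DNAStringSet(c(chr1 = coding))
  genome_minus <- Biostrings::DNAStringSet(c(chr1 = rc))
  n <- nchar(coding)
  on_plus <- mk_single_gene(sprintf("chr1\t.\tCDS\t1\t%d\t.\t+\t0\tID=c;Parent=g1.t1", n),
                            span = c(1, n))
  on_minus <- mk_single_gene(sprintf("chr1\t.\tCDS\t1\t%d\t.\t-\t0\tID=c;Parent=g1.t1", n),
                             strand = "-", span = c(1, n))
  expect_equal(extract_proteins(on_minus, genome_minus)$sequence,
               extract_proteins(on_plus, genome_plus)$sequence)
  expect_equal(extract_proteins(on_plus, genome_plus)$sequence, prot)
})

test_that("frame errors and internal stops are reported as specified", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGAAATAGATGTAAAAATAG"))
  bad_frame <- mk_single_gene("chr1\t.\tCDS\t1\t8\t.\t+\t0\tID=c;Parent=g1.t1", span = c(1, 8))
  expect_error(extract_proteins(bad_frame, genome), "divisible by 3",
               class = "cs_data_error")
  internal <- mk_single_gene("chr1\t.\tCDS\t10\t21\t.\t+\t0\tID=c;Parent=g1.t1",
                             span = c(10, 21))
  expect_warning(p <- extract_proteins(internal, genome), "internal stop")
  expect_true(p$internal_stop)
  expect_true(grepl("*", p$sequence, fixed = TRUE))
})

test_that("CDS length accounting brackets protein length on simulated genes", {
  b <- simulate_bundle(simulation_config(seed = 3, n_genes = 20, n_chimeras = 4))
  p <- extract_proteins(b$ref, b$genome)
  cds_tot <- merge(b$ref$cds[, .(total = sum(end - start)), by = transcript_id],
                   p, by = "transcript_id")
  expect_true(all(cds_tot$total >= cds_tot$length * 3))
  expect_true(all(cds_tot$total <= cds_tot$length * 3 + 3))
})

test_that("protein FASTA writing enforces invariants and round trips", {
  p <- data.table(protein_id = c("p1", "p2"), gene_id = c("g1", "g2"),
                  sequence = c(rand_protein(70), rand_protein(61)),
                  length = c(70L, 61L))
  f <- tempfile(fileext = ".fasta")
  write_protein_fasta(p, f)
  back <- read_protein_fasta(f)
  expect_equal(back$protein_id, p$protein_id)
  expect_equal(back$sequence, p$sequence)
  expect_error(write_protein_fasta(rbind(p, p[1]), f), "duplicate")
  expect_error(write_protein_fasta(data.table(protein_id = "z", gene_id = "g",
                                              sequence = "", length = 0L), f),
               "zero-length")
  empty <- tempfile(fileext = ".fasta")
  write_protein_fasta(p[0], empty)
  expect_true(file.exists(empty))
  expect_equal(length(readLines(empty)), 0L)
})
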