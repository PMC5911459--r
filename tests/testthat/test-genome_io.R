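# Reading genomes and annotations into the internal 0-based half-open
# convention, and strand-aware upstream extraction.

write_fasta <- function(seqs, path = withr::local_tempfile(fileext = ".fasta",
                                                           .local_envir = parent.frame())) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

test_that("FASTA genomes load, normalise, and default to linear", {
  p <- write_fasta(list(chr = "acgt"))
  g <- read_genome(p, "fasta")
  expect_equal(g$length, 4L)
  expect_equal(g$sequence, "ACGT")
  expect_equal(g$topology, "linear")
  expect_equal(read_genome(p, "fasta", circular = TRUE)$topology, "circular")
})

test_that("multi-record FASTA requires a selector and lists available ids", {
  p <- write_fasta(list(chrA = "ACGTACGT", chrB = "GGGCCC"))
  expect_error(read_genome(p, "fasta"), "chrA.*chrB")
  expect_equal(read_genome(p, "fasta", record = "chrB")$sequence, "GGGCCC")
  expect_error(read_genome(p, "fasta", record = "nope"), "not found")
})

test_that("invalid genome input is rejected", {
  p <- write_fasta(list(chr = "ACQT"))
  expect_error(read_genome(p, "fasta"), "outside the DNA alphabet")
  expect_error(genome_record("x", ""), "empty")
  expect_error(read_genome("no/such/file.fasta", "fasta"), "no such file")
})

make_genbank <- function(seq, cds_lines, topology = "linear",
                         path = withr::local_tempfile(fileext = ".gb",
                                                      .local_envir = parent.frame())) {
  n <- nchar(seq)
  chunks <- substring(seq, seq(1, n, 60), pmin(seq(60, n + 59, 60), n))
  origin <- sprintf("%9d %s", seq(1, n, 60),
                    vapply(chunks, function(ch)
                      paste(substring(ch, seq(1, nchar(ch), 10),
                                      pmin(seq(10, nchar(ch) + 9, 10), nchar(ch))),
                            collapse = " "), character(1)))
  writeLines(c(
    sprintf("LOCUS       testrec %d bp    DNA     %s   UNA 01-JAN-2000",
            n, topology),
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    cds_lines,
    "ORIGIN",
    tolower(origin),
    "//"), path)
  path
}

test_that("GenBank topology, sequence, and CDS locations are parsed", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  p <- make_genbank(seq, c(
    "     CDS             complement(11..40)",
    '                     /locus_tag="geneM"'), topology = "circular")
  g <- read_genome(p, "genbank")
  expect_equal(g$topology, "circular")
  expect_equal(g$sequence, seq)

  genes <- read_annotations(p, "genbank")
  expect_equal(genes$start, 10L)
  expect_equal(genes$end, 40L)
  expect_equal(genes$strand, "-")
  # coding-strand start codon is the reverse complement of bases 38..40
  expect_equal(genes$annotated_start_codon,
               oracle_revcomp(substr(seq, 38, 40)))
})

test_that("GFF3 coordinates shift to 0-based half-open and round-trip", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t101\t160\t.\t+\t0\tID=gA;locus_tag=gA",
               "chr\tsrc\tCDS\t201\t263\t.\t-\t0\tID=gB;locus_tag=gB"),
             gff)
  genes <- read_annotations(gff, "gff3")
  expect_equal(genes$start, c(100L, 200L))
  expect_equal(genes$end, c(160L, 263L))
  expect_equal(genes$strand, c("+", "-"))

  out <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, out, seqid = "chr")
  back <- read_annotations(out, "gff3")
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$gene_id, genes$gene_id)
})

test_that("a CDS whose length is not a multiple of 3 is flagged, not dropped", {
  expect_warning(g <- gene_model("odd", 10, 60, "+"), "divisible by 3")
  expect_equal(nrow(g), 1L)
  expect_true(g$length_flag)
})

test_that("out-of-bounds genes on a linear genome are an error", {
  genome <- genome_record("g", strrep("ACGT", 25))
  expect_error(gene_model("far", 90, 120, "+", genome = genome), "bounds")
})

test_that("upstream extraction truncates at the linear edge", {
  genome <- genome_record("g", strrep("ACGT", 25))
  gene0 <- gene_model("g0", 0, 30, "+")
  expect_equal(extract_upstream(genome, gene0, 15), "")
  gene30 <- gene_model("g30", 30, 60, "+")
  expect_equal(extract_upstream(genome, gene30, 6), substr(genome$sequence, 25, 30))
  expect_equal(extract_upstream(genome, gene30, 0), "")
  expect_equal(nchar(extract_upstream(genome, gene30, 100)), 30L)
})

test_that("minus-strand extraction obeys the strand-symmetry oracle", {
  set.seed(7)
  for (i in 1:50) {
    L <- sample(60:200, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    genome <- genome_record("g", seq)
    s <- sample(10:(L - 40), 1); e <- s + 30
    gene_minus <- gene_model("gm", s, e, "-")
    # mirror onto the reverse-complemented genome as a plus-strand gene
    genome_rc <- genome_record("g_rc", oracle_revcomp(seq))
    gene_plus <- gene_model("gp", L - e, L - s, "+")
    n <- sample(0:20, 1)
    expect_identical(extract_upstream(genome, gene_minus, n),
                     extract_upstream(genome_rc, gene_plus, n))
  }
})

test_that("circular genomes wrap and always return the full window", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  genome <- genome_record("c", seq, topology = "circular")
  gene <- gene_model("g", 6, 36, "+")
  up <- extract_upstream(genome, gene, 20)
  expect_equal(nchar(up), 20L)
  expect_equal(up, paste0(substr(seq, 67, 80), substr(seq, 1, 6)))
  # property: any window shorter than the genome returns exactly n bases
  for (n in c(1, 10, 79)) {
    expect_equal(nchar(extract_upstream(genome, gene, n)), n)
  }
  gene_m <- gene_model("gm", 50, 80, "-")
  expect_equal(nchar(extract_upstream(genome, gene_m, 40)), 40L)
})
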