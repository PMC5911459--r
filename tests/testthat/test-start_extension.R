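# The upstream in-frame alternative-start scan and extended-ORF reports.

# genome with a fully specified upstream codon context (given 5'->3',
# nearest codon last) followed by a short CDS
planted_gene <- function(upstream_codons, cds = "ATGGCTGCTTAA", pad = 30) {
  left <- strrep("C", pad)
  up <- paste(upstream_codons, collapse = "")
  genome <- genome_record("p", paste0(left, up, cds, strrep("C", 9)))
  start0 <- pad + nchar(up)
  list(genome = genome,
       gene = gene_model("g1", start0, start0 + nchar(cds), "+",
                         genome = genome))
}

test_that("translation follows the standard code with initiator handling", {
  expect_equal(translate_cds("ATGGCTTAA"), "MA")
  expect_equal(translate_cds("TTGGCT", initiator_as_met = TRUE), "MA")
  expect_equal(translate_cds("TTGGCT"), "LA")  # literal TTG is leucine
  expect_error(translate_cds("ATGTAAATG"), "codon 2")
  expect_error(translate_cds("ATGGC"), "multiple of 3")
  expect_equal(translate_cds("ATGNNNGCT"), "MXA")
})

test_that("an immediately upstream in-frame stop yields no candidates", {
  fx <- planted_gene(c("TTG", "TAA"))
  cands <- scan_upstream_starts(fx$genome, fx$gene)
  expect_equal(nrow(cands), 0L)
})

test_that("a planted TTG five codons upstream is found with extension 5", {
  fx <- planted_gene(c("TAA", "CCC", "TTG", "CGC", "CGA", "GCC", "GAC"))
  cands <- scan_upstream_starts(fx$genome, fx$gene,
                                allowed_starts = c("TTG", "GTG"))
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$codon, "TTG")
  expect_equal(cands$extension_aa, 5L)
  expect_equal(cands$genomic_offset, fx$gene$start - 15L)
  # matches the enumeration oracle
  expect_equal(cands$extension_aa,
               oracle_upstream_scan(fx$genome$sequence, fx$gene$start,
                                    fx$gene$end, "+"))
})

test_that("candidates at the annotated start itself are never emitted", {
  fx <- planted_gene(c("GTG", "TTG"))
  cands <- scan_upstream_starts(fx$genome, fx$gene)
  expect_true(all(cands$extension_aa >= 1))
})

test_that("the scan stops at the linear genome edge without error", {
  genome <- genome_record("e", "GCTATGGCTTAA")
  gene <- gene_model("g", 3, 12, "+", genome = genome)
  cands <- scan_upstream_starts(genome, gene)
  expect_equal(nrow(cands), 0L)  # only one incomplete upstream codon
})

test_that("an unusual annotated start codon warns but the scan proceeds", {
  fx <- planted_gene(c("TTG", "CCC"), cds = "CTGGCTTAA")
  cands <- scan_upstream_starts(fx$genome, fx$gene)
  expect_match(paste(attr(cands, "warnings"), collapse = " "),
               "not ATG/GTG/TTG")
  expect_equal(cands$extension_aa, 2L)
})

test_that("N-containing codons match nothing and do not stop the scan", {
  fx0 <- planted_gene(c("TAA", "TTG", "NNN", "CCC"))
  cands <- scan_upstream_starts(fx0$genome, fx0$gene)
  expect_equal(cands$extension_aa, 3L)
  expect_match(paste(attr(cands, "warnings"), collapse = " "), "contains N")
})

test_that("scan equals the brute-force oracle on random genes, both strands", {
  set.seed(2024)
  n_checked <- 0
  for (i in 1:300) {
    fx <- random_gene_fixture()
    got <- scan_upstream_starts(fx$genome, fx$gene,
                                allowed_starts = c("TTG", "GTG"),
                                max_extension_codons = 60)
    want <- oracle_upstream_scan(fx$genome$sequence, fx$gene$start,
                                 fx$gene$end, fx$strand, max_k = 60)
    expect_equal(got$extension_aa, want)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
})

test_that("no candidate is separated from the annotated start by a stop", {
  set.seed(99)
  for (i in 1:100) {
    fx <- random_gene_fixture()
    got <- scan_upstream_starts(fx$genome, fx$gene,
                                allowed_starts = c("ATG", "TTG", "GTG"))
    if (nrow(got) == 0) next
    up <- extract_upstream(fx$genome, fx$gene, 3 * max(got$extension_aa))
    codons <- substring(up, seq(1, nchar(up), 3), seq(3, nchar(up), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("results are invariant under reverse-complementing the genome", {
  set.seed(17)
  for (i in 1:50) {
    fx <- random_gene_fixture()
    L <- fx$genome$length
    genome_rc <- genome_record("rc", oracle_revcomp(fx$genome$sequence))
    flipped <- if (fx$strand == "+") "-" else "+"
    gene_rc <- gene_model("g1", L - fx$gene$end, L - fx$gene$start, flipped)
    a <- scan_upstream_starts(fx$genome, fx$gene)
    b <- scan_upstream_starts(genome_rc, gene_rc)
    expect_equal(a$extension_aa, b$extension_aa)
    expect_equal(a$codon, b$codon)
    expect_equal(a$sd_score, b$sd_score)
  }
})

test_that("enlarging the scan window never removes a candidate", {
  set.seed(31)
  for (i in 1:50) {
    fx <- random_gene_fixture()
    small <- scan_upstream_starts(fx$genome, fx$gene, max_extension_codons = 10)
    big <- scan_upstream_starts(fx$genome, fx$gene, max_extension_codons = 40)
    expect_true(all(small$extension_aa %in% big$extension_aa))
  }
})

test_that("extension reports choose the most upstream candidate", {
  fx <- planted_gene(c("TAA", "TTG", "CCC", "GTG", "CGC"),
                     cds = "ATGGCTGATTAA")
  rep <- build_extension_report(fx$genome, fx$gene,
                                allowed_starts = c("TTG", "GTG"))
  expect_equal(rep$extension_aa, 4L)
  expect_equal(rep$chosen$codon, "TTG")
  expect_equal(rep$initiator_literal, "L")
  # chosen form: TTG CCC GTG CGC ATG GCT GAT (stop untranslated), initiator as M
  expect_equal(rep$extended_protein, "MPVRMAD")
  # length = extension + original codon count - 1 (stop untranslated)
  expect_equal(nchar(rep$extended_protein),
               rep$extension_aa + (fx$gene$end - fx$gene$start) / 3 - 1)
  expect_equal(rep$annotated_protein, "MAD")
})

test_that("a gene with no candidates reports its annotated translation", {
  fx <- planted_gene(c("TAA", "CCC"))
  rep <- build_extension_report(fx$genome, fx$gene)
  expect_null(rep$chosen)
  expect_equal(rep$extension_aa, 0L)
  expect_equal(rep$extended_protein, rep$annotated_protein)
})

test_that("an internal stop in the annotated CDS is a per-gene error", {
  fx <- planted_gene(c("TTG", "CCC"), cds = "ATGTAGGCTTAA")
  expect_error(build_extension_report(fx$genome, fx$gene), "stop codon at codon 2")
})

test_that("batch scanning flags failing genes without aborting", {
  fx <- planted_gene(c("TAA", "TTG", "CCC"))
  bad_genome <- genome_record("b", paste0(strrep("C", 12), "ATGTAGGCTTAA"))
  genes3 <- rbind(fx$gene, fx$gene, gene_model("bad", 12, 24, "+"))
  genes3$gene_id <- c("g1", "g2", "bad")
  # one genome per batch: plant the bad gene into the same genome
  genome <- genome_record("m", paste0(fx$genome$sequence, "ATGTAGGCTTAA"))
  genes3$start[3] <- fx$genome$length
  genes3$end[3] <- fx$genome$length + 12
  reports <- scan_all(genome, genes3)
  expect_length(reports, 3L)
  expect_null(reports[[1]]$error)
  expect_null(reports[[2]]$error)
  expect_match(reports[[3]]$error, "stop codon")
  tab <- extension_table(reports)
  expect_equal(sum(!is.na(tab$error)), 1L)

  expect_length(scan_all(genome, fx$gene[0, ]), 0L)
})

test_that("extended proteins are written as FASTA with ext suffixes", {
  fx <- planted_gene(c("TAA", "TTG", "CCC"))
  reports <- scan_all(fx$genome, fx$gene)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_extended_fasta(reports, out)
  aa <- Biostrings::readAAStringSet(out)
  expect_equal(names(aa), "g1|ext2")
  expect_equal(as.character(aa[[1]]), reports[[1]]$extended_protein)
})
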