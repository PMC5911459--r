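# Synthetic fixtures: genomes with planted N-terminal extensions and SD
# motifs at known positions, and colony counts simulated from a known true
# error rate. Every planted construct is built so the scan's stop-barrier
# property holds by construction: codons inside a planted extension are
# drawn from the 58 codons that are neither stops nor initiators, so the
# planted candidates are exactly the candidates present.

CODONS_ALL <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))
SAFE_CODONS <- setdiff(CODONS_ALL, c(STOP_CODONS, START_CODONS))

random_bases <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_safe_codons <- function(n) {
  if (n == 0L) return(character())
  sample(SAFE_CODONS, n, replace = TRUE)
}

# Build one gene cassette in coding orientation:
#   [stop barrier][15-base SD window][planted extension codons][ATG ... TAA]
# `plan` is a data frame of candidate starts (extension_aa, codon); the most
# upstream one is the truth "chosen" form. With an empty plan the barrier
# stop sits immediately upstream of the annotated ATG, so no candidate can
# exist.
build_locus <- function(plan, cds_codons, sd_offset = NA,
                        sd_consensus = "GGAGG") {
  cds <- paste0("ATG", paste(random_safe_codons(cds_codons - 2L), collapse = ""),
                "TAA")
  if (nrow(plan) == 0L) {
    return(list(upstream = "TAA", cds = cds, ext_nt = "",
                sd_seq = NA_character_,
                true_protein = translate_cds(cds, initiator_as_met = TRUE)))
  }
  plan <- plan[order(-plan$extension_aa), , drop = FALSE]
  kmax <- plan$extension_aa[1L]
  ext <- random_safe_codons(kmax)
  ext[kmax - plan$extension_aa + 1L] <- plan$codon  # coding order: u_kmax first

  # 15-base window upstream of the chosen candidate; in-frame triplets must
  # stay neither start nor stop so the plan is the complete candidate set
  sd_seq <- NA_character_
  repeat {
    win <- strsplit(random_bases(15L), "")[[1L]]
    if (!is.na(sd_offset)) {
      cl <- nchar(sd_consensus)
      stopifnot(sd_offset <= -4L - cl + 1L, sd_offset >= -15L)
      win[16L + sd_offset + seq_len(cl) - 1L] <- strsplit(sd_consensus, "")[[1L]]
      sd_seq <- sd_consensus
    }
    win <- paste(win, collapse = "")
    trip <- substring(win, c(1L, 4L, 7L, 10L, 13L), c(3L, 6L, 9L, 12L, 15L))
    if (!any(trip %in% c(STOP_CODONS, START_CODONS))) break
  }

  ext_nt <- paste(ext, collapse = "")
  list(upstream = paste0("TAA", win, ext_nt), cds = cds, ext_nt = ext_nt,
       sd_seq = sd_seq,
       true_protein = translate_cds(paste0(ext_nt, cds),
                                    initiator_as_met = TRUE))
}

#' Generate a synthetic genome with planted N-terminal extensions
#'
#' Plants genes on both strands whose upstream regions contain in-frame
#' alternative starts, interrupting stops, and SD motifs at known
#' positions, plus a per-gene truth record for scoring recovery. A gene
#' planted with \code{extension_aa = 0} carries a stop immediately upstream
#' in frame, so the genome contains no in-frame alternative start upstream
#' of it within the scan window.
#'
#' @param n_genes Number of genes (ignored when \code{truth_spec} is given).
#' @param length Genome length in bases; must accommodate all cassettes.
#' @param truth_spec Optional data frame with one row per gene: columns
#'   \code{extension_aa} (0 for none), \code{codon} (planted initiator,
#'   ignored when extension is 0), \code{strand}, \code{sd_offset} (negative
#'   offset of a planted SD consensus, or NA), \code{cds_codons}, and
#'   optionally \code{secondary_ext}/\code{secondary_codon} for a second,
#'   less upstream candidate. When \code{NULL}, a random spec is drawn.
#' @param seed Integer seed fixing all randomness.
#' @param gc Background GC content; \code{0.56} approximates the GC-rich
#'   A. pernix genome.
#' @param circular Genome topology.
#' @param sd_consensus Consensus planted when \code{sd_offset} is set.
#' @return List with \code{genome} ([genome_record()]), \code{genes}
#'   ([gene_model()]), and \code{truth} (data frame: \code{gene_id},
#'   \code{strand}, \code{extension_aa}, \code{codon}, \code{sd_offset},
#'   \code{sd_seq}, \code{true_protein}).
#' @export
generate_genome <- function(n_genes = 5L, length = 10000L, truth_spec = NULL,
                            seed, gc = 0.5, circular = FALSE,
                            sd_consensus = "GGAGG") {
  set.seed(seed)
  if (is.null(truth_spec)) {
    truth_spec <- data.frame(
      extension_aa = sample(0:15, n_genes, replace = TRUE),
      codon = sample(c("TTG", "GTG"), n_genes, replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      sd_offset = sample(c(NA, -12L, -10L, -8L), n_genes, replace = TRUE),
      cds_codons = sample(20:50, n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  n <- nrow(truth_spec)
  if (is.null(truth_spec$gene_id)) truth_spec$gene_id <- sprintf("gene%03d", seq_len(n))
  if (is.null(truth_spec$sd_offset)) truth_spec$sd_offset <- NA_integer_
  if (is.null(truth_spec$cds_codons)) truth_spec$cds_codons <- 30L

  loci <- vector("list", n)
  for (i in seq_len(n)) {
    ext <- truth_spec$extension_aa[i]
    plan <- if (ext > 0L) {
      data.frame(extension_aa = ext, codon = truth_spec$codon[i],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(extension_aa = integer(), codon = character(),
                 stringsAsFactors = FALSE)
    }
    if (!is.null(truth_spec$secondary_ext) &&
        !is.na(truth_spec$secondary_ext[i])) {
      plan <- rbind(plan, data.frame(
        extension_aa = truth_spec$secondary_ext[i],
        codon = truth_spec$secondary_codon[i], stringsAsFactors = FALSE))
    }
    loci[[i]] <- build_locus(plan, truth_spec$cds_codons[i],
                             sd_offset = truth_spec$sd_offset[i],
                             sd_consensus = sd_consensus)
  }
  cassettes <- vapply(loci, function(l) paste0(l$upstream, l$cds), character(1))
  clens <- nchar(cassettes)
  free <- length - sum(clens)
  if (free < 2L * (n + 1L)) {
    stop("genes exceed genome length: need > ", sum(clens) + 2L * (n + 1L),
         " bases", call. = FALSE)
  }
  gap <- free %/% (n + 1L)

  seq_parts <- character(0)
  pos <- 0L
  starts <- ends <- integer(n)
  for (i in seq_len(n)) {
    seq_parts <- c(seq_parts, random_bases(gap, gc))
    pos <- pos + gap
    cassette <- cassettes[i]
    ulen <- nchar(loci[[i]]$upstream)
    cds_len <- nchar(loci[[i]]$cds)
    if (truth_spec$strand[i] == "+") {
      starts[i] <- pos + ulen
      ends[i] <- pos + ulen + cds_len
      seq_parts <- c(seq_parts, cassette)
    } else {
      starts[i] <- pos + clens[i] - ulen - cds_len
      ends[i] <- pos + clens[i] - ulen
      seq_parts <- c(seq_parts, revcomp(cassette))
    }
    pos <- pos + clens[i]
  }
  seq_parts <- c(seq_parts, random_bases(length - pos, gc))
  genome <- genome_record("synthetic_genome", paste(seq_parts, collapse = ""),
                          topology = if (circular) "circular" else "linear")
  genes <- gene_model(truth_spec$gene_id, starts, ends, truth_spec$strand,
                      genome = genome)
  truth <- data.frame(
    gene_id = truth_spec$gene_id,
    strand = truth_spec$strand,
    extension_aa = truth_spec$extension_aa,
    codon = ifelse(truth_spec$extension_aa > 0L, truth_spec$codon,
                   NA_character_),
    sd_offset = ifelse(truth_spec$extension_aa > 0L, truth_spec$sd_offset,
                       NA_integer_),
    sd_seq = vapply(loci, function(l) l$sd_seq, character(1)),
    true_protein = vapply(loci, function(l) l$true_protein, character(1)),
    stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, truth = truth)
}

#' Write a synthetic genome bundle to disk
#'
#' Emits FASTA + GFF3 + a truth JSON so the fixture can be consumed by the
#' command-line pipeline exactly like real data.
#'
#' @param bundle Result of [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named paths, invisibly.
#' @export
write_synthetic_genome <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genes.gff3")
  truth <- file.path(dir, "truth.json")
  seqs <- Biostrings::DNAStringSet(bundle$genome$sequence)
  names(seqs) <- bundle$genome$id
  Biostrings::writeXStringSet(seqs, fasta)
  write_gff3(bundle$genes, gff, seqid = bundle$genome$id)
  jsonlite::write_json(bundle$truth, truth, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(c(fasta = fasta, gff3 = gff, truth = truth))
}

#' Simulate lacZ-alpha colony counts from a known true error rate
#'
#' Each colony is an independent Bernoulli trial: a sample colony is mutant
#' with probability \code{true_er * bp * d + mf_background}, a background
#' colony with probability \code{mf_background}. This is exactly the model
#' under which the point estimator \code{ER = (mf - mf_bg)/(bp d)} is
#' unbiased, so parameter recovery on these simulations checks the
#' estimator, not the biology of plasmid transformation.
#'
#' @param true_er True error rate in errors per base per template doubling.
#' @param bp,d Assay parameters (scorable target size, template doublings).
#' @param n_colonies Colonies plated per replicate (background included).
#' @param mf_background Background mutation frequency.
#' @param n_replicates Number of sample replicates.
#' @param seed Integer seed.
#' @param label Sample label prefix; replicates become label-1, label-2, ...
#' @return List with \code{counts} (data frame in the fidelity input
#'   schema, including one \code{Background} row) and \code{truth} (the
#'   simulation spec).
#' @export
simulate_colony_counts <- function(true_er, bp = 345, d = 12,
                                   n_colonies = 10000L,
                                   mf_background = 0.0061,
                                   n_replicates = 5L, seed,
                                   label = "Sample") {
  p <- true_er * bp * d + mf_background
  if (p > 1) stop("implied mutation frequency ", signif(p, 4), " exceeds 1",
                  call. = FALSE)
  if (true_er < 0 || mf_background < 0 || mf_background > 1) {
    stop("invalid simulation spec", call. = FALSE)
  }
  set.seed(seed)
  mut <- stats::rbinom(n_replicates, n_colonies, p)
  bg <- stats::rbinom(1L, n_colonies, mf_background)
  counts <- data.frame(
    label = c(sprintf("%s-%d", label, seq_len(n_replicates)), "Background"),
    total_colonies = rep(n_colonies, n_replicates + 1L),
    mutant_colonies = c(mut, bg),
    stringsAsFactors = FALSE)
  list(counts = counts,
       truth = list(true_er = true_er, bp = bp, d = d,
                    n_colonies = n_colonies, mf_background = mf_background,
                    n_replicates = n_replicates, seed = seed))
}

#' Synthetic reconstruction of the A. pernix polB1/polB3 upstream regions
#'
#' Builds a small synthetic genome carrying two genes configured like the
#' re-annotated A. pernix polymerase loci: a polB1-like gene whose upstream
#' frame holds a TTG 58 codons and a GTG 36 codons before the annotated
#' ATG (no interrupting stop), and a polB3-like gene (placed on the minus
#' strand) with a single TTG 19 codons upstream, each candidate preceded by
#' an SD consensus in the -15..-4 window. The flanking and coding sequence
#' is random GC-rich background, not genomic sequence: this is a synthetic
#' stand-in that encodes the documented gene architecture, suitable for
#' validating the scan and its extension-counting convention.
#'
#' @param seed Integer seed (fixed default so the loci are reproducible).
#' @return As [generate_genome()]: list of \code{genome}, \code{genes},
#'   \code{truth}.
#' @export
synthetic_polb_loci <- function(seed = 20180416L) {
  spec <- data.frame(
    gene_id = c("polB1_synthetic", "polB3_synthetic"),
    extension_aa = c(58L, 19L),
    codon = c("TTG", "TTG"),
    secondary_ext = c(36L, NA),
    secondary_codon = c("GTG", NA),
    strand = c("+", "-"),
    sd_offset = c(-10L, -9L),
    cds_codons = c(80L, 60L),
    stringsAsFactors = FALSE)
  generate_genome(truth_spec = spec, length = 1500L, seed = seed, gc = 0.56)
}
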