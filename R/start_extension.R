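# Upstream in-frame alternative-start scanning.
#
# The scan walks upstream of an annotated start codon-by-codon, in frame,
# recording every codon from the allowed initiator set until the first
# in-frame stop (TAA/TAG/TGA), the window limit, or the genome edge. Each
# recorded candidate defines an N-terminally extended ORF; Shine-Dalgarno
# evidence is scored in the -15..-4 window of each candidate.

#' Scan upstream of an annotated start for in-frame alternative initiators
#'
#' @param genome A [genome_record()].
#' @param gene A single-row [gene_model()].
#' @param allowed_starts Codon set accepted as initiators. The default
#'   includes ATG for generality; pass \code{c("TTG", "GTG")} to search only
#'   the alternative initiators upstream of an ATG-annotated gene, as in the
#'   A. pernix polB re-annotation.
#' @param max_extension_codons Upstream window in codons (default 200,
#'   larger than any plausible missed N-terminus).
#' @param sd_consensus,sd_min_score Passed to [find_sd()] for each candidate.
#' @return A data frame of candidates ordered from most to least upstream,
#'   with columns \code{codon}, \code{extension_aa} (codons gained,
#'   candidate start counted as one residue), \code{genomic_offset} (0-based
#'   plus-strand position of the leftmost base of the candidate codon),
#'   \code{sd_offset}, \code{sd_seq}, \code{sd_score}, \code{sd_truncated},
#'   and \code{g_at_minus3}. Scan warnings (unusual annotated start codon,
#'   ambiguous N codons treated as matching nothing) are attached as the
#'   \code{"warnings"} attribute; the gene id as \code{"gene_id"}.
#' @export
scan_upstream_starts <- function(genome, gene,
                                 allowed_starts = c("ATG", "GTG", "TTG"),
                                 max_extension_codons = 200L,
                                 sd_consensus = "GGAGG", sd_min_score = 4L) {
  stopifnot(max_extension_codons >= 1L)
  allowed_starts <- toupper(allowed_starts)
  warnings <- character()

  anno <- gene$annotated_start_codon[1L]
  if (is.na(anno)) {
    anno <- start_codon_of(genome, gene$start[1L], gene$end[1L], gene$strand[1L])
  }
  if (!anno %in% START_CODONS) {
    warnings <- c(warnings, sprintf(
      "annotated start codon %s of %s is not ATG/GTG/TTG", anno,
      gene$gene_id[1L]))
  }

  # one extraction covers the whole scan window plus the 15-base SD window
  # of the most upstream possible candidate
  want <- 3L * as.integer(max_extension_codons) + 15L
  if (genome$topology == "circular") want <- min(want, genome$length - 1L)
  up <- extract_upstream(genome, gene, want)
  L <- nchar(up)

  rows <- list()
  k <- 0L
  repeat {
    k <- k + 1L
    if (k > max_extension_codons) break
    lo <- L - 3L * k + 1L
    if (lo < 1L) break  # genome edge: incomplete codon ends the scan
    codon <- substr(up, lo, lo + 2L)
    if (grepl("N", codon, fixed = TRUE)) {
      warnings <- c(warnings, sprintf(
        "codon %s at extension %d contains N; treated as neither start nor stop",
        codon, k))
      next
    }
    if (codon %in% STOP_CODONS) break
    if (codon %in% allowed_starts) {
      cand_up <- substr(up, max(1L, lo - 15L), lo - 1L)
      sd <- find_sd(cand_up, consensus = sd_consensus, min_score = sd_min_score)
      rows[[length(rows) + 1L]] <- data.frame(
        codon = codon,
        extension_aa = k,
        genomic_offset = if (gene$strand[1L] == "+")
          gene$start[1L] - 3L * k else gene$end[1L] + 3L * k - 3L,
        sd_offset = if (is.null(sd)) NA_integer_ else sd$offset,
        sd_seq = if (is.null(sd)) NA_character_ else sd$matched_seq,
        sd_score = if (is.null(sd)) NA_integer_ else sd$score,
        sd_truncated = if (is.null(sd)) NA else sd$truncated,
        g_at_minus3 = if (nchar(cand_up) >= 3L) g_at_minus3(cand_up) else NA,
        stringsAsFactors = FALSE
      )
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(codon = character(), extension_aa = integer(),
               genomic_offset = integer(), sd_offset = integer(),
               sd_seq = character(), sd_score = integer(),
               sd_truncated = logical(), g_at_minus3 = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(-out$extension_aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gene_id") <- gene$gene_id[1L]
  attr(out, "warnings") <- warnings
  out
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param dna Coding sequence, length a multiple of 3, optionally ending in
#'   a stop codon (which is not translated). Codons containing N translate
#'   to \code{X}.
#' @param initiator_as_met Report position 1 as M regardless of the literal
#'   codon, as the initiator tRNA does for GTG/TTG starts.
#' @return Amino-acid string.
#' @export
translate_cds <- function(dna, initiator_as_met = FALSE) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  n_cod <- length(aa)
  internal_stop <- which(aa[-n_cod] == "*")
  if (length(internal_stop)) {
    stop("internal stop codon at codon ", internal_stop[1L], call. = FALSE)
  }
  if (aa[n_cod] == "*") aa <- aa[-n_cod]
  if (initiator_as_met && length(aa)) aa[1L] <- "M"
  paste(aa, collapse = "")
}

#' Build the extended-ORF report for one gene
#'
#' The chosen form is the most-upstream candidate (the "long" form, by
#' analogy with the L/M/S naming of the A. pernix polymerase constructs);
#' its translation initiates at the candidate codon, reported as methionine.
#'
#' @param genome A [genome_record()].
#' @param gene A single-row [gene_model()].
#' @param candidates Candidate table from [scan_upstream_starts()]; computed
#'   here when \code{NULL}.
#' @param ... Passed to [scan_upstream_starts()] when candidates are
#'   computed internally.
#' @return A list of class \code{extension_report}: \code{gene_id},
#'   \code{candidates}, \code{chosen} (single-row data frame or \code{NULL}),
#'   \code{extension_aa} (0 when no candidate), \code{extended_protein},
#'   \code{annotated_protein}, \code{initiator_literal} (literal translation
#'   of the chosen initiator codon), and \code{warnings}.
#' @export
build_extension_report <- function(genome, gene, candidates = NULL, ...) {
  if (is.null(candidates)) {
    candidates <- scan_upstream_starts(genome, gene, ...)
  }
  cds <- cds_sequence(genome, gene)
  # the annotated frame must be clean before any extension is proposed
  annotated_protein <- tryCatch(
    translate_cds(cds, initiator_as_met = TRUE),
    error = function(e) stop("gene ", gene$gene_id[1L], ": ",
                             conditionMessage(e), call. = FALSE))
  warnings <- attr(candidates, "warnings")
  if (nrow(candidates) == 0L) {
    rep <- list(gene_id = gene$gene_id[1L], candidates = candidates,
                chosen = NULL, extension_aa = 0L,
                extended_protein = annotated_protein,
                annotated_protein = annotated_protein,
                initiator_literal = substr(annotated_protein, 1L, 1L),
                warnings = warnings)
    class(rep) <- "extension_report"
    return(rep)
  }
  chosen <- candidates[1L, , drop = FALSE]
  ext_nt <- extract_upstream(genome, gene, 3L * chosen$extension_aa)
  ext_cds <- paste0(ext_nt, cds)
  extended_protein <- translate_cds(ext_cds, initiator_as_met = TRUE)
  rep <- list(gene_id = gene$gene_id[1L], candidates = candidates,
              chosen = chosen, extension_aa = chosen$extension_aa,
              extended_protein = extended_protein,
              annotated_protein = annotated_protein,
              initiator_literal =
                unname(Biostrings::GENETIC_CODE[chosen$codon]),
              warnings = warnings)
  class(rep) <- "extension_report"
  rep
}

#' @export
print.extension_report <- function(x, ...) {
  cat(sprintf("<extension_report> %s: %d candidate(s)", x$gene_id,
              nrow(x$candidates)))
  if (!is.null(x$chosen)) {
    cat(sprintf("; chosen %s, +%d aa", x$chosen$codon, x$extension_aa))
  }
  cat("\n")
  if (nrow(x$candidates)) print(x$candidates)
  invisible(x)
}

# Coding-strand CDS sequence of a gene (annotated start through stop).
cds_sequence <- function(genome, gene) {
  s <- genome_subseq(genome, gene$start[1L], gene$end[1L])
  if (gene$strand[1L] == "-") s <- revcomp(s)
  s
}

#' Scan a batch of genes
#'
#' Genes failing per-gene validation (e.g. an internal stop in the annotated
#' frame) yield a report carrying an \code{error} field instead of aborting
#' the batch.
#'
#' @param genome A [genome_record()].
#' @param genes A [gene_model()] data frame.
#' @param ... Passed to [build_extension_report()].
#' @return List of \code{extension_report} objects, one per gene, in input
#'   order.
#' @export
scan_all <- function(genome, genes, ...) {
  lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, , drop = FALSE]
    tryCatch(build_extension_report(genome, gene, ...),
             error = function(e) {
               rep <- list(gene_id = gene$gene_id, candidates = NULL,
                           chosen = NULL, extension_aa = NA_integer_,
                           extended_protein = NA_character_,
                           annotated_protein = NA_character_,
                           initiator_literal = NA_character_,
                           warnings = character(),
                           error = conditionMessage(e))
               class(rep) <- "extension_report"
               rep
             })
  })
}

#' Tabulate extension reports for TSV output
#'
#' One row per candidate (or a single row for genes without candidates),
#' with genomic positions converted to 1-based for output.
#'
#' @param reports List of \code{extension_report} objects.
#' @return A data frame with columns \code{gene_id}, \code{rank},
#'   \code{codon}, \code{extension_aa}, \code{position} (1-based),
#'   \code{sd_offset}, \code{sd_seq}, \code{sd_score}, \code{g_at_minus3},
#'   \code{chosen}, \code{error}.
#' @export
extension_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (!is.null(r$error) || is.null(r$candidates) || nrow(r$candidates) == 0L) {
      return(data.frame(gene_id = r$gene_id, rank = NA_integer_,
                        codon = NA_character_, extension_aa = 0L,
                        position = NA_integer_, sd_offset = NA_integer_,
                        sd_seq = NA_character_, sd_score = NA_integer_,
                        g_at_minus3 = NA, chosen = FALSE,
                        error = if (is.null(r$error)) NA_character_ else r$error,
                        stringsAsFactors = FALSE))
    }
    cc <- r$candidates
    data.frame(gene_id = r$gene_id, rank = seq_len(nrow(cc)),
               codon = cc$codon, extension_aa = cc$extension_aa,
               position = cc$genomic_offset + 1L, sd_offset = cc$sd_offset,
               sd_seq = cc$sd_seq, sd_score = cc$sd_score,
               g_at_minus3 = cc$g_at_minus3,
               chosen = seq_len(nrow(cc)) == 1L, error = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write extended proteins as FASTA
#'
#' Headers carry an \code{|ext<N>} suffix giving the number of added
#' residues of the chosen form (0 when the annotated form stands).
#'
#' @param reports List of \code{extension_report} objects.
#' @param path Output FASTA path.
#' @export
write_extended_fasta <- function(reports, path) {
  ok <- Filter(function(r) is.null(r$error), reports)
  seqs <- vapply(ok, function(r) r$extended_protein, character(1))
  names(seqs) <- vapply(ok, function(r)
    sprintf("%s|ext%d", r$gene_id, r$extension_aa), character(1))
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
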