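# Genome and annotation input/output.
#
# Internal coordinate convention: 0-based half-open intervals stored on the
# plus strand, with a `strand` field giving the coding orientation. GFF3
# (1-based inclusive) and GenBank location strings are converted at the
# boundary; all user-facing TSV reports are 1-based.

STOP_CODONS  <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

#' Construct a genome record
#'
#' A genome record holds one chromosome or plasmid sequence as an uppercase
#' string over \code{A,C,G,T,N}, together with its topology. Circular
#' topology permits coordinate arithmetic modulo the genome length, which
#' matters when extracting sequence upstream of a gene near the origin.
#'
#' @param id Sequence identifier.
#' @param sequence DNA sequence (character scalar or \code{DNAString}).
#'   Lower-case input is normalised to upper case.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class \code{genome_record} with fields \code{id},
#'   \code{sequence}, \code{topology} and \code{length}.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("genome sequence is empty", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("genome sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  }
  structure(
    list(id = as.character(id), sequence = sequence, topology = topology,
         length = nchar(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Read a genome sequence from FASTA or GenBank
#'
#' FASTA genomes default to linear topology; circularity must be declared
#' explicitly with \code{circular = TRUE} (silent wraparound would create
#' phantom upstream extensions). GenBank files carry topology on their LOCUS
#' line, which is respected.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"genbank"`.
#' @param record For multi-record FASTA files, the id of the record to load.
#'   With more than one record and no selector the reader refuses, listing
#'   the available ids.
#' @param circular Declare a FASTA genome circular. Ignored for GenBank.
#' @return A [genome_record()].
#' @export
read_genome <- function(path, format = c("fasta", "genbank"), record = NULL,
                        circular = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "fasta") {
    seqs <- withCallingHandlers(
      tryCatch(Biostrings::readDNAStringSet(path),
               error = function(e) stop("cannot parse FASTA file '", path,
                                        "': ", conditionMessage(e),
                                        call. = FALSE)),
      warning = function(w) {
        # Biostrings silently drops letters outside the DNA alphabet; a
        # corrupted genome must be an error, not a shorter sequence
        if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
          stop("FASTA file '", path, "' contains characters outside the ",
               "DNA alphabet", call. = FALSE)
        }
        invokeRestart("muffleWarning")
      })
    if (length(seqs) == 0L) stop("FASTA file contains no records", call. = FALSE)
    ids <- sub("\\s.*$", "", names(seqs))
    if (is.null(record)) {
      if (length(seqs) > 1L) {
        stop("FASTA file has ", length(seqs),
             " records; pass `record` to select one of: ",
             paste(ids, collapse = ", "), call. = FALSE)
      }
      record <- ids[1L]
    }
    i <- match(record, ids)
    if (is.na(i)) stop("record '", record, "' not found; available: ",
                       paste(ids, collapse = ", "), call. = FALSE)
    genome_record(ids[i], as.character(seqs[[i]]),
                  topology = if (circular) "circular" else "linear")
  } else {
    gb <- parse_genbank(path)
    genome_record(gb$id, gb$sequence, topology = gb$topology)
  }
}

#' Construct gene models
#'
#' @param gene_id Character vector of gene identifiers.
#' @param start,end 0-based half-open plus-strand interval of the CDS
#'   (including the stop codon when annotated, as in GFF3/GenBank CDS
#'   features).
#' @param strand `"+"` or `"-"`.
#' @param genome Optional [genome_record()]; when supplied, the annotated
#'   start codon is read off the genome and stored, and coordinates are
#'   bounds-checked for linear genomes.
#' @return A data frame of class \code{gene_model} with one row per gene:
#'   \code{gene_id}, \code{start}, \code{end}, \code{strand},
#'   \code{annotated_start_codon}, \code{length_flag} (TRUE when the CDS
#'   length is not a multiple of 3).
#' @export
gene_model <- function(gene_id, start, end, strand, genome = NULL) {
  n <- length(gene_id)
  stopifnot(length(start) == n, length(end) == n, length(strand) == n)
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stop("gene end must exceed start", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  length_flag <- ((end - start) %% 3L) != 0L
  if (any(length_flag)) {
    warning("CDS length not divisible by 3 for: ",
            paste(gene_id[length_flag], collapse = ", "),
            " (retained with length_flag)", call. = FALSE)
  }
  codon <- rep(NA_character_, n)
  if (!is.null(genome)) {
    if (genome$topology == "linear" &&
        (any(start < 0L) || any(end > genome$length))) {
      bad <- which(start < 0L | end > genome$length)
      stop("gene(s) out of genome bounds on a linear genome: ",
           paste(gene_id[bad], collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(n)) {
      codon[i] <- start_codon_of(genome, start[i], end[i], strand[i])
    }
  }
  structure(
    data.frame(gene_id = as.character(gene_id), start = start, end = end,
               strand = strand, annotated_start_codon = codon,
               length_flag = length_flag, stringsAsFactors = FALSE),
    class = c("gene_model", "data.frame")
  )
}

# Start-codon 3-mer at the coding-strand start of a 0-based half-open interval.
start_codon_of <- function(genome, start, end, strand) {
  if (strand == "+") {
    genome_subseq(genome, start, start + 3L)
  } else {
    revcomp(genome_subseq(genome, end - 3L, end))
  }
}

#' Read gene annotations from GFF3 or GenBank
#'
#' Only CDS features are used. Coordinates are converted to the internal
#' 0-based half-open plus-strand convention. A CDS whose length is not a
#' multiple of 3 is retained and flagged with a warning rather than dropped.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @param genome Optional [genome_record()] used to bounds-check coordinates
#'   and record the annotated start codons.
#' @return A [gene_model()] data frame.
#' @export
read_annotations <- function(path, format = c("gff3", "genbank"),
                             genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "cds"]
    if (length(gr) == 0L) stop("no CDS features in ", path, call. = FALSE)
    meta <- S4Vectors::mcols(gr)
    pick <- function(col) if (col %in% colnames(meta)) as.character(meta[[col]]) else rep(NA_character_, length(gr))
    id <- pick("locus_tag")
    for (col in c("ID", "Name", "gene")) {
      alt <- pick(col)
      id <- ifelse(is.na(id) | !nzchar(id), alt, id)
    }
    id[is.na(id)] <- paste0("cds_", seq_along(gr))[is.na(id)]
    gene_model(id,
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               genome = genome)
  } else {
    gb <- parse_genbank(path)
    if (nrow(gb$cds) == 0L) stop("no CDS features in ", path, call. = FALSE)
    if (is.null(genome) && nzchar(gb$sequence)) {
      genome <- genome_record(gb$id, gb$sequence, gb$topology)
    }
    gene_model(gb$cds$gene_id, gb$cds$start, gb$cds$end, gb$cds$strand,
               genome = genome)
  }
}

#' Write gene models to GFF3
#'
#' Writes one CDS line per gene, converting internal 0-based half-open
#' coordinates back to GFF3's 1-based inclusive convention. Reading the file
#' back with [read_annotations()] reproduces the internal coordinates.
#'
#' @param genes A [gene_model()] data frame.
#' @param path Output path.
#' @param seqid Sequence id for column 1.
#' @export
write_gff3 <- function(genes, path, seqid = "genome") {
  lines <- c("##gff-version 3",
             sprintf("%s\torfex\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
                     seqid, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Extract sequence immediately upstream of a gene's annotated start
#'
#' Returns the \code{n_bases} bases immediately 5' of the annotated start
#' codon on the coding strand (reverse-complemented for minus-strand genes).
#' On a linear genome the window is truncated at the edge; on a circular
#' genome it wraps around the origin. A short return is legal, never an
#' error.
#'
#' @param genome A [genome_record()].
#' @param gene A single-row [gene_model()] (or list with `start`, `end`,
#'   `strand`).
#' @param n_bases Number of bases requested (>= 0).
#' @return A character string of at most \code{n_bases} bases, 5' to 3' on
#'   the coding strand, ending at position -1 relative to the start codon.
#' @export
extract_upstream <- function(genome, gene, n_bases) {
  stopifnot(n_bases >= 0)
  n_bases <- as.integer(n_bases)
  if (n_bases == 0L) return("")
  if (gene$strand[1L] == "+") {
    from <- gene$start[1L] - n_bases
    to <- gene$start[1L]
    if (genome$topology == "linear") from <- max(0L, from)
    genome_subseq(genome, from, to)
  } else {
    from <- gene$end[1L]
    to <- gene$end[1L] + n_bases
    if (genome$topology == "linear") to <- min(genome$length, to)
    revcomp(genome_subseq(genome, from, to))
  }
}

# 0-based half-open substring with circular wrap-around. For circular
# genomes any window narrower than the genome is legal; offsets are reduced
# modulo length.
genome_subseq <- function(genome, from, to) {
  if (to <= from) return("")
  L <- genome$length
  if (genome$topology == "linear") {
    if (from < 0L || to > L) {
      stop("coordinates [", from, ",", to, ") outside linear genome of length ",
           L, call. = FALSE)
    }
    return(substr(genome$sequence, from + 1L, to))
  }
  if (to - from > L) stop("window longer than circular genome", call. = FALSE)
  width <- to - from
  idx_from <- ((from %% L) + L) %% L
  idx_to <- idx_from + width
  if (idx_to <= L) {
    substr(genome$sequence, idx_from + 1L, idx_to)
  } else {
    paste0(substr(genome$sequence, idx_from + 1L, L),
           substr(genome$sequence, 1L, idx_to - L))
  }
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over A,C,G,T,N.
#' @return The reverse complement, same case.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---- minimal GenBank flat-file parsing ------------------------------------
# Scope: LOCUS topology, ORIGIN sequence, and CDS features with simple
# `a..b` / `complement(a..b)` locations plus /locus_tag and /gene
# qualifiers. join() locations are outside the package's remit and are
# skipped with a warning.

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ",
                                path, call. = FALSE)
  topology <- if (grepl("\\bcircular\\b", locus[1L], ignore.case = TRUE))
    "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus[1L])), "\\s+")[[1L]][1L]

  origin <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(origin)) {
    endrec <- grep("^//", lines)
    endrec <- endrec[endrec > origin[1L]][1L]
    if (is.na(endrec)) endrec <- length(lines) + 1L
    body <- lines[(origin[1L] + 1L):(endrec - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }

  feat_start <- grep("^FEATURES", lines)
  cds <- data.frame(gene_id = character(), start = integer(), end = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  if (length(feat_start)) {
    stop_at <- c(grep("^ORIGIN", lines), grep("^CONTIG", lines),
                 length(lines) + 1L)
    stop_at <- min(stop_at[stop_at > feat_start[1L]])
    flines <- lines[(feat_start[1L] + 1L):(stop_at - 1L)]
    # a feature starts at column 6; continuation/qualifier lines are deeper
    is_key <- grepl("^ {5}\\S", flines)
    key_idx <- which(is_key)
    for (k in seq_along(key_idx)) {
      first <- key_idx[k]
      last <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(flines)
      key <- sub("^\\s+", "", substr(flines[first], 1, 20))
      key <- strsplit(key, "\\s+")[[1L]][1L]
      if (!identical(key, "CDS")) next
      block <- flines[first:last]
      loc <- sub("^\\s*CDS\\s+", "", block[1L])
      # location may continue onto lines before the first qualifier
      qual_start <- grep("^\\s+/", block)
      loc_end <- if (length(qual_start)) qual_start[1L] - 1L else length(block)
      if (loc_end > 1L) {
        loc <- paste0(loc, paste(trimws(block[2:loc_end]), collapse = ""))
      }
      parsed <- parse_gb_location(loc)
      if (is.null(parsed)) {
        warning("skipping CDS with unsupported location: ", loc, call. = FALSE)
        next
      }
      qual <- paste(block, collapse = " ")
      gid <- gb_qualifier(qual, "locus_tag")
      if (is.na(gid)) gid <- gb_qualifier(qual, "gene")
      if (is.na(gid)) gid <- sprintf("cds_%d", nrow(cds) + 1L)
      cds <- rbind(cds, data.frame(gene_id = gid, start = parsed$start,
                                   end = parsed$end, strand = parsed$strand,
                                   stringsAsFactors = FALSE))
    }
  }
  list(id = id, sequence = seq, topology = topology, cds = cds)
}

# `a..b` or `complement(a..b)` (with optional <,> partial markers) to
# 0-based half-open plus-strand coordinates.
parse_gb_location <- function(loc) {
  loc <- gsub("\\s|[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc)) return(NULL)
  ab <- as.integer(strsplit(loc, "\\.\\.", fixed = FALSE)[[1L]])
  list(start = ab[1L] - 1L, end = ab[2L], strand = strand)
}

gb_qualifier <- function(text, name) {
  m <- regmatches(text, regexec(sprintf('/%s="([^"]*)"', name), text))[[1L]]
  if (length(m) == 2L) m[2L] else NA_character_
}
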