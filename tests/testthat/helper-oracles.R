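# Independent oracles, written against plain strings with their own index
# arithmetic so they share no code path with the package internals.

oracle_revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Enumerate every in-frame codon upstream of `start0` (0-based plus-strand
# first base of the annotated start codon, coding strand given by `strand`)
# and return the extension sizes of all allowed starts before the first
# stop, most upstream first. Linear genome.
oracle_upstream_scan <- function(genome_seq, start0, end0, strand,
                                 allowed = c("TTG", "GTG"), max_k = 200) {
  if (strand == "-") {
    L <- nchar(genome_seq)
    genome_seq <- oracle_revcomp(genome_seq)
    # mirrored coordinates: plus-strand [s,e) becomes [L-e, L-s)
    s <- L - end0
    start0 <- s
  }
  found <- integer()
  for (k in seq_len(max_k)) {
    lo <- start0 - 3 * k  # 0-based
    if (lo < 0) break
    codon <- substr(genome_seq, lo + 1, lo + 3)
    if (codon %in% c("TAA", "TAG", "TGA")) break
    if (codon %in% allowed) found <- c(found, k)
  }
  rev(found)
}

# Exhaustive SD search: all alignment offsets of the consensus inside the
# -15..-4 window, longest identity run each, deepest alignment wins ties.
oracle_find_sd <- function(upstream, consensus = "GGAGG", min_score = 4) {
  upstream <- toupper(upstream)
  L <- nchar(upstream)
  cl <- nchar(consensus)
  best <- NULL
  for (o in seq(min(15, L), 4 + cl - 1)) {
    if (o < cl + 3) break
    seg <- substr(upstream, L - o + 1, L - o + cl)
    if (nchar(seg) < cl) next
    hits <- strsplit(seg, "")[[1]] == strsplit(consensus, "")[[1]]
    # longest run and its first position
    len <- 0; start <- 0; cur <- 0
    for (i in seq_along(hits)) {
      if (hits[i]) {
        cur <- cur + 1
        if (cur > len) { len <- cur; start <- i - cur + 1 }
      } else cur <- 0
    }
    if (len > 0 && (is.null(best) || len > best$score)) {
      best <- list(offset = -(o - start + 1),
                   matched_seq = substr(seg, start, start + len - 1),
                   score = len)
    }
  }
  if (is.null(best) || best$score < min_score) NULL else best
}

# A random linear genome with one gene in a random position and strand.
# The upstream context is unconstrained, which is the point: the scan and
# the brute-force oracle must agree on arbitrary sequence.
random_gene_fixture <- function(cds_codons = 10, pad = 120) {
  bases <- c("A", "C", "G", "T")
  cds <- paste0("ATG",
                paste(sample(setdiff(orfex_all_codons(),
                                     c("TAA", "TAG", "TGA")),
                             cds_codons - 2, replace = TRUE), collapse = ""),
                "TAA")
  left <- paste(sample(bases, pad, replace = TRUE), collapse = "")
  right <- paste(sample(bases, sample(5:30, 1), replace = TRUE), collapse = "")
  strand <- sample(c("+", "-"), 1)
  seq_plus <- paste0(left, cds, right)
  if (strand == "-") {
    L <- nchar(seq_plus)
    s_cod <- nchar(left)              # 0-based coding-orientation start
    e_cod <- s_cod + nchar(cds)
    genome_seq <- oracle_revcomp(seq_plus)
    start0 <- L - e_cod
    end0 <- L - s_cod
  } else {
    genome_seq <- seq_plus
    start0 <- nchar(left)
    end0 <- start0 + nchar(cds)
  }
  list(genome = genome_record("rand", genome_seq),
       gene = gene_model("g1", start0, end0, strand),
       strand = strand)
}

orfex_all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
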