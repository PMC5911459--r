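# Shine-Dalgarno motif detection.
#
# Positions are counted on the coding strand relative to the first base of
# the start codon: -1 is the base immediately 5' of it. In A. pernix,
# structural genes are typically preceded by an SD box between positions
# -15 and -4, and show a marked enrichment of G at position -3; both signals
# are scored here per candidate start.

#' Find the best Shine-Dalgarno match upstream of a start codon
#'
#' Scores every ungapped alignment of the consensus within the fixed window
#' at positions -15..-4 and reports the longest run of consecutive identical
#' bases at the best alignment. This deliberately simple scheme (rather than
#' a 16S rRNA hybridisation free-energy model) keeps the detector
#' reproducible and configurable; the consensus defaults to \code{GGAGG},
#' with purine-rich alternates such as \code{AGGAGG} selectable.
#'
#' @param upstream DNA string oriented 5' to 3', ending at position -1
#'   (the base immediately before the start codon). Should be at least 15
#'   bases; shorter windows are scored over what is available and flagged
#'   \code{truncated}.
#' @param consensus SD consensus sequence.
#' @param min_score Minimum run length for a reported match (default 4).
#' @param window Integer pair giving the search window in negative
#'   coordinates; the default \code{c(-15, -4)} is the region where
#'   A. pernix structural genes carry their SD boxes.
#' @return \code{NULL} when no alignment reaches \code{min_score}; otherwise
#'   a list of class \code{sd_match} with \code{offset} (negative position
#'   of the first matched base), \code{matched_seq} (the matched run),
#'   \code{score} (run length) and \code{truncated}.
#' @export
find_sd <- function(upstream, consensus = "GGAGG", min_score = 4L,
                    window = c(-15L, -4L)) {
  upstream <- toupper(upstream)
  L <- nchar(upstream)
  cl <- nchar(consensus)
  truncated <- L < abs(window[1L])
  # deepest alignment offset: consensus start at position -o, o <= 15
  o_max <- min(abs(window[1L]), L)
  # shallowest: the consensus must end at or before position -4
  o_min <- abs(window[2L]) + cl - 1L
  if (o_max < o_min) return(NULL)
  cons <- strsplit(consensus, "")[[1L]]
  best <- NULL
  for (o in seq(o_max, o_min)) {  # most upstream first: wins ties
    # consensus base i sits at position -(o - i + 1) = upstream index L-o+i
    idx <- L - o + seq_len(cl)
    win <- strsplit(substr(upstream, idx[1L], idx[cl]), "")[[1L]]
    hit <- win == cons
    run <- longest_run(hit)
    if (run$length == 0L) next
    if (is.null(best) || run$length > best$score) {
      best <- list(
        offset = -(o - run$start + 1L),
        matched_seq = substr(upstream, idx[run$start],
                             idx[run$start] + run$length - 1L),
        score = run$length,
        truncated = truncated
      )
    }
  }
  if (is.null(best) || best$score < min_score) return(NULL)
  class(best) <- "sd_match"
  best
}

#' @export
print.sd_match <- function(x, ...) {
  cat(sprintf("<sd_match> %s at %d (score %d%s)\n", x$matched_seq, x$offset,
              x$score, if (isTRUE(x$truncated)) ", truncated window" else ""))
  invisible(x)
}

# First maximal run of TRUE, scanning from the upstream (left) end.
longest_run <- function(hit) {
  best_len <- 0L; best_start <- 0L; cur <- 0L
  for (i in seq_along(hit)) {
    if (hit[i]) {
      cur <- cur + 1L
      if (cur > best_len) {
        best_len <- cur
        best_start <- i - cur + 1L
      }
    } else cur <- 0L
  }
  list(length = best_len, start = best_start)
}

#' Is the base at position -3 a G?
#'
#' The enrichment of G three bases upstream of the initiation codon is a
#' species-level signature of A. pernix translation starts and is reported
#' alongside SD evidence for every candidate.
#'
#' @param upstream DNA string ending at position -1, length >= 3.
#' @return \code{TRUE} iff position -3 is G.
#' @export
g_at_minus3 <- function(upstream) {
  L <- nchar(upstream)
  if (L < 3L) stop("upstream window shorter than 3 bases", call. = FALSE)
  substr(toupper(upstream), L - 2L, L - 2L) == "G"
}
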