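# lacZ-alpha blue/white PCR fidelity statistics.
#
# A target fragment carrying lacZ-alpha is amplified, re-cloned, and plated
# on X-gal: white and pale-blue colonies score as mutated products. The
# mutation frequency mf is the mutant fraction of colonies; the polymerase
# error rate, in errors per base per template doubling, is
#
#   ER = (mf_sample - mf_background) / (bp * d)
#
# where bp is the size of the phenotypically scorable target (345 bp for
# lacZ-alpha) and d the number of template doublings, 2^d = product/input.

#' Assay parameters for the lacZ-alpha fidelity statistic
#'
#' @param bp Scorable target size in base pairs (default 345, the
#'   lacZ-alpha region whose mutations abolish alpha-complementation).
#' @param d Template doublings; see [template_doublings()]. Default 12.
#' @param mf_background Mutation frequency of the re-ligated, unamplified
#'   control.
#' @param confirmed_fraction Fraction of white colonies confirmed (by colony
#'   PCR) to carry an insert; scales mutant counts. Default 1.
#' @return A list of class \code{assay_parameters}.
#' @export
assay_parameters <- function(bp = 345, d = 12, mf_background = 0,
                             confirmed_fraction = 1) {
  if (bp <= 0) stop("bp must be positive", call. = FALSE)
  if (d <= 0) stop("d must be positive", call. = FALSE)
  if (mf_background < 0 || mf_background > 1) {
    stop("mf_background must lie in [0,1]", call. = FALSE)
  }
  if (confirmed_fraction < 0 || confirmed_fraction > 1) {
    stop("confirmed_fraction must lie in [0,1]", call. = FALSE)
  }
  structure(list(bp = bp, d = d, mf_background = mf_background,
                 confirmed_fraction = confirmed_fraction),
            class = "assay_parameters")
}

#' Mutation frequency from colony counts
#'
#' The ratio of mutant to total colonies, optionally scaled by the fraction
#' of white colonies confirmed to carry an insert.
#'
#' @param mutant_colonies,total_colonies Colony counts.
#' @param confirmed_fraction Confirmed-insert fraction in [0,1].
#' @return Mutation frequency in [0,1]. Vectorised.
#' @export
mutation_frequency <- function(mutant_colonies, total_colonies,
                               confirmed_fraction = 1) {
  if (any(total_colonies <= 0)) {
    stop("total_colonies must be positive", call. = FALSE)
  }
  if (any(mutant_colonies < 0) || any(mutant_colonies > total_colonies)) {
    stop("mutant_colonies must lie in [0, total_colonies]", call. = FALSE)
  }
  (mutant_colonies * confirmed_fraction) / total_colonies
}

#' Template doublings from amplification yield
#'
#' Solves \code{2^d = product / start} for d.
#'
#' @param product_amount,start_amount Amounts of PCR product and starting
#'   target in the same units (mass or copies).
#' @return The number of template doublings, \code{log2(product/start)}.
#' @export
template_doublings <- function(product_amount, start_amount) {
  if (any(product_amount <= 0) || any(start_amount <= 0)) {
    stop("amounts must be positive", call. = FALSE)
  }
  log2(product_amount / start_amount)
}

#' Polymerase error rate per base per template doubling
#'
#' @param mf_sample Sample mutation frequency (vectorised).
#' @param params An [assay_parameters()] object (carries bp, d and the
#'   background mutation frequency).
#' @return Error rate(s). A sample mf below background yields a negative
#'   rate, returned as-is with a warning rather than clamped, so quality
#'   problems stay visible.
#' @export
error_rate <- function(mf_sample, params) {
  stopifnot(inherits(params, "assay_parameters"))
  er <- (mf_sample - params$mf_background) / (params$bp * params$d)
  if (any(er < 0)) {
    warning("sample mutation frequency below background: negative error rate",
            call. = FALSE)
  }
  er
}

#' Mean and spread of replicate error rates
#'
#' Replicate summaries use the population standard deviation (divisor n),
#' the convention under which the published per-group spreads of the
#' ApePolB3/PfuPolB assay are reproduced; the sample SD (divisor n-1) is
#' not.
#'
#' @param rates Non-empty numeric vector of per-replicate error rates.
#' @return List with \code{mean} and \code{spread}.
#' @export
summarize_error_rates <- function(rates) {
  if (length(rates) == 0L) stop("no error rates to summarize", call. = FALSE)
  m <- mean(rates)
  list(mean = m, spread = sqrt(mean((rates - m)^2)))
}

#' Compute a full fidelity table from colony counts
#'
#' Takes a colony-count table (one row per plating), computes per-row
#' mutation frequencies and error rates against the background row, and
#' summarises replicate groups as mean +/- population SD. Replicates are
#' grouped by label prefix: \code{ApePolB3-1} .. \code{ApePolB3-5} form
#' group \code{ApePolB3}.
#'
#' @param counts Data frame (or path to a TSV) with columns \code{label},
#'   \code{total_colonies}, \code{mutant_colonies}, and optionally
#'   \code{mf_override}. When \code{mf_override} is present and non-missing
#'   it is used as that row's mutation frequency in place of the count
#'   ratio — the route by which independently corrected published mf values
#'   enter the computation.
#' @param params An [assay_parameters()] object. When its
#'   \code{mf_background} is 0 (the default), the background is taken from
#'   the single row whose label equals \code{background_label}; that row
#'   must then exist and be unique.
#' @param background_label Label identifying the background row.
#' @return List of class \code{fidelity_result}: \code{records} (per-row
#'   data frame with \code{label}, \code{group}, counts, \code{mf},
#'   \code{er}), \code{summary} (per-group \code{n}, \code{mean_er},
#'   \code{sd_er}), and \code{params}.
#' @export
run_fidelity_table <- function(counts, params = assay_parameters(),
                               background_label = "Background") {
  if (is.character(counts) && length(counts) == 1L) {
    counts <- read_counts_tsv(counts)
  }
  need <- c("label", "total_colonies", "mutant_colonies")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    stop("counts table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(counts) == 0L) stop("counts table is empty", call. = FALSE)
  for (i in seq_len(nrow(counts))) {
    t <- counts$total_colonies[i]; m <- counts$mutant_colonies[i]
    if (is.na(t) || is.na(m) || t <= 0 || m < 0 || m > t) {
      stop("invalid colony counts at row ", i, " (label '",
           counts$label[i], "')", call. = FALSE)
    }
  }

  mf <- mutation_frequency(counts$mutant_colonies, counts$total_colonies,
                           params$confirmed_fraction)
  if ("mf_override" %in% names(counts)) {
    use <- !is.na(counts$mf_override)
    mf[use] <- counts$mf_override[use]
  }

  is_bg <- counts$label == background_label
  if (params$mf_background > 0) {
    mf_bg <- params$mf_background
  } else {
    if (sum(is_bg) == 0L) {
      stop("no background row labelled '", background_label,
           "' and no explicit mf_background", call. = FALSE)
    }
    if (sum(is_bg) > 1L) {
      stop("duplicate background rows labelled '", background_label, "'",
           call. = FALSE)
    }
    mf_bg <- mf[is_bg]
  }
  params$mf_background <- mf_bg

  er <- rep(NA_real_, nrow(counts))
  if (any(!is_bg)) er[!is_bg] <- error_rate(mf[!is_bg], params)

  records <- data.frame(
    label = counts$label,
    group = sub("-[0-9]+$", "", counts$label),
    total_colonies = counts$total_colonies,
    mutant_colonies = counts$mutant_colonies,
    mf = mf, er = er, stringsAsFactors = FALSE)

  groups <- unique(records$group[!is_bg])
  summary <- do.call(rbind, lapply(groups, function(g) {
    r <- records$er[records$group == g & !is_bg]
    s <- summarize_error_rates(r)
    data.frame(group = g, n = length(r), mean_er = s$mean, sd_er = s$spread,
               stringsAsFactors = FALSE)
  }))

  structure(list(records = records, summary = summary, params = params),
            class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat("<fidelity_result>\n")
  rec <- x$records
  rec$mf <- sprintf("%.4f", rec$mf)
  rec$er <- ifelse(is.na(x$records$er), "",
                   formatC(x$records$er, format = "e", digits = 1))
  print(rec, row.names = FALSE)
  cat(sprintf("\nbp = %g, d = %g, background mf = %.4f\n",
              x$params$bp, x$params$d, x$params$mf_background))
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      cat(sprintf("%s: ER = %s +/- %s (n = %d)\n", x$summary$group[i],
                  formatC(x$summary$mean_er[i], format = "e", digits = 1),
                  formatC(x$summary$sd_er[i], format = "e", digits = 1),
                  x$summary$n[i]))
    }
  }
  invisible(x)
}

read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Colony counts from the ApePolB3 / PfuPolB lacZ-alpha fidelity assay
#'
#' Published per-replicate colony counts comparing the PCR fidelity of the
#' A. pernix PolB3 long form against P. furiosus PolB, plus the re-ligation
#' background. The \code{mf_override} column carries the published
#' per-replicate mutation frequencies, which for the polymerase samples
#' include a correction not derivable from the raw counts; downstream error
#' rates are therefore reconstructed from this column (see the methods
#' vignette).
#'
#' @return Data frame with columns \code{label}, \code{total_colonies},
#'   \code{mutant_colonies}, \code{mf_override}.
#' @export
lacz_assay_counts <- function() {
  path <- system.file("extdata", "apepolb3_pfupolb_colony_counts.tsv",
                      package = "orfex", mustWork = TRUE)
  read_counts_tsv(path)
}

#' Write a fidelity result as TSV plus a JSON summary
#'
#' @param result A \code{fidelity_result}.
#' @param tsv_path,json_path Output paths (either may be \code{NULL}).
#'   Displayed mf is rounded to 4 decimal places and ER to 2 significant
#'   figures in the TSV, matching assay reporting convention; the JSON
#'   carries full precision.
#' @export
write_fidelity_report <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    rec <- result$records
    rec$mf <- sprintf("%.4f", rec$mf)
    rec$er <- ifelse(is.na(result$records$er), "",
                     formatC(signif(result$records$er, 2), format = "e",
                             digits = 1))
    utils::write.table(rec, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(params = unclass(result$params),
           records = result$records, summary = result$summary),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(result)
}
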