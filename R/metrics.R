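# Fragment-based coverage and background error profiling over a target
# panel.

#' @noRd
pair_intervals <- function(tbl) {
  w1 <- cigar_ref_width(tbl$cigar1)
  w2 <- cigar_ref_width(tbl$cigar2)
  tibble::tibble(
    rname = tbl$rname,
    s1 = tbl$pos1, e1 = tbl$pos1 + w1 - 1L,
    s2 = tbl$pos2, e2 = tbl$pos2 + w2 - 1L
  )
}

#' Mean fragment coverage over a target panel
#'
#' Per panel position, counts distinct templates overlapping it: the two
#' mates of a pair are one sequenced fragment, so positions covered by
#' both mates count the template once rather than twice. The mean is
#' taken over every panel position, including positions with zero depth.
#'
#' @param tbl Pair-level tibble (raw pairs or any consensus stream) with
#'   `rname`, `pos1`, `cigar1`, `pos2`, `cigar2`.
#' @param panel Panel tibble (`contig`, `start`, `end`, 1-based
#'   inclusive).
#' @return Mean fragment depth (fragments per panel position).
#' @export
fragment_coverage <- function(tbl, panel) {
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  if (nrow(tbl) == 0L) return(0)
  bad <- setdiff(unique(tbl$rname), unique(panel$contig))
  # reads on non-panel contigs are fine; a panel contig absent from the
  # data is fine too - but warn loudly if NOTHING matches
  if (length(bad) == length(unique(tbl$rname))) {
    stop("no contig shared between alignments and panel; offenders: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  iv <- pair_intervals(tbl)
  total <- 0
  for (ctg in unique(panel$contig)) {
    p <- panel[panel$contig == ctg, ]
    x <- iv[iv$rname == ctg, ]
    if (nrow(x) == 0L) next
    maxlen <- max(p$end, x$e1, x$e2)
    cov <- IRanges::coverage(IRanges::IRanges(x$s1, x$e1), width = maxlen) +
      IRanges::coverage(IRanges::IRanges(x$s2, x$e2), width = maxlen)
    os <- pmax(x$s1, x$s2); oe <- pmin(x$e1, x$e2)
    dup <- os <= oe
    if (any(dup)) {
      cov <- cov - IRanges::coverage(IRanges::IRanges(os[dup], oe[dup]),
                                     width = maxlen)
    }
    pr <- IRanges::IRanges(p$start, p$end)
    total <- total + sum(sum(IRanges::Views(cov, pr)))
  }
  total / sum(panel$end - panel$start + 1)
}

#' Consensus efficiency
#'
#' The fragment coverage of a consensus stream divided by the fragment
#' coverage of the uncollapsed reads: the number of consensus sequences
#' produced per sequenced read. An efficiency of 10% means ten reads were
#' needed per consensus sequence.
#'
#' @param cov_consensus,cov_uncollapsed Mean fragment coverages.
#' @return Proportion, or `NA` if the denominator is zero.
#' @export
efficiency <- function(cov_consensus, cov_uncollapsed) {
  ifelse(cov_uncollapsed > 0, cov_consensus / cov_uncollapsed, NA_real_)
}

#' Duplex recovery rate
#'
#' Observed DCS coverage over its theoretical expectation: since two
#' strand consensuses are consumed per duplex consensus, at most half of
#' the SSCS coverage can be recovered as DCS.
#'
#' @param cov_dcs,cov_sscs Mean fragment coverages.
#' @return `cov_dcs / (cov_sscs / 2)`, or `NA` if `cov_sscs` is zero.
#' @export
dcs_recovery <- function(cov_dcs, cov_sscs) {
  ifelse(cov_sscs > 0, cov_dcs / (cov_sscs / 2), NA_real_)
}

#' Coverage, efficiency and recovery report for a pipeline run
#'
#' When the run used Singleton Correction, the SSCS coverage includes the
#' corrected singletons (the merged single-strand consensus stream that
#' feeds duplex formation), matching how the streams are merged for
#' downstream use.
#'
#' @param run A `duplex_run`.
#' @param panel Panel tibble.
#' @return One-row tibble: `cov_uncollapsed`, `cov_sscs`, `cov_dcs`,
#'   `efficiency_sscs`, `efficiency_dcs`, `recovery_dcs`,
#'   `singleton_fraction`, `sc_rate`, `sc_event_rate`.
#' @export
coverage_report <- function(run, panel) {
  stopifnot(inherits(run, "duplex_run"))
  sscs_prov <- c("SSCS", if (run$sc) c("SC_by_SSCS", "SC_by_singleton"))
  sscs <- dplyr::filter(run$cons, .data$provenance %in% sscs_prov)
  cov_un <- fragment_coverage(run$pairs, panel)
  cov_ss <- fragment_coverage(sscs, panel)
  cov_dc <- fragment_coverage(run$dcs, panel)
  g <- glance(run)
  tibble::tibble(
    cov_uncollapsed = cov_un, cov_sscs = cov_ss, cov_dcs = cov_dc,
    efficiency_sscs = efficiency(cov_ss, cov_un),
    efficiency_dcs = efficiency(cov_dc, cov_un),
    recovery_dcs = dcs_recovery(cov_dc, cov_ss),
    singleton_fraction = g$singleton_fraction,
    sc_rate = g$sc_rate,
    sc_event_rate = g$sc_event_rate
  )
}

# ---------------------------------------------------------------------------

.sub_classes <- {
  b <- c("A", "C", "G", "T")
  unlist(lapply(b, function(r) paste0(r, ">", b[b != r])))
}

#' Selector-wide background error report
#'
#' Builds per-position base frequencies over the panel and measures the
#' background error rate: non-reference bases divided by all sequenced
#' bases within the panel. A non-reference allele reaching the allele
#' frequency ceiling at its position (default 5%) is treated as a putative
#' variant and excluded from the error numerator for that allele only; N
#' bases are excluded from both numerator and denominator. Substitutions
#' are tallied into the 12 reference>observed classes.
#'
#' @param tbl Pair-level tibble (raw pairs or any consensus stream).
#' @param reference Named character vector of contig sequences.
#' @param panel Panel tibble.
#' @param af_ceiling Alleles at or above this frequency are considered
#'   variants, not errors (the comparison for errors is strictly below).
#' @return Object of class `error_report`: total/error base counts, the
#'   error rate, the fraction of panel positions with zero non-reference
#'   observations, and the 12-class substitution count table.
#' @export
error_report <- function(tbl, reference, panel, af_ceiling = 0.05) {
  reference <- as_reference(reference)
  miss <- setdiff(panel$contig, names(reference))
  if (length(miss)) {
    stop("panel contigs missing from reference: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  panel_width <- sum(panel$end - panel$start + 1)

  freq <- base_frequencies(tbl, reference, panel)
  if (nrow(freq) == 0L) {
    counts <- tibble::tibble(class = .sub_classes, n = 0L)
    out <- list(n_bases = 0L, n_errors = 0L, error_rate = NA_real_,
                error_free_positions = 1, substitutions = counts,
                af_ceiling = af_ceiling, panel_width = panel_width)
    class(out) <- "error_report"
    return(out)
  }

  pos_tot <- dplyr::summarise(
    dplyr::group_by(freq, .data$contig, .data$pos),
    depth = sum(.data$count), .groups = "drop")
  freq <- dplyr::left_join(freq, pos_tot, by = c("contig", "pos"))
  freq$af <- freq$count / freq$depth
  nonref <- freq$base != freq$ref
  is_error <- nonref & freq$af < af_ceiling

  n_bases <- sum(freq$count)
  n_errors <- sum(freq$count[is_error])
  err_pos <- dplyr::distinct(freq[nonref, ], .data$contig, .data$pos)
  counts <- dplyr::count(
    dplyr::mutate(freq[is_error, ],
                  class = paste0(.data$ref, ">", .data$base)),
    .data$class, wt = .data$count, name = "n")
  counts <- dplyr::left_join(tibble::tibble(class = .sub_classes), counts,
                             by = "class")
  counts$n[is.na(counts$n)] <- 0L

  out <- list(
    n_bases = n_bases, n_errors = n_errors,
    error_rate = if (n_bases > 0) n_errors / n_bases else NA_real_,
    error_free_positions = 1 - nrow(err_pos) / panel_width,
    substitutions = counts, af_ceiling = af_ceiling,
    panel_width = panel_width
  )
  class(out) <- "error_report"
  out
}

# long per-position allele counts restricted to the panel; N excluded
#' @noRd
base_frequencies <- function(tbl, reference, panel) {
  out <- list()
  for (ctg in unique(panel$contig)) {
    x <- tbl[tbl$rname == ctg, ]
    if (nrow(x) == 0L) next
    iv <- pair_intervals(x)
    pos <- c(seq_expand(iv$s1, iv$e1), seq_expand(iv$s2, iv$e2))
    base <- c(chars_expand(x$seq1), chars_expand(x$seq2))
    keep <- base != "N" & in_panel(pos, panel[panel$contig == ctg, ])
    if (!any(keep)) next
    cnt <- dplyr::count(
      tibble::tibble(pos = pos[keep], base = base[keep]),
      .data$pos, .data$base, name = "count")
    cnt$contig <- ctg
    cnt$ref <- substring(reference[[ctg]], cnt$pos, cnt$pos)
    out[[ctg]] <- cnt
  }
  if (length(out) == 0L) {
    return(tibble::tibble(pos = integer(), base = character(),
                          count = integer(), contig = character(),
                          ref = character()))
  }
  dplyr::bind_rows(out)
}

#' @noRd
seq_expand <- function(from, to) {
  w <- to - from + 1L
  rep(from, w) + sequence(w) - 1L
}

#' @noRd
chars_expand <- function(seqs) {
  unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
}

#' @noRd
in_panel <- function(pos, panel_ctg) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(panel_ctg))) {
    hit <- hit | (pos >= panel_ctg$start[i] & pos <= panel_ctg$end[i])
  }
  hit
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report>\n")
  cat(sprintf("  %d bases in panel, %d background errors (rate %.3g)\n",
              x$n_bases, x$n_errors, x$error_rate))
  cat(sprintf("  error-free panel positions: %.4f (AF ceiling %g)\n",
              x$error_free_positions, x$af_ceiling))
  invisible(x)
}

#' Tidy an error report
#'
#' @param x An `error_report`.
#' @param ... Unused.
#' @return The 12-class substitution count tibble with per-class rates.
#' @method tidy error_report
#' @export
tidy.error_report <- function(x, ...) {
  dplyr::mutate(x$substitutions,
                rate = ifelse(x$n_bases > 0, .data$n / x$n_bases, NA_real_))
}

#' One-row summary of an error report
#'
#' @param x An `error_report`.
#' @param ... Unused.
#' @return One-row tibble with totals, the error rate, and the error-free
#'   position fraction.
#' @method glance error_report
#' @export
glance.error_report <- function(x, ...) {
  tibble::tibble(n_bases = x$n_bases, n_errors = x$n_errors,
                 error_rate = x$error_rate,
                 error_free_positions = x$error_free_positions)
}

#' Substitution-class imbalance
#'
#' Ratio of the counts of two substitution classes, used for the
#' oxidative-damage signature (G>T versus its complementary-strand mirror
#' C>A). When neither class was observed the profile is trivially
#' balanced and the ratio is 1; a nonzero numerator over a zero
#' denominator is `Inf`.
#'
#' @param report An `error_report`.
#' @param num,den Substitution class labels.
#' @return Numeric ratio.
#' @export
substitution_imbalance <- function(report, num = "G>T", den = "C>A") {
  s <- report$substitutions
  a <- s$n[s$class == num]; b <- s$n[s$class == den]
  if (a == 0 && b == 0) return(1)
  a / b
}
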