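#' Run the duplex consensus pipeline on aligned, tagged read pairs
#'
#' Orchestrates the full error-suppression cascade: family grouping,
#' SSCS collapsing, Singleton Correction (optional), duplex consensus
#' formation, and the merged all-unique-molecules table.
#'
#' @param pairs Pair tibble of aligned tagged reads ([pair_alignments()]
#'   output or a [simulate_library()] `$pairs` table).
#' @param config A [consensus_config()].
#' @param sc Apply Singleton Correction.
#' @return Object of class `duplex_run` with elements:
#'   \describe{
#'     \item{pairs}{input pairs with family annotations.}
#'     \item{cons}{strand consensus table after collapsing (and
#'       correction when `sc = TRUE`); provenance column distinguishes
#'       SSCS, corrected, and uncorrected singletons.}
#'     \item{dcs}{duplex consensus reads.}
#'     \item{unpaired}{strand consensuses without a duplex partner.}
#'     \item{unique}{merged all-unique-molecules table.}
#'     \item{counts}{stream sizes (see [tidy.duplex_run()]).}
#'   }
#' @examples
#' sim <- simulate_library(sim_config(n_molecules = 50), seed = 7)
#' run <- run_duplex_pipeline(sim$pairs)
#' tidy(run)
#' @export
run_duplex_pipeline <- function(pairs, config = consensus_config(),
                                sc = TRUE) {
  pairs <- assign_families(pairs)
  cons <- collapse_families(pairs, config)
  if (sc) cons <- correct_singletons(cons, config)
  duplex <- pair_strands(cons, use_sc = sc)
  uncorrected <- dplyr::filter(
    cons, .data$provenance %in% c("singleton", "uncorrected_singleton"))
  unique_tbl <- merge_all_unique(duplex$dcs, duplex$unpaired, uncorrected,
                                 strict_unique = sc)
  counts <- tibble::tibble(
    stream = c("pairs", "families", "sscs", "singletons", "sc_by_sscs",
               "sc_by_singleton", "uncorrected", "dcs", "unpaired_sscs",
               "unique_molecules"),
    n = c(nrow(pairs),
          dplyr::n_distinct(pairs$family_key),
          sum(cons$provenance == "SSCS"),
          sum(pairs$family_size == 1L),
          sum(cons$provenance == "SC_by_SSCS"),
          sum(cons$provenance == "SC_by_singleton"),
          sum(cons$provenance %in% c("singleton", "uncorrected_singleton")),
          nrow(duplex$dcs),
          nrow(duplex$unpaired),
          nrow(unique_tbl))
  )
  structure(
    list(pairs = pairs, cons = cons, dcs = duplex$dcs,
         unpaired = duplex$unpaired, unique = unique_tbl,
         counts = counts, config = config, sc = sc),
    class = "duplex_run"
  )
}

#' @export
print.duplex_run <- function(x, ...) {
  cat("<duplex_run>", if (x$sc) "with" else "without",
      "Singleton Correction\n")
  n <- function(s) x$counts$n[x$counts$stream == s]
  cat(sprintf(
    "  %d read pairs -> %d families: %d SSCS + %d singletons\n",
    n("pairs"), n("families"), n("sscs"), n("singletons")))
  if (x$sc) {
    cat(sprintf(
      "  rescued: %d by SSCS, %d by singletons; %d uncorrected\n",
      n("sc_by_sscs"), n("sc_by_singleton"), n("uncorrected")))
  }
  cat(sprintf("  %d DCS, %d unpaired strand consensuses, %d unique molecules\n",
              n("dcs"), n("unpaired_sscs"), n("unique_molecules")))
  invisible(x)
}

#' Tidy a duplex pipeline run
#'
#' @param x A `duplex_run`.
#' @param ... Unused.
#' @return Tibble of stream sizes with columns `stream` and `n`.
#' @method tidy duplex_run
#' @export
tidy.duplex_run <- function(x, ...) x$counts

#' One-row summary of a duplex pipeline run
#'
#' @param x A `duplex_run`.
#' @param ... Unused.
#' @return One-row tibble: pair/family/stream counts plus the singleton
#'   fraction (singleton families over all families), the singleton
#'   correction rate (rescued singletons over all singletons), and the
#'   correction event rate (rescued singletons over all families) - the
#'   quantity that peaks at intermediate depth, where singletons are both
#'   abundant and likely to find a sequenced complementary strand.
#' @method glance duplex_run
#' @export
glance.duplex_run <- function(x, ...) {
  n <- function(s) x$counts$n[x$counts$stream == s]
  n_single <- n("singletons")
  n_resc <- n("sc_by_sscs") + n("sc_by_singleton")
  tibble::tibble(
    n_pairs = n("pairs"), n_families = n("families"), n_sscs = n("sscs"),
    n_singletons = n_single, n_rescued = n_resc, n_dcs = n("dcs"),
    n_unique = n("unique_molecules"),
    singleton_fraction = ifelse(n("families") > 0,
                                n_single / n("families"), NA_real_),
    sc_rate = ifelse(n_single > 0, n_resc / n_single, NA_real_),
    sc_event_rate = ifelse(n("families") > 0,
                           n_resc / n("families"), NA_real_)
  )
}

#' Write the output streams of a run as SAM files
#'
#' Emits the conventional output set: `sscs.sam`, the per-method corrected
#' singleton files, `uncorrected_singletons.sam`, the merged
#' `sscs_sc.sam`, `dcs.sam`, and `all_unique_molecules.sam`.
#'
#' @param run A `duplex_run`.
#' @param dir Output directory (created if needed).
#' @param reference Optional reference for `@SQ` header lines.
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, file) {
    write_sam(pairs_to_sam(cons_as_pairs(tbl)), file.path(dir, file),
              reference = reference)
    file.path(dir, file)
  }
  prov <- function(p) dplyr::filter(run$cons, .data$provenance %in% p)
  paths <- c(
    emit(prov("SSCS"), "sscs.sam"),
    if (run$sc) emit(prov("SC_by_SSCS"), "sscs.singleton.sscs_corrected.sam"),
    if (run$sc) emit(prov("SC_by_singleton"),
                     "sscs.singleton.singleton_corrected.sam"),
    emit(prov(c("singleton", "uncorrected_singleton")),
         "uncorrected_singletons.sam"),
    if (run$sc) emit(prov(c("SSCS", "SC_by_SSCS", "SC_by_singleton")),
                     "sscs_sc.sam"),
    emit(run$dcs, if (run$sc) "dcs_sc.sam" else "dcs.sam"),
    emit(run$unique, "all_unique_molecules.sam")
  )
  invisible(paths)
}

# consensus rows -> pair-tibble shape expected by pairs_to_sam
#' @noRd
cons_as_pairs <- function(cons) {
  out <- cons
  out$id <- if ("pairing_tag" %in% names(cons)) cons$pairing_tag else
    cons$family_key
  out
}
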