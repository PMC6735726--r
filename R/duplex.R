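# Duplex consensus formation: condensing the two complementary strand
# consensuses of one molecule into a DCS.

#' Form a duplex consensus from two complementary strand consensuses
#'
#' Matched bases between the plus- and minus-strand consensus reads are
#' preserved; mismatches are masked with N, which eliminates asymmetric
#' strand artefacts such as oxidative G>T damage. The base quality of a
#' concordant position is the maximum of the two strand qualities.
#'
#' @param plus,minus Single-row consensus tibbles sharing a duplex key, on
#'   the `+` and `-` strand respectively.
#' @return One-row DCS tibble in the plus strand's coordinates, provenance
#'   `"DCS"`, family size the sum of the contributing sizes.
#' @export
form_dcs <- function(plus, minus) {
  if (!identical(plus$duplex_key, minus$duplex_key) ||
      !identical(plus$strand, "+") || !identical(minus$strand, "-")) {
    stop("DCS requires the two complementary strands of one molecule",
         call. = FALSE)
  }
  form_dcs_impl(plus, minus)
}

#' @noRd
form_dcs_impl <- function(plus, minus) {
  cfg <- consensus_config()   # quality gate unused below
  out <- correct_against(plus, minus, cfg, quality_filter = FALSE)
  # concordant quality: maximum of the two strands
  m1 <- concord_strings(plus$seq1, plus$qual1, minus$seq2, minus$qual2,
                        cfg, quality_filter = FALSE, qual_max = TRUE)
  m2 <- concord_strings(plus$seq2, plus$qual2, minus$seq1, minus$qual1,
                        cfg, quality_filter = FALSE, qual_max = TRUE)
  out$qual1 <- m1$qual
  out$qual2 <- m2$qual
  out$provenance <- "DCS"
  out$family_size <- plus$family_size + minus$family_size
  out$family_key <- out$duplex_key   # byte-stable canonical name
  out$pairing_tag <- pairing_tag(out)
  out
}

#' Pair strand consensuses into duplex consensus sequences
#'
#' Groups consensus reads (SSCS and, when Singleton Correction ran,
#' corrected singletons) by duplex key. Keys with both strands present
#' yield one DCS; leftovers go to the unpaired stream. More than two
#' strand consensuses under one duplex key would violate family grouping
#' and raises an error.
#'
#' @param cons Consensus tibble ([collapse_families()] or
#'   [correct_singletons()] output).
#' @param use_sc Include corrected singletons (`SC_by_SSCS`,
#'   `SC_by_singleton`) as duplex-eligible partners.
#' @return List with tibbles `dcs` and `unpaired`.
#' @export
pair_strands <- function(cons, use_sc = TRUE) {
  eligible_prov <- c("SSCS", if (use_sc) c("SC_by_SSCS", "SC_by_singleton"))
  elig <- dplyr::filter(cons, .data$provenance %in% eligible_prov)
  if (nrow(elig) == 0L) return(list(dcs = elig, unpaired = elig))
  if (max(table(elig$duplex_key)) > 2L) {
    stop(">2 strand consensuses under one duplex key; grouping violated",
         call. = FALSE)
  }
  plus <- elig[elig$strand == "+", ]
  minus <- elig[elig$strand == "-", ]
  m <- match(plus$duplex_key, minus$duplex_key)
  hit <- !is.na(m)
  dcs <- plus[0, ]
  if (any(hit)) {
    dcs <- form_dcs_impl(plus[hit, ], minus[m[hit], ])
  }
  unpaired <- dplyr::bind_rows(plus[!hit, ], minus[is.na(match(
    minus$duplex_key, plus$duplex_key)), ])
  list(dcs = dcs, unpaired = unpaired)
}

#' Merge all unique molecules into one table
#'
#' Combines DCS, duplex-unpaired SSCS, and uncorrected singletons so that
#' every recovered template molecule is represented exactly once - the
#' table used for molecule-level coverage and variant review.
#'
#' With Singleton Correction every molecule ends up in exactly one stream,
#' so the merged table is unique per duplex key and this is asserted. In a
#' traditional (no-rescue) run, the two strands of an unrescued molecule
#' may legitimately appear as separate single-strand records (e.g. an
#' unpaired SSCS plus the complementary uncorrected singleton); pass
#' `strict_unique = FALSE` to relax the check to per-strand uniqueness.
#'
#' @param dcs,unpaired_sscs,uncorrected Disjoint consensus tibbles.
#' @param strict_unique Require at most one record per molecule (duplex
#'   key); always enforced at the strand (family key) level.
#' @return Single tibble; duplicate representation is an error.
#' @export
merge_all_unique <- function(dcs, unpaired_sscs, uncorrected,
                             strict_unique = TRUE) {
  out <- dplyr::bind_rows(dcs, unpaired_sscs, uncorrected)
  if (anyDuplicated(out$family_key) > 0L) {
    stop("a molecule strand is represented more than once in the merged table",
         call. = FALSE)
  }
  if (strict_unique && anyDuplicated(out$duplex_key) > 0L) {
    stop("a molecule is represented more than once in the merged table",
         call. = FALSE)
  }
  out
}
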