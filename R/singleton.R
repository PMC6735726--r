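# Singleton Correction: cross-strand rescue of read families of size one.
#
# Both records in a comparison are aligned consensus/read rows in
# reference-forward coordinates, so mate 1 of one strand overlays mate 2
# of the complementary strand at the same locus and no explicit reverse
# complement is needed.

# per-position concordance of two equal-length reference-forward strings:
# concordant bases passing the quality filter on both sides are retained
# (quality = min of the two); discordant or low-quality positions become N
# with quality 0. `quality_filter = FALSE` skips the Phred gate (duplex
# consensus formation compares already-filtered consensus reads).
#' @noRd
concord_strings <- function(seq_a, qual_a, seq_b, qual_b, cfg,
                            quality_filter = TRUE, qual_max = FALSE) {
  stopifnot(length(seq_a) == length(seq_b))
  if (length(seq_a) == 0L) return(list(seq = character(), qual = character()))
  out_seq <- character(length(seq_a))
  out_qual <- character(length(seq_a))
  len <- nchar(seq_a)
  stopifnot(all(len == nchar(seq_b)))
  for (L in unique(len)) {
    sel <- which(len == L)
    A <- seq_matrix(seq_a[sel]); B <- seq_matrix(seq_b[sel])
    QA <- qual_matrix(qual_a[sel]); QB <- qual_matrix(qual_b[sel])
    ok <- A == B & A != "N"
    if (quality_filter) ok <- ok & qual_pass(QA, cfg) & qual_pass(QB, cfg)
    cons <- ifelse(ok, A, "N")
    q <- if (qual_max) pmax(QA, QB) else pmin(QA, QB)
    q[!ok] <- 0L
    out_seq[sel] <- collapse_rows(cons)
    out_qual[sel] <- qual_int_to_string(q)
  }
  list(seq = out_seq, qual = out_qual)
}

# orient a complementary partner to a target row: partner mate 2 overlays
# target mate 1 and vice versa
#' @noRd
correct_against <- function(target, partner, cfg, quality_filter = TRUE) {
  m1 <- concord_strings(target$seq1, target$qual1, partner$seq2,
                        partner$qual2, cfg, quality_filter)
  m2 <- concord_strings(target$seq2, target$qual2, partner$seq1,
                        partner$qual1, cfg, quality_filter)
  out <- target
  out$seq1 <- m1$seq; out$qual1 <- m1$qual
  out$seq2 <- m2$seq; out$qual2 <- m2$qual
  out
}

#' Correct a singleton against its complementary SSCS
#'
#' @param singleton,sscs Single-row consensus tibbles sharing a duplex key
#'   and lying on opposite strands.
#' @param config A [consensus_config()] (only the quality threshold is
#'   used).
#' @return The corrected singleton (provenance `"SC_by_SSCS"`); concordant
#'   bases passing Q30 on both sides are retained, everything else is
#'   masked with N. The SSCS itself is not modified.
#' @export
correct_by_sscs <- function(singleton, sscs, config = consensus_config()) {
  if (!identical(singleton$duplex_key, sscs$duplex_key) ||
      identical(singleton$strand, sscs$strand)) {
    stop("singleton and SSCS are not complementary strands of one molecule",
         call. = FALSE)
  }
  out <- correct_against(singleton, sscs, config)
  out$provenance <- "SC_by_SSCS"
  out
}

#' Correct two complementary singletons against one another
#'
#' @param s1,s2 Single-row consensus tibbles sharing a duplex key, on
#'   opposite strands.
#' @param config A [consensus_config()].
#' @return Two-row tibble: both corrected singletons (provenance
#'   `"SC_by_singleton"`), one per strand, so downstream duplex pairing
#'   sees both. The operation is symmetric in its arguments.
#' @export
correct_by_singleton <- function(s1, s2, config = consensus_config()) {
  if (!identical(s1$duplex_key, s2$duplex_key) ||
      identical(s1$strand, s2$strand)) {
    stop("singletons are not complementary strands of one molecule",
         call. = FALSE)
  }
  out <- dplyr::bind_rows(correct_against(s1, s2, config),
                          correct_against(s2, s1, config))
  out$provenance <- "SC_by_singleton"
  out
}

#' Run Singleton Correction over a consensus table
#'
#' Step-wise rescue of the singleton stream: each singleton is first
#' grouped with a complementary SSCS (correction by SSCS); if none exists
#' it is paired with the complementary singleton (correction by
#' singletons); otherwise it stays uncorrected. Each singleton is consumed
#' at most once and the three output streams are disjoint.
#'
#' @param cons Output of [collapse_families()].
#' @param config A [consensus_config()].
#' @return `cons` with singleton rows re-labelled by provenance
#'   (`"SC_by_SSCS"`, `"SC_by_singleton"`, or `"uncorrected_singleton"`)
#'   and their sequences corrected; SSCS rows pass through unchanged.
#' @export
correct_singletons <- function(cons, config = consensus_config()) {
  sscs <- dplyr::filter(cons, .data$provenance == "SSCS")
  singles <- dplyr::filter(cons, .data$provenance == "singleton")
  if (anyDuplicated(singles$family_key) > 0L) {
    stop("multiple singletons share a family key; grouping is inconsistent",
         call. = FALSE)
  }

  # (i) SC by SSCS: complementary SSCS exists (opposite strand guaranteed:
  # same duplex key + same strand would be the same family)
  m <- match(singles$duplex_key, sscs$duplex_key)
  by_sscs <- !is.na(m)
  corrected_sscs <- singles[0, ]
  if (any(by_sscs)) {
    corrected_sscs <- correct_against(singles[by_sscs, ],
                                      sscs[m[by_sscs], ], config)
    corrected_sscs$provenance <- "SC_by_SSCS"
  }

  # (ii) SC by singletons: the two strands' singletons pair up
  rest <- singles[!by_sscs, ]
  corrected_pairs <- singles[0, ]
  if (nrow(rest) > 0L) {
    plus <- rest[rest$strand == "+", ]
    minus <- rest[rest$strand == "-", ]
    pm <- match(plus$duplex_key, minus$duplex_key)
    hit <- !is.na(pm)
    if (any(hit)) {
      a <- plus[hit, ]; b <- minus[pm[hit], ]
      ca <- correct_against(a, b, config)
      cb <- correct_against(b, a, config)
      corrected_pairs <- dplyr::bind_rows(ca, cb)
      corrected_pairs$provenance <- "SC_by_singleton"
    }
    consumed <- c(plus$family_key[hit], minus$family_key[pm[hit]])
    rest <- rest[!(rest$family_key %in% consumed), ]
  }
  rest$provenance <- "uncorrected_singleton"

  out <- dplyr::bind_rows(sscs, corrected_sscs, corrected_pairs, rest)
  stopifnot(nrow(out) == nrow(cons))
  out
}
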