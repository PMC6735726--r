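#' Extract in-line duplex UMIs from raw read pairs
#'
#' Each read starts with a 2 bp UMI followed by a single invariant spacer
#' base required by the ligation chemistry. The two UMIs are concatenated
#' (mate 1 UMI first) into a 4-character duplex barcode, the first
#' `umi_len + 1` bases and qualities are trimmed from both mates, and the
#' barcode is appended to the identifier behind a reserved delimiter so it
#' survives alignment in the query name. Pairs whose spacer base differs
#' from the expected spacer on either mate are rejected, as are pairs with
#' reads too short to contain UMI, spacer, and at least one insert base.
#'
#' UMIs containing N are retained; grouping simply treats N as a fifth
#' symbol. UMI base qualities are not checked here - quality filtering
#' happens at the consensus stage.
#'
#' @param reads Tibble of raw read pairs (`id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`), e.g. from [read_fastq_pairs()] or a [simulate_library()]
#'   `$reads` table.
#' @param umi_len UMI length per read (bp).
#' @param spacer Invariant spacer base.
#' @param delim Reserved delimiter between identifier stem and barcode.
#' @return The input tibble with columns `status` (`"tagged"`,
#'   `"rejected_spacer"`, or `"rejected_short"`), `barcode`, and trimmed
#'   `seq1`/`qual1`/`seq2`/`qual2`; for tagged rows `id` carries the
#'   barcode suffix. Rejected rows keep their original fields. Row order
#'   is preserved.
#' @examples
#' reads <- tibble::tibble(
#'   id = c("a", "b"),
#'   seq1 = c("ACTGGGG", "ACAGGGG"), qual1 = c("IIIIIII", "IIIIIII"),
#'   seq2 = c("GGTCCCC", "GGTCCCC"), qual2 = c("IIIIIII", "IIIIIII")
#' )
#' extract_umis(reads)  # "a" tagged with barcode ACGG, "b" rejected
#' @export
extract_umis <- function(reads, umi_len = 2L, spacer = "T", delim = "|") {
  stopifnot(all(c("id", "seq1", "qual1", "seq2", "qual2") %in% names(reads)))
  if (any(nchar(reads$seq1) != nchar(reads$qual1)) ||
      any(nchar(reads$seq2) != nchar(reads$qual2))) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  prefix <- umi_len + 1L            # UMI + spacer
  min_len <- prefix + 1L            # at least one insert base
  long_enough <- nchar(reads$seq1) >= min_len & nchar(reads$seq2) >= min_len
  sp1 <- substr(reads$seq1, prefix, prefix)
  sp2 <- substr(reads$seq2, prefix, prefix)
  status <- dplyr::case_when(
    !long_enough ~ "rejected_short",
    sp1 != spacer | sp2 != spacer ~ "rejected_spacer",
    TRUE ~ "tagged"
  )
  barcode <- ifelse(
    status == "tagged",
    paste0(substr(reads$seq1, 1L, umi_len), substr(reads$seq2, 1L, umi_len)),
    NA_character_
  )
  tagged <- status == "tagged"
  out <- reads
  out$status <- status
  out$barcode <- barcode
  out$id[tagged] <- paste(reads$id[tagged], barcode[tagged], sep = delim)
  for (col in c("seq1", "qual1", "seq2", "qual2")) {
    out[[col]][tagged] <- substr(reads[[col]][tagged], prefix + 1L,
                                 nchar(reads[[col]][tagged]))
  }
  dplyr::relocate(out, "id", "status", "barcode")
}

#' Keep only successfully tagged pairs
#'
#' @param extracted Output of [extract_umis()].
#' @return The tagged rows, without the `status` column.
#' @export
tagged_pairs <- function(extracted) {
  dplyr::select(dplyr::filter(extracted, .data$status == "tagged"), -"status")
}
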