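#' Molecular family keys for tagged read pairs
#'
#' Each aligned, tagged read pair is assigned a family key - the composite
#' molecular identifier of one strand of one template molecule - built
#' from the duplex barcode, the genomic mapping positions and CIGAR
#' strings of both mates, the read orientations, and the strand of origin
#' (mate 1 forward implies plus, mate 1 reverse implies minus). Read pairs
#' sharing a family key are PCR duplicates of the same strand of the same
#' molecule. Coordinates are the 1-based leftmost mapping positions as
#' recorded in the alignment; soft clips are not unwound, because CIGAR
#' equality already separates clip variants.
#'
#' The duplex key is the strand-canonical form under which the two
#' complementary strands of one molecule hash together: the key of a pair
#' and of its duplex transform (barcode halves interchanged, mate slots
#' swapped, strand flipped) serialize to the same duplex key.
#'
#' @param pairs Pair tibble (see [pair_alignments()]); an `orient` column
#'   is derived from `strand` when absent.
#' @param umi_len UMI length per barcode half.
#' @return `pairs` with added columns `family_key`, `duplex_key`, and
#'   `family_size` (number of pairs sharing the family key).
#' @export
assign_families <- function(pairs, umi_len = 2L) {
  need <- c("barcode", "rname", "strand", "pos1", "cigar1", "pos2", "cigar2")
  stopifnot(all(need %in% names(pairs)))
  if (any(is.na(pairs$barcode)) || any(!nzchar(pairs$barcode))) {
    stop("missing barcode: UMI extraction must precede family grouping",
         call. = FALSE)
  }
  orient <- if ("orient" %in% names(pairs)) pairs$orient else
    ifelse(pairs$strand == "+", "FR", "RF")
  key <- family_key_string(pairs$barcode, pairs$rname, pairs$pos1,
                           pairs$cigar1, pairs$pos2, pairs$cigar2,
                           pairs$strand, orient)
  partner <- family_key_string(swap_barcode(pairs$barcode, umi_len),
                               pairs$rname, pairs$pos2, pairs$cigar2,
                               pairs$pos1, pairs$cigar1,
                               flip_strand(pairs$strand), str_rev(orient))
  out <- pairs
  out$family_key <- key
  out$duplex_key <- pmin(key, partner)
  dplyr::add_count(out, .data$family_key, name = "family_size")
}

#' @noRd
family_key_string <- function(barcode, rname, pos1, cigar1, pos2, cigar2,
                              strand, orient) {
  paste(barcode, rname, pos1, cigar1, pos2, cigar2, strand, orient,
        sep = "/")
}

#' Duplex transform of a family key
#'
#' Maps the family key of one strand of a molecule to the key its
#' complementary strand would carry: the two barcode halves are
#' interchanged (AC/GT becomes GT/AC), the mate slots (position and CIGAR)
#' are swapped, the strand is flipped, and the orientation string is
#' mirrored. The transform is an involution.
#'
#' @param key Family key string(s) from [assign_families()].
#' @param umi_len UMI length per barcode half.
#' @return Transformed key string(s).
#' @export
duplex_transform <- function(key, umi_len = 2L) {
  parts <- stringr::str_split_fixed(key, stringr::fixed("/"), 8L)
  family_key_string(
    swap_barcode(parts[, 1], umi_len), parts[, 2],
    parts[, 5], parts[, 6], parts[, 3], parts[, 4],
    flip_strand(parts[, 7]), str_rev(parts[, 8])
  )
}

#' Strand-canonical duplex key of a family key
#'
#' @param key Family key string(s).
#' @param umi_len UMI length per barcode half.
#' @return The lexicographic minimum of the key and its
#'   [duplex_transform()]; identical for the two strands of one molecule.
#' @export
duplex_key <- function(key, umi_len = 2L) {
  pmin(key, duplex_transform(key, umi_len))
}

#' Family size distribution
#'
#' @param pairs Output of [assign_families()].
#' @return Tibble with columns `family_size` and `n_families`.
#' @export
family_size_distribution <- function(pairs) {
  fam <- dplyr::distinct(pairs, .data$family_key, .data$family_size)
  dplyr::count(fam, .data$family_size, name = "n_families")
}
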