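# Internal string/quality helpers.
#
# Sequences travel through the pipeline as plain character vectors in
# reference-forward orientation (the convention of aligned records), so
# per-position work is done on character matrices built from equal-length
# strings.

# characters legal in Phred+33 strings, indexed by Q+1 (Q = 0..93)
.qual_chars <- strsplit(rawToChar(as.raw(33:126)), "", fixed = TRUE)[[1]]

#' @noRd
seq_matrix <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(character(), 0L, 0L))
  L <- nchar(x[1L])
  stopifnot(all(nchar(x) == L))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

#' @noRd
qual_matrix <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(integer(), 0L, 0L))
  L <- nchar(x[1L])
  stopifnot(all(nchar(x) == L))
  matrix(utf8ToInt(paste(x, collapse = "")) - 33L,
         nrow = n, ncol = L, byrow = TRUE)
}

# rows of a character matrix back to strings
#' @noRd
collapse_rows <- function(m) {
  if (nrow(m) == 0L) return(character())
  if (ncol(m) == 0L) return(rep("", nrow(m)))
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' @noRd
qual_int_to_string <- function(m) {
  stopifnot(all(m >= 0 & m <= 93))
  chr <- matrix(.qual_chars[m + 1L], nrow = nrow(m), ncol = ncol(m))
  collapse_rows(chr)
}

#' @noRd
revcomp <- function(x) {
  out <- rep("", length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])
    ))
  }
  out
}

# reference-space width of a CIGAR string (M/D/N/=/X consume reference)
#' @noRd
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# swap the two 2-bp halves of a duplex barcode: "ACGT" -> "GTAC"
#' @noRd
swap_barcode <- function(barcode, umi_len = 2L) {
  paste0(substr(barcode, umi_len + 1L, 2L * umi_len),
         substr(barcode, 1L, umi_len))
}

#' @noRd
str_rev <- function(x) stringi::stri_reverse(x)

#' @noRd
flip_strand <- function(strand) {
  ifelse(strand == "+", "-", "+")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
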