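#' Read a reference genome from FASTA
#'
#' @param path FASTA file (plain or gzip).
#' @return Named character vector of contig sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_reference(x)
}

#' Write a reference genome to FASTA
#'
#' @param reference Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_reference <- function(reference, path) {
  reference <- as_reference(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read a target panel from BED
#'
#' BED is 0-based half-open; the returned tibble is 1-based inclusive as
#' used throughout the package.
#'
#' @param path BED file with at least 3 columns.
#' @return Tibble with columns `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  stopifnot(ncol(x) >= 3)
  tibble::tibble(contig = as.character(x[[1]]),
                 start = as.integer(x[[2]]) + 1L,
                 end = as.integer(x[[3]]))
}

#' Write a target panel to BED
#'
#' @param panel Tibble with columns `contig`, `start`, `end` (1-based
#'   inclusive).
#' @param path Output path.
#' @export
write_bed <- function(panel, path) {
  readr::write_tsv(
    tibble::tibble(contig = panel$contig, start = panel$start - 1L,
                   end = panel$end),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' Mates are matched by order (the FASTQ convention); identifiers must
#' agree on the stem shared by both mates.
#'
#' @param r1,r2 FASTQ paths (plain or gzip).
#' @return Tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  read_one <- function(path) {
    # the reader notes that metadata columns are not carried over
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  f1 <- read_one(r1)
  f2 <- read_one(r2)
  stopifnot(length(f1) == length(f2))
  id1 <- sub("\\s.*$", "", names(f1))
  id2 <- sub("\\s.*$", "", names(f2))
  id1 <- sub("/1$", "", id1); id2 <- sub("/2$", "", id2)
  stopifnot(identical(id1, id2))
  tibble::tibble(
    id = id1,
    seq1 = unname(as.character(f1)),
    qual1 = unname(as.character(Biostrings::quality(f1))),
    seq2 = unname(as.character(f2)),
    qual2 = unname(as.character(Biostrings::quality(f2)))
  )
}

#' Write a read-pair tibble to paired FASTQ files
#'
#' Round-trips through [read_fastq_pairs()] byte-exactly on sequences,
#' qualities, and identifiers.
#'
#' @param pairs Tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param r1,r2 Output FASTQ paths (a `.gz` suffix compresses).
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals)
    )
    names(x) <- ids
    # the writer warns that the (empty) metadata columns are not written
    withCallingHandlers(
      Biostrings::writeQualityScaledXStringSet(
        x, path, compress = grepl("\\.gz$", path)),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  write_one(pairs$seq1, pairs$qual1, pairs$id, r1)
  write_one(pairs$seq2, pairs$qual2, pairs$id, r2)
  invisible(c(r1, r2))
}

# ---------------------------------------------------------------------------
# SAM records as tibbles. SAM is the text form of the alignment interchange
# format; records are tab-delimited with 11 mandatory fields. `samtools
# view -h` converts BAM to this form and `samtools view -b` back.

.sam_cols <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "rnext", "pnext", "tlen", "seq", "qual")

#' Read alignment records from a SAM file
#'
#' @param path SAM text file (use `samtools view -h` to convert from BAM).
#' @return Tibble with the 11 mandatory SAM fields (optional tags are
#'   dropped) and the header lines in attribute `"header"`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      list(character(), integer(), character(), integer(), integer(),
           character(), character(), integer(), integer(), character(),
           character()),
      .sam_cols))
    attr(out, "header") <- hdr
    return(out)
  }
  parts <- stringr::str_split_fixed(body, "\t", 12L)
  out <- tibble::tibble(
    qname = parts[, 1], flag = as.integer(parts[, 2]),
    rname = parts[, 3], pos = as.integer(parts[, 4]),
    mapq = as.integer(parts[, 5]), cigar = parts[, 6],
    rnext = parts[, 7], pnext = as.integer(parts[, 8]),
    tlen = as.integer(parts[, 9]), seq = parts[, 10], qual = parts[, 11]
  )
  attr(out, "header") <- hdr
  out
}

#' Write alignment records to a SAM file
#'
#' @param aln Tibble with the 11 mandatory SAM fields (see [read_sam()]).
#' @param path Output path.
#' @param reference Optional named character vector of contig sequences;
#'   when given, `@SQ` header lines are emitted.
#' @export
write_sam <- function(aln, path, reference = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:coordinate"
  if (!is.null(reference)) {
    reference <- as_reference(reference)
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                          nchar(reference)))
  }
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                  aln$cigar, aln$rnext, aln$pnext, aln$tlen, aln$seq,
                  aln$qual)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

# SAM flag bits
.flag_paired <- 1L; .flag_unmapped <- 4L; .flag_mate_unmapped <- 8L
.flag_reverse <- 16L; .flag_mate_reverse <- 32L
.flag_read1 <- 64L; .flag_read2 <- 128L
.flag_secondary <- 256L; .flag_supplementary <- 2048L

#' @noRd
has_flag <- function(flag, bit) bitwAnd(flag, bit) > 0L

#' Convert a tagged pair tibble to per-record SAM form
#'
#' One row per pair becomes two records (mates), with the barcode appended
#' to the query name behind the reserved `|` delimiter. Flags encode a
#' proper pair with the orientation implied by `strand` (`+`: mate 1
#' forward / mate 2 reverse; `-`: the converse).
#'
#' @param pairs Pair tibble (`id`, `barcode`, `rname`, `strand`, `pos1`,
#'   `cigar1`, `seq1`, `qual1`, `pos2`, `cigar2`, `seq2`, `qual2`).
#' @return SAM record tibble sorted by coordinate.
#' @export
pairs_to_sam <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) return(read_sam_empty())
  plus <- pairs$strand == "+"
  f1 <- 1L + 2L + .flag_read1 + ifelse(plus, .flag_mate_reverse, .flag_reverse)
  f2 <- 1L + 2L + .flag_read2 + ifelse(plus, .flag_reverse, .flag_mate_reverse)
  qname <- paste(pairs$id, pairs$barcode, sep = "|")
  end1 <- pairs$pos1 + cigar_ref_width(pairs$cigar1) - 1L
  end2 <- pairs$pos2 + cigar_ref_width(pairs$cigar2) - 1L
  lo <- pmin(pairs$pos1, pairs$pos2); hi <- pmax(end1, end2)
  tl <- hi - lo + 1L
  rec <- function(flag, pos, cigar, seq, qual, pnext, tlen) {
    tibble::tibble(qname = qname, flag = flag, rname = pairs$rname,
                   pos = pos, mapq = 60L, cigar = cigar, rnext = "=",
                   pnext = pnext, tlen = tlen, seq = seq, qual = qual)
  }
  out <- dplyr::bind_rows(
    rec(f1, pairs$pos1, pairs$cigar1, pairs$seq1, pairs$qual1, pairs$pos2,
        ifelse(pairs$pos1 <= pairs$pos2, tl, -tl)),
    rec(f2, pairs$pos2, pairs$cigar2, pairs$seq2, pairs$qual2, pairs$pos1,
        ifelse(pairs$pos2 < pairs$pos1, tl, -tl))
  )
  dplyr::arrange(out, .data$rname, .data$pos)
}

#' @noRd
read_sam_empty <- function() {
  tibble::as_tibble(stats::setNames(
    list(character(), integer(), character(), integer(), integer(),
         character(), character(), integer(), integer(), character(),
         character()),
    .sam_cols))
}

#' Filter alignment records for consensus building
#'
#' Drops records that are unmapped, have an unmapped mate, or carry
#' multiple alignments (secondary/supplementary records), then drops
#' orphans whose mate is absent from the file after those filters.
#'
#' @param aln SAM record tibble from [read_sam()].
#' @return The kept records, with a tibble of per-reason drop counts in
#'   attribute `"dropped"`.
#' @export
filter_alignments <- function(aln) {
  reason <- dplyr::case_when(
    has_flag(aln$flag, .flag_unmapped) ~ "unmapped",
    has_flag(aln$flag, .flag_mate_unmapped) ~ "mate-unmapped",
    has_flag(aln$flag, .flag_secondary) |
      has_flag(aln$flag, .flag_supplementary) ~ "multi-alignment",
    TRUE ~ NA_character_
  )
  keep <- aln[is.na(reason), ]
  # mate presence: need exactly one mate-1 and one mate-2 record per qname
  r1 <- has_flag(keep$flag, .flag_read1)
  tab1 <- table(keep$qname[r1]); tab2 <- table(keep$qname[!r1])
  ok <- intersect(names(tab1)[tab1 == 1L], names(tab2)[tab2 == 1L])
  orphan <- !(keep$qname %in% ok)
  dropped <- dplyr::count(
    tibble::tibble(reason = c(reason[!is.na(reason)],
                              rep("orphan", sum(orphan)))),
    .data$reason, name = "n")
  out <- keep[!orphan, ]
  attr(out, "dropped") <- dropped
  out
}

#' Pair filtered alignment records into the pipeline's pair tibble
#'
#' Joins the two mates of each template into one row, splits the barcode
#' out of the query name, and infers the strand of origin from read
#' orientation and read number (mate 1 forward implies the plus strand,
#' mate 1 reverse the minus strand).
#'
#' @param aln Filtered SAM record tibble (see [filter_alignments()]).
#' @param delim Barcode delimiter in the query name.
#' @return Pair tibble with columns `id`, `barcode`, `rname`, `strand`,
#'   `pos1`, `cigar1`, `seq1`, `qual1`, `pos2`, `cigar2`, `seq2`, `qual2`,
#'   `orient`.
#' @export
pair_alignments <- function(aln, delim = "|") {
  if (nrow(aln) == 0L) {
    return(tibble::tibble(
      id = character(), barcode = character(), rname = character(),
      strand = character(), pos1 = integer(), cigar1 = character(),
      seq1 = character(), qual1 = character(), pos2 = integer(),
      cigar2 = character(), seq2 = character(), qual2 = character(),
      orient = character()))
  }
  if (!all(grepl(delim, aln$qname, fixed = TRUE))) {
    stop("query names carry no barcode; run UMI extraction first",
         call. = FALSE)
  }
  r1 <- aln[has_flag(aln$flag, .flag_read1), ]
  r2 <- aln[has_flag(aln$flag, .flag_read2), ]
  m <- match(r1$qname, r2$qname)
  stopifnot(!anyNA(m))
  r2 <- r2[m, ]
  split_at <- regexpr(delim, r1$qname, fixed = TRUE)
  rev1 <- has_flag(r1$flag, .flag_reverse)
  rev2 <- has_flag(r2$flag, .flag_reverse)
  tibble::tibble(
    id = substr(r1$qname, 1L, split_at - 1L),
    barcode = substr(r1$qname, split_at + 1L, nchar(r1$qname)),
    rname = r1$rname,
    strand = ifelse(rev1, "-", "+"),
    pos1 = r1$pos, cigar1 = r1$cigar, seq1 = r1$seq, qual1 = r1$qual,
    pos2 = r2$pos, cigar2 = r2$cigar, seq2 = r2$seq, qual2 = r2$qual,
    orient = paste0(ifelse(rev1, "R", "F"), ifelse(rev2, "R", "F"))
  )
}
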