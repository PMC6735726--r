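#' Consensus configuration
#'
#' @param min_base_quality Phred threshold; bases below it are removed
#'   before consensus evaluation (default 30, i.e. error probability at
#'   most one in a thousand). The comparator is `>=` and is exposed via
#'   `quality_strict` for the strict `>` reading.
#' @param consensus_cutoff Minimum proportion of quality-surviving reads
#'   that must carry the most common base for it to be called (default
#'   0.7); below the cutoff the position is masked with N. Must exceed 0.5
#'   so the call is unambiguous.
#' @param quality_strict If `TRUE`, require quality strictly above the
#'   threshold.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(min_base_quality = 30L, consensus_cutoff = 0.7,
                             quality_strict = FALSE) {
  stopifnot(consensus_cutoff > 0.5, consensus_cutoff <= 1,
            min_base_quality >= 0)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 consensus_cutoff = consensus_cutoff,
                 quality_strict = isTRUE(quality_strict)),
            class = "consensus_config")
}

#' @noRd
qual_pass <- function(q, cfg) {
  if (cfg$quality_strict) q > cfg$min_base_quality
  else q >= cfg$min_base_quality
}

#' Consensus base for one aligned column of a read family
#'
#' Bases failing the quality threshold are removed first; among the
#' survivors the most common base is assigned if its proportion is greater
#' than or equal to the consensus cutoff, otherwise N. An empty survivor
#' set yields N. Ties can never reach a cutoff above 0.5, so they also
#' yield N.
#'
#' @param base Character vector of observed bases at one position across
#'   the family.
#' @param qual Integer Phred scores (same length).
#' @param config A [consensus_config()].
#' @return Single character: the consensus base or `"N"`.
#' @examples
#' consensus_base(c(rep("A", 7), rep("G", 3)), rep(37L, 10))  # "A" at 0.7
#' consensus_base(c(rep("A", 6), rep("G", 4)), rep(37L, 10))  # "N"
#' @export
consensus_base <- function(base, qual, config = consensus_config()) {
  stopifnot(length(base) == length(qual))
  keep <- qual_pass(qual, config)
  base <- base[keep]
  if (length(base) == 0L) return("N")
  tab <- table(base)
  top <- which.max(tab)
  if (tab[top] / length(base) >= config$consensus_cutoff) names(tab)[top]
  else "N"
}

# Vectorised consensus over many families at once. `seqs`/`quals` are
# equal-length strings; `fam` is an integer family index (1..nfam). The
# consensus quality is the maximum quality among reads agreeing with the
# consensus base; masked positions get quality 0.
#' @noRd
consensus_matrix <- function(seqs, quals, fam, cfg) {
  nfam <- max(fam)
  M <- seq_matrix(seqs)
  Q <- qual_matrix(quals)
  pass <- qual_pass(Q, cfg)
  letters5 <- c("A", "C", "G", "T", "N")
  counts <- lapply(letters5, function(b) {
    rowsum((M == b & pass) + 0L, fam, reorder = TRUE)
  })
  total <- Reduce(`+`, counts)
  best <- matrix(1L, nfam, ncol(M))
  best_n <- counts[[1L]]
  for (k in 2:5) {
    upd <- counts[[k]] > best_n
    best[upd] <- k
    best_n[upd] <- counts[[k]][upd]
  }
  called <- total > 0L & best_n >= cfg$consensus_cutoff * total
  cons <- matrix("N", nfam, ncol(M))
  cons[called] <- letters5[best[called]]

  # group-maximum quality over agreeing reads, one member rank at a time
  ord <- order(fam)
  rank_in_fam <- stats::ave(fam[ord], fam[ord], FUN = seq_along)
  cq <- matrix(0L, nfam, ncol(M))
  for (r in seq_len(max(rank_in_fam))) {
    rows <- ord[rank_in_fam == r]
    f <- fam[rows]
    agree <- M[rows, , drop = FALSE] == cons[f, , drop = FALSE] &
      pass[rows, , drop = FALSE]
    qr <- Q[rows, , drop = FALSE] * agree
    cq[f, ] <- pmax(cq[f, , drop = FALSE], qr)
  }
  cq[cons == "N"] <- 0L
  list(seq = collapse_rows(cons), qual = qual_int_to_string(cq))
}

#' Collapse read families into single-strand consensus sequences
#'
#' Families of two or more PCR-duplicate read pairs are collapsed
#' per-position with [consensus_base()] semantics, independently for each
#' mate (members of a family share mapping position and CIGAR by
#' construction of the key, so positions pair by read offset). Families of
#' size one are routed unchanged to the singleton stream.
#'
#' @param pairs Output of [assign_families()].
#' @param config A [consensus_config()].
#' @return Consensus tibble with one row per family: the pair-level
#'   coordinate/CIGAR fields, consensus `seq1`/`qual1`/`seq2`/`qual2`,
#'   `family_size`, `family_key`, `duplex_key`, `strand`, and `provenance`
#'   (`"SSCS"` for collapsed families, `"singleton"` for size-1 families).
#' @export
collapse_families <- function(pairs, config = consensus_config()) {
  stopifnot(all(c("family_key", "duplex_key", "family_size")
                %in% names(pairs)))
  cols <- c("barcode", "rname", "strand", "pos1", "cigar1", "pos2",
            "cigar2", "family_key", "duplex_key", "family_size")

  singles <- dplyr::filter(pairs, .data$family_size == 1L)
  singles <- dplyr::select(singles, dplyr::all_of(c(
    cols, "seq1", "qual1", "seq2", "qual2", "id")))
  singles$provenance <- "singleton"

  fams <- dplyr::filter(pairs, .data$family_size >= 2L)
  if (nrow(fams) == 0L) {
    sscs <- singles[0, setdiff(names(singles), "id")]
  } else {
    fams <- dplyr::arrange(fams, .data$family_key)
    meta <- dplyr::distinct(fams, dplyr::pick(dplyr::all_of(cols)))
    stopifnot(!anyDuplicated(meta$family_key))
    # consensus per mate; families processed in batches of equal read length
    out1 <- consensus_by_length(fams$seq1, fams$qual1, fams$family_key,
                                meta$family_key, config)
    out2 <- consensus_by_length(fams$seq2, fams$qual2, fams$family_key,
                                meta$family_key, config)
    sscs <- meta
    sscs$seq1 <- out1$seq; sscs$qual1 <- out1$qual
    sscs$seq2 <- out2$seq; sscs$qual2 <- out2$qual
    sscs$provenance <- "SSCS"
  }
  singles$id <- NULL
  out <- dplyr::bind_rows(sscs, singles)
  out$pairing_tag <- pairing_tag(out)
  tibble::as_tibble(out)
}

# run consensus_matrix per read-length batch, return in meta key order
#' @noRd
consensus_by_length <- function(seqs, quals, keys, meta_keys, cfg) {
  len <- nchar(seqs)
  res_seq <- character(length(meta_keys))
  res_qual <- character(length(meta_keys))
  names(res_seq) <- names(res_qual) <- meta_keys
  for (L in unique(len)) {
    sel <- len == L
    k <- keys[sel]
    fam <- match(k, sort(unique(k)))
    cm <- consensus_matrix(seqs[sel], quals[sel], fam, cfg)
    res_seq[sort(unique(k))] <- cm$seq
    res_qual[sort(unique(k))] <- cm$qual
  }
  list(seq = unname(res_seq), qual = unname(res_qual))
}

# consensus query name: barcode, coordinate-ordered mapping, strand of
# origin, CIGARs ordered by strand/read number, family size
#' @noRd
pairing_tag <- function(x) {
  lo_first <- x$pos1 <= x$pos2
  paste(x$barcode, x$rname,
        pmin(x$pos1, x$pos2), pmax(x$pos1, x$pos2),
        ifelse(x$strand == "+", "plus", "minus"),
        ifelse(lo_first, paste(x$cigar1, x$cigar2, sep = "."),
               paste(x$cigar2, x$cigar1, sep = ".")),
        x$family_size, sep = ":")
}

#' Split a consensus table into SSCS and singleton streams
#'
#' @param cons Output of [collapse_families()].
#' @return List with elements `sscs` and `singletons`.
#' @export
route_families <- function(cons) {
  list(sscs = dplyr::filter(cons, .data$provenance == "SSCS"),
       singletons = dplyr::filter(cons, .data$provenance == "singleton"))
}
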