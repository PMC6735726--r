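# Small in-code fixtures and brute-force oracles shared across tests.

Q37 <- rawToChar(as.raw(37 + 33))  # "F"
Q25 <- rawToChar(as.raw(25 + 33))

qstr <- function(q, n) strrep(rawToChar(as.raw(q + 33)), n)

# one aligned tagged read pair with sensible defaults
make_pair <- function(id = "p1", barcode = "ACGT", rname = "toy",
                      strand = "+", pos1 = 100L, pos2 = 150L,
                      seq1 = "ACGTACGTAC", seq2 = "TTGCATTGCA",
                      qual1 = NULL, qual2 = NULL,
                      cigar1 = NULL, cigar2 = NULL) {
  tibble::tibble(
    id = id, barcode = barcode, rname = rname, strand = strand,
    pos1 = as.integer(pos1),
    cigar1 = cigar1 %||% paste0(nchar(seq1), "M"),
    seq1 = seq1, qual1 = qual1 %||% strrep(Q37, nchar(seq1)),
    pos2 = as.integer(pos2),
    cigar2 = cigar2 %||% paste0(nchar(seq2), "M"),
    seq2 = seq2, qual2 = qual2 %||% strrep(Q37, nchar(seq2))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# replicate a pair into a PCR-duplicate family of size n
make_family <- function(n, ...) {
  base <- make_pair(...)
  fam <- base[rep(1L, n), ]
  fam$id <- paste0(base$id, ".", seq_len(n))
  fam
}

# the complementary-strand pair of the same molecule
complement_pair <- function(pair, id = paste0(pair$id, "c")) {
  out <- pair
  out$id <- id
  out$barcode <- paste0(substr(pair$barcode, 3, 4),
                        substr(pair$barcode, 1, 2))
  out$strand <- ifelse(pair$strand == "+", "-", "+")
  out$pos1 <- pair$pos2; out$cigar1 <- pair$cigar2
  out$seq1 <- pair$seq2; out$qual1 <- pair$qual2
  out$pos2 <- pair$pos1; out$cigar2 <- pair$cigar1
  out$seq2 <- pair$seq1; out$qual2 <- pair$qual1
  out
}

mutate_base <- function(seq, at, to) {
  substr(seq, at, at) <- to
  seq
}

# O(n^2) brute-force partition of pairs into molecule-strand families by
# field-wise comparison (independent of the key-string implementation)
brute_force_partition <- function(pairs) {
  n <- nrow(pairs)
  lab <- seq_len(n)
  same <- function(i, j) {
    pairs$barcode[i] == pairs$barcode[j] &&
      pairs$rname[i] == pairs$rname[j] &&
      pairs$strand[i] == pairs$strand[j] &&
      pairs$pos1[i] == pairs$pos1[j] && pairs$pos2[i] == pairs$pos2[j] &&
      pairs$cigar1[i] == pairs$cigar1[j] && pairs$cigar2[i] == pairs$cigar2[j]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (same(i, j)) {
        lab[lab == lab[i]] <- lab[j]
        break
      }
    }
  }
  lab
}

# per-position fragment depth by naive counting
brute_force_coverage <- function(pairs, panel) {
  w1 <- as.integer(sub("M", "", pairs$cigar1))
  w2 <- as.integer(sub("M", "", pairs$cigar2))
  tot <- 0L; width <- 0L
  for (k in seq_len(nrow(panel))) {
    for (p in seq(panel$start[k], panel$end[k])) {
      hit <- pairs$rname == panel$contig[k] &
        ((p >= pairs$pos1 & p <= pairs$pos1 + w1 - 1L) |
           (p >= pairs$pos2 & p <= pairs$pos2 + w2 - 1L))
      tot <- tot + sum(hit)
      width <- width + 1L
    }
  }
  tot / width
}

# tiny reference/panel for fast simulations
small_sim_config <- function(...) {
  ref <- sim_reference(c(toy = 12000L), seed = 11L)
  sim_config(reference = ref,
             panel = sim_panel(ref, n_targets = 2L, target_width = 1200L),
             ...)
}

# strand-pattern stream counts straight from the simulator truth table:
# (>=2,>=2) both SSCS; (1,>=2) rescue by SSCS; (1,1) rescue pair;
# (1,0) uncorrected singleton
truth_stream_counts <- function(truth) {
  a <- pmin(truth$n_plus, 2L); b <- pmin(truth$n_minus, 2L)
  list(
    sscs = sum(a == 2L) + sum(b == 2L),
    singletons = sum(a == 1L) + sum(b == 1L),
    sc_by_sscs = sum(a == 1L & b == 2L) + sum(a == 2L & b == 1L),
    sc_by_singleton = 2L * sum(a == 1L & b == 1L),
    uncorrected = sum(a == 1L & b == 0L) + sum(a == 0L & b == 1L),
    dcs_traditional = sum(a == 2L & b == 2L),
    dcs_sc = sum(a >= 1L & b >= 1L)
  )
}
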