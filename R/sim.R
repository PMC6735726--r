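#' Simulation configuration for duplex-UMI libraries
#'
#' Describes a hybrid-capture duplex sequencing experiment: template
#' molecules are drawn from a target panel on a reference genome, each
#' molecule carries a 2 bp + 2 bp in-line UMI pair (one UMI ligated at each
#' fragment end) and a single invariant spacer base, and each of its two
#' strands is sequenced as a number of PCR-duplicate read pairs drawn from a
#' per-strand count distribution. Two error channels are modelled: a
#' symmetric per-base substitution channel (polymerase/sequencer noise,
#' independent per read) and a strand-confined oxidative channel in which a
#' damaged molecule's reads from one strand report T at a single
#' reference-G site while the complementary strand is unaffected.
#'
#' @param reference Named character vector of contig sequences (or a
#'   [Biostrings::DNAStringSet]). Default: the bundled ~50 kb toy genome.
#' @param panel Tibble with columns `contig`, `start`, `end` (1-based,
#'   inclusive) giving the target intervals. Default: the bundled toy panel.
#' @param n_molecules Number of template molecules to draw.
#' @param fragment_mean,fragment_sd Mean and SD of sheared fragment length
#'   in bp (defaults 170 +/- 25, emulating a ~180-250 bp sonication target
#'   after adapter/UMI trimming).
#' @param read_length Sequenced read length in bp after UMI/spacer removal.
#' @param umi_len Length of each in-line UMI (2 bp per read end).
#' @param spacer Invariant spacer base between UMI and insert.
#' @param strand_dist Per-strand read-count distribution: `"ztpois"`
#'   (zero-truncated Poisson; every strand sequenced at least once),
#'   `"pois"` (plain Poisson; strand dropout possible), or `"fixed"`.
#' @param strand_mean Mean of the count distribution (the fixed count for
#'   `"fixed"`, lambda otherwise).
#' @param seq_error_rate Per-base substitution probability per read.
#' @param oxidation_rate Per-molecule probability of a single-strand G>T
#'   lesion.
#' @param qual_high,qual_low,frac_below_q30 Base qualities follow a
#'   two-point mixture: Phred `qual_high` with probability
#'   `1 - frac_below_q30` and `qual_low` otherwise, so the consensus
#'   quality filter is exercised with a controllable knob.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_library()], [expected_stream_sizes()]
#' @export
sim_config <- function(reference = NULL,
                       panel = NULL,
                       n_molecules = 1000L,
                       fragment_mean = 170,
                       fragment_sd = 25,
                       read_length = 100L,
                       umi_len = 2L,
                       spacer = "T",
                       strand_dist = c("ztpois", "pois", "fixed"),
                       strand_mean = 1.2,
                       seq_error_rate = 1e-3,
                       oxidation_rate = 0,
                       qual_high = 37L,
                       qual_low = 25L,
                       frac_below_q30 = 0.05) {
  strand_dist <- match.arg(strand_dist)
  if (is.null(reference)) reference <- toy_reference()
  reference <- as_reference(reference)
  if (is.null(panel)) panel <- toy_panel()
  stopifnot(
    all(c("contig", "start", "end") %in% names(panel)),
    all(panel$contig %in% names(reference)),
    all(panel$start >= 1),
    all(panel$end <= nchar(reference)[match(panel$contig, names(reference))]),
    n_molecules >= 1,
    read_length >= 4,
    seq_error_rate >= 0, seq_error_rate <= 1,
    oxidation_rate >= 0, oxidation_rate <= 1,
    frac_below_q30 >= 0, frac_below_q30 <= 1,
    nchar(spacer) == 1L
  )
  structure(
    list(
      reference = reference, panel = tibble::as_tibble(panel),
      n_molecules = as.integer(n_molecules),
      fragment_mean = fragment_mean, fragment_sd = fragment_sd,
      read_length = as.integer(read_length),
      umi_len = as.integer(umi_len), spacer = spacer,
      strand_dist = strand_dist, strand_mean = strand_mean,
      seq_error_rate = seq_error_rate, oxidation_rate = oxidation_rate,
      qual_high = as.integer(qual_high), qual_low = as.integer(qual_low),
      frac_below_q30 = frac_below_q30
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  reference:", length(x$reference), "contig(s),",
      sum(nchar(x$reference)), "bp; panel:", nrow(x$panel), "target(s),",
      sum(x$panel$end - x$panel$start + 1), "bp\n")
  cat("  molecules:", x$n_molecules,
      sprintf("| fragment %g +/- %g bp | reads %d bp\n",
              x$fragment_mean, x$fragment_sd, x$read_length))
  cat(sprintf("  per-strand reads: %s(%g) | error %g | oxidation %g\n",
              x$strand_dist, x$strand_mean, x$seq_error_rate,
              x$oxidation_rate))
  invisible(x)
}

#' @noRd
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
  } else {
    out <- reference
  }
  stopifnot(is.character(out), !is.null(names(out)), all(nchar(out) > 0))
  out
}

#' Generate a random toy reference genome
#'
#' Uniform-base contigs suitable as a synthetic mapping target for the read
#' simulator.
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return Named character vector of contig sequences.
#' @export
sim_reference <- function(contig_lengths = c(toy = 50000L), seed = 1L) {
  stopifnot(!is.null(names(contig_lengths)))
  withr::with_seed(seed, {
    vapply(contig_lengths, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Evenly spaced target panel over a reference
#'
#' @param reference Named character vector of contig sequences.
#' @param n_targets Number of intervals (laid out on the first contig).
#' @param target_width Width of each interval in bp.
#' @return Tibble with columns `contig`, `start`, `end` (1-based inclusive).
#' @export
sim_panel <- function(reference, n_targets = 6L, target_width = 1500L) {
  reference <- as_reference(reference)
  contig <- names(reference)[1L]
  len <- nchar(reference[[1L]])
  stopifnot(n_targets * target_width < len - 1000L)
  gap <- (len - n_targets * target_width) %/% (n_targets + 1L)
  start <- gap + (seq_len(n_targets) - 1L) * (target_width + gap) + 1L
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(start + target_width - 1L))
}

#' @noRd
toy_reference <- function() {
  path <- system.file("extdata", "toy_genome.fa", package = "duplexsc")
  if (nzchar(path)) {
    read_reference(path)
  } else {
    sim_reference(c(toy = 50000L), seed = 20190525L)
  }
}

#' @noRd
toy_panel <- function() {
  path <- system.file("extdata", "toy_panel.bed", package = "duplexsc")
  if (nzchar(path)) {
    read_bed(path)
  } else {
    sim_panel(toy_reference())
  }
}

# per-strand read count draws
#' @noRd
draw_strand_counts <- function(n, dist, mean) {
  switch(dist,
    fixed  = rep(as.integer(round(mean)), n),
    pois   = stats::rpois(n, mean),
    ztpois = {
      u <- stats::runif(n, min = stats::dpois(0, mean), max = 1)
      stats::qpois(u, mean)
    }
  )
}

# P(count == 0), P(count == 1), P(count >= 2) for a strand-count distribution
#' @noRd
strand_count_probs <- function(dist, mean) {
  switch(dist,
    fixed = {
      k <- as.integer(round(mean))
      c(p0 = as.numeric(k == 0), p1 = as.numeric(k == 1),
        p2 = as.numeric(k >= 2))
    },
    pois = c(p0 = stats::dpois(0, mean), p1 = stats::dpois(1, mean),
             p2 = stats::ppois(1, mean, lower.tail = FALSE)),
    ztpois = {
      z <- 1 - stats::dpois(0, mean)
      c(p0 = 0, p1 = stats::dpois(1, mean) / z,
        p2 = stats::ppois(1, mean, lower.tail = FALSE) / z)
    }
  )
}

#' Simulate a duplex-UMI sequencing library with ground truth
#'
#' Draws template molecules from the configured panel, assigns each a UMI
#' pair and per-strand PCR-duplicate read counts, injects substitution
#' errors and optional single-strand oxidative G>T lesions, and emits both
#' raw FASTQ-style read pairs (UMI + spacer + insert, read orientation) and
#' truth-aligned tagged read pairs (reference-forward, as an aligner
#' preserving the tagged read names would report them). The aligned table
#' is the default test path for the pipeline; the FASTQ table feeds
#' [extract_umis()] and external aligners.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness is derived from it.
#' @return A list of class `duplex_sim` with elements
#'   \describe{
#'     \item{truth}{one row per molecule: locus, fragment true sequence,
#'       UMI pair, per-strand read counts, lesion strand/position.}
#'     \item{pairs}{aligned tagged read pairs, one row per read pair
#'       (columns `id`, `barcode`, `rname`, `pos1`, `cigar1`, `seq1`,
#'       `qual1`, idem for mate 2, `strand`, `molecule_id`, injected error
#'       offsets as list-columns).}
#'     \item{reads}{raw read pairs as sequenced (`id`, `seq1`, `qual1`,
#'       `seq2`, `qual2`), UMI and spacer still in place.}
#'     \item{reference, panel, config, seed}{inputs, for provenance.}
#'   }
#' @export
simulate_library <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), simulate_library_impl(config, seed))
}

#' @noRd
simulate_library_impl <- function(cfg, seed) {
  ref <- cfg$reference
  panel <- cfg$panel
  n <- cfg$n_molecules
  rl <- cfg$read_length
  bases <- c("A", "C", "G", "T")

  # --- molecules ---------------------------------------------------------
  widths <- panel$end - panel$start + 1
  iv <- sample.int(nrow(panel), n, replace = TRUE, prob = widths)
  contig <- panel$contig[iv]
  clen <- nchar(ref)[match(contig, names(ref))]
  flen <- as.integer(round(stats::rnorm(n, cfg$fragment_mean, cfg$fragment_sd)))
  flen <- pmax(flen, min(30L, rl))   # shorter fragments read through
  flen <- pmin(flen, clen)
  # fragment must overlap its target interval by >= 1 bp
  lo <- pmax(1L, panel$start[iv] - flen + 1L)
  hi <- pmin(panel$end[iv], clen - flen + 1L)
  fstart <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
  fend <- fstart + flen - 1L

  umi_pool <- as.vector(outer(bases, bases, paste0))
  umi1 <- sample(umi_pool, n, replace = TRUE)
  umi2 <- sample(umi_pool, n, replace = TRUE)

  n_plus <- draw_strand_counts(n, cfg$strand_dist, cfg$strand_mean)
  n_minus <- draw_strand_counts(n, cfg$strand_dist, cfg$strand_mean)

  frag_seq <- unname(substring(ref[match(contig, names(ref))], fstart, fend))

  # oxidative lesions: one reference-G site per damaged molecule, reads of
  # one strand only
  lesion_strand <- rep(NA_character_, n)
  lesion_pos <- rep(NA_integer_, n)
  damaged <- which(stats::runif(n) < cfg$oxidation_rate)
  for (i in damaged) {
    gpos <- gregexpr("G", frag_seq[i], fixed = TRUE)[[1L]]
    if (gpos[1L] == -1L) next
    lesion_pos[i] <- fstart[i] + gpos[sample.int(length(gpos), 1L)] - 1L
    lesion_strand[i] <- sample(c("+", "-"), 1L)
  }

  truth <- tibble::tibble(
    molecule_id = seq_len(n), contig = contig,
    frag_start = fstart, frag_end = fend, frag_len = flen,
    true_seq = frag_seq,
    umi1 = umi1, umi2 = umi2,
    n_plus = n_plus, n_minus = n_minus,
    lesion_strand = lesion_strand, lesion_pos = lesion_pos
  )

  # --- read pairs --------------------------------------------------------
  mol <- c(rep(seq_len(n), n_plus), rep(seq_len(n), n_minus))
  strand <- c(rep("+", sum(n_plus)), rep("-", sum(n_minus)))
  np <- length(mol)
  if (np == 0L) {
    return(empty_sim(truth, ref, panel, cfg, seed))
  }
  ord <- order(mol, strand)
  mol <- mol[ord]; strand <- strand[ord]
  serial <- stats::ave(mol, mol, strand == "+", FUN = seq_along)

  p_contig <- truth$contig[mol]
  p_fs <- fstart[mol]; p_fe <- fend[mol]; p_fl <- flen[mol]
  w <- pmin(rl, p_fl)                       # read-through truncation
  left_pos <- p_fs
  right_pos <- p_fe - w + 1L
  plus <- strand == "+"
  pos1 <- ifelse(plus, left_pos, right_pos)
  pos2 <- ifelse(plus, right_pos, left_pos)
  refidx <- match(p_contig, names(ref))
  seq1 <- unname(substring(ref[refidx], pos1, pos1 + w - 1L))
  seq2 <- unname(substring(ref[refidx], pos2, pos2 + w - 1L))

  # lesions: all reads of the damaged strand report T at the lesion site
  lp <- lesion_pos[mol]
  hit <- !is.na(lp) & strand == lesion_strand[mol]
  for (m in 1:2) {
    pos <- if (m == 1) pos1 else pos2
    rows <- which(hit & lp >= pos & lp <= pos + w - 1L)
    if (length(rows)) {
      off <- lp[rows] - pos[rows] + 1L
      if (m == 1) substring(seq1[rows], off, off) <- "T"
      else substring(seq2[rows], off, off) <- "T"
    }
  }

  # substitution channel: independent per read copy
  err1 <- inject_errors(seq1, cfg$seq_error_rate, bases)
  err2 <- inject_errors(seq2, cfg$seq_error_rate, bases)
  seq1 <- err1$seq; seq2 <- err2$seq

  qual1 <- draw_quals(w, cfg)
  qual2 <- draw_quals(w, cfg)

  barcode <- ifelse(plus, paste0(umi1[mol], umi2[mol]),
                    paste0(umi2[mol], umi1[mol]))
  id <- paste0("m", mol, ifelse(plus, "p", "n"), serial)
  cig <- paste0(w, "M")

  pairs <- tibble::tibble(
    id = id, barcode = barcode, rname = p_contig, strand = strand,
    pos1 = pos1, cigar1 = cig, seq1 = seq1, qual1 = qual1,
    pos2 = pos2, cigar2 = cig, seq2 = seq2, qual2 = qual2,
    molecule_id = mol,
    err_off1 = err1$offsets, err_off2 = err2$offsets
  )

  # --- raw FASTQ pairs (read orientation, UMI + spacer prepended) --------
  umi_r1 <- ifelse(plus, umi1[mol], umi2[mol])
  umi_r2 <- ifelse(plus, umi2[mol], umi1[mol])
  prefix_q <- strrep(.qual_chars[cfg$qual_high + 1L], cfg$umi_len + 1L)
  r1_seq <- ifelse(plus, seq1, revcomp(seq1))
  r2_seq <- ifelse(plus, revcomp(seq2), seq2)
  r1_q <- ifelse(plus, qual1, str_rev(qual1))
  r2_q <- ifelse(plus, str_rev(qual2), qual2)
  reads <- tibble::tibble(
    id = id,
    seq1 = paste0(umi_r1, cfg$spacer, r1_seq),
    qual1 = paste0(prefix_q, r1_q),
    seq2 = paste0(umi_r2, cfg$spacer, r2_seq),
    qual2 = paste0(prefix_q, r2_q)
  )

  structure(
    list(truth = truth, pairs = pairs, reads = reads,
         reference = ref, panel = panel, config = cfg, seed = seed),
    class = "duplex_sim"
  )
}

#' @noRd
empty_sim <- function(truth, ref, panel, cfg, seed) {
  structure(
    list(
      truth = truth,
      pairs = tibble::tibble(
        id = character(), barcode = character(), rname = character(),
        strand = character(), pos1 = integer(), cigar1 = character(),
        seq1 = character(), qual1 = character(), pos2 = integer(),
        cigar2 = character(), seq2 = character(), qual2 = character(),
        molecule_id = integer(), err_off1 = list(), err_off2 = list()
      ),
      reads = tibble::tibble(id = character(), seq1 = character(),
                             qual1 = character(), seq2 = character(),
                             qual2 = character()),
      reference = ref, panel = panel, config = cfg, seed = seed
    ),
    class = "duplex_sim"
  )
}

# Bernoulli(e) substitutions per base; returns mutated strings and the
# read-local offsets of the injected errors (list-column)
#' @noRd
inject_errors <- function(seqs, rate, bases) {
  n <- length(seqs)
  offsets <- rep(list(integer()), n)
  if (rate <= 0 || n == 0L) return(list(seq = seqs, offsets = offsets))
  w <- nchar(seqs)
  k <- stats::rbinom(n, w, rate)
  ev_read <- rep(seq_len(n), k)
  if (length(ev_read)) {
    ev_off <- 1L + as.integer(floor(stats::runif(length(ev_read)) * w[ev_read]))
    dup <- duplicated(cbind(ev_read, ev_off))
    ev_read <- ev_read[!dup]; ev_off <- ev_off[!dup]
    alt_pick <- sample.int(3L, length(ev_read), replace = TRUE)
    for (j in seq_along(ev_read)) {
      i <- ev_read[j]; o <- ev_off[j]
      cur <- substr(seqs[i], o, o)
      alt <- bases[bases != cur]
      if (length(alt) == 3L) {        # leave non-ACGT bases untouched
        substr(seqs[i], o, o) <- alt[alt_pick[j]]
        offsets[[i]] <- c(offsets[[i]], o)
      }
    }
  }
  list(seq = seqs, offsets = offsets)
}

# two-point quality mixture as Phred+33 strings, one per read
#' @noRd
draw_quals <- function(widths, cfg) {
  tot <- sum(widths)
  if (tot == 0L) return(rep("", length(widths)))
  low <- stats::runif(tot) < cfg$frac_below_q30
  q <- ifelse(low, cfg$qual_low, cfg$qual_high)
  big <- paste(.qual_chars[q + 1L], collapse = "")
  ends <- cumsum(widths)
  substring(big, ends - widths + 1L, ends)
}

#' @export
print.duplex_sim <- function(x, ...) {
  cat("<duplex_sim>", nrow(x$truth), "molecules,", nrow(x$pairs),
      "read pairs (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Analytic expected stream sizes for a simulated library
#'
#' Closed-form expected counts (and binomial standard deviations) of the
#' pipeline's output streams given the per-strand read-count distribution:
#' a strand with >= 2 reads collapses to an SSCS; a singleton strand facing
#' an SSCS is corrected by SSCS; two facing singletons correct one another;
#' a singleton with an unsequenced complementary strand stays uncorrected.
#' A duplex consensus forms whenever both strands yield a consensus read
#' (both >= 2 without Singleton Correction; both >= 1 with it).
#'
#' @param config A [sim_config()] (only the strand-count distribution and
#'   `n_molecules` are used).
#' @return Tibble with columns `stream`, `expected`, `sd`.
#' @export
expected_stream_sizes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- strand_count_probs(config$strand_dist, config$strand_mean)
  n <- config$n_molecules
  p0 <- p[["p0"]]; p1 <- p[["p1"]]; p2 <- p[["p2"]]
  # per-molecule event probabilities; sscs can occur on both strands
  rows <- list(
    sscs                 = list(e = 2 * p2,      v = 2 * p2 * (1 - p2)),
    singletons           = list(e = 2 * p1,      v = 2 * p1 * (1 - p1)),
    sc_by_sscs           = list(e = 2 * p1 * p2, v = 2 * p1 * p2 * (1 - 2 * p1 * p2)),
    sc_by_singleton_pair = list(e = p1^2,        v = p1^2 * (1 - p1^2)),
    uncorrected          = list(e = 2 * p1 * p0, v = 2 * p1 * p0 * (1 - 2 * p1 * p0)),
    dcs_traditional      = list(e = p2^2,        v = p2^2 * (1 - p2^2)),
    dcs_sc               = list(e = (p1 + p2)^2, v = (p1 + p2)^2 * (1 - (p1 + p2)^2))
  )
  tibble::tibble(
    stream = names(rows),
    expected = unname(n * vapply(rows, `[[`, numeric(1), "e")),
    sd = unname(sqrt(n * vapply(rows, `[[`, numeric(1), "v")))
  )
}

#' Collapse coincidental molecule collisions in a truth table
#'
#' Two simulated molecules drawn with identical fragment coordinates and
#' identical UMI pairs are indistinguishable to any UMI-based method: their
#' reads form one read family per strand. This helper merges such
#' collisions (summing per-strand read counts) so that stream sizes
#' computed from the truth table match what a correct pipeline can
#' observe. Collisions are rare but real at large molecule counts.
#'
#' @param truth A [simulate_library()] `$truth` table.
#' @return The truth table with colliding molecules merged; the number of
#'   merges is recorded in attribute `"n_collisions"`.
#' @export
collapse_truth <- function(truth) {
  merged <- dplyr::summarise(
    dplyr::group_by(truth, .data$contig, .data$frag_start, .data$frag_end,
                    .data$umi1, .data$umi2),
    molecule_id = min(.data$molecule_id),
    n_plus = sum(.data$n_plus), n_minus = sum(.data$n_minus),
    .groups = "drop")
  attr(merged, "n_collisions") <- nrow(truth) - nrow(merged)
  merged
}
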