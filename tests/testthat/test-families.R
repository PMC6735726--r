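# Family keys, duplex transform/key, alignment filtering, and the
# brute-force partition oracle.

test_that("identical duplicate pairs get identical keys; key components discriminate", {
  dup <- make_family(2, id = "d")
  keyed <- assign_families(dup)
  expect_equal(keyed$family_key[1], keyed$family_key[2])
  expect_equal(keyed$family_size, c(2L, 2L))

  # same fragment, one read soft-clip variant: different family
  clip <- make_pair(id = "c", cigar1 = "9M1S",
                    seq1 = "ACGTACGTAC")
  both <- assign_families(dplyr::bind_rows(make_pair(id = "a"), clip))
  expect_false(both$family_key[1] == both$family_key[2])

  # differing barcode, position, or strand all separate families
  vars <- dplyr::bind_rows(
    make_pair(id = "x"),
    make_pair(id = "x2", barcode = "ACGA"),
    make_pair(id = "x3", pos1 = 101L),
    make_pair(id = "x4", strand = "-")
  )
  expect_equal(dplyr::n_distinct(assign_families(vars)$family_key), 4L)
})

test_that("missing barcode is a pipeline-order violation", {
  p <- make_pair(); p$barcode <- NA_character_
  expect_error(assign_families(p), "extraction")
})

test_that("duplex transform interchanges barcode halves and is an involution", {
  key <- assign_families(make_pair(barcode = "ACGT"))$family_key
  t1 <- duplex_transform(key)
  # AC/GT barcodes become GT/AC on the complementary strand
  expect_match(t1, "^GTAC/")
  expect_match(t1, "/-/")
  expect_equal(duplex_transform(t1), key)

  # the complementary pair built by hand carries exactly the transform key
  comp <- complement_pair(make_pair(barcode = "ACGT"))
  expect_equal(assign_families(comp)$family_key, t1)
})

test_that("duplex key is strand-canonical and collision-free across molecules", {
  p <- make_pair(barcode = "ACGT")
  both <- assign_families(dplyr::bind_rows(p, complement_pair(p)))
  expect_equal(both$duplex_key[1], both$duplex_key[2])
  expect_equal(dplyr::n_distinct(both$family_key), 2L)

  sim <- simulate_library(small_sim_config(n_molecules = 400,
                                           strand_dist = "fixed",
                                           strand_mean = 1), seed = 21)
  keyed <- assign_families(sim$pairs)
  # every simulated duplex pair: plus-strand key transforms to minus key
  agg <- dplyr::summarise(
    dplyr::group_by(keyed, .data$molecule_id),
    one_duplex = dplyr::n_distinct(.data$duplex_key) == 1L,
    .groups = "drop")
  expect_true(all(agg$one_duplex))
  # distinct molecules yield distinct duplex keys
  expect_equal(dplyr::n_distinct(keyed$duplex_key),
               dplyr::n_distinct(keyed$molecule_id))
})

test_that("hash grouping matches the brute-force pairwise partition", {
  for (s in 1:5) {
    sim <- simulate_library(small_sim_config(n_molecules = 25,
                                             strand_dist = "ztpois",
                                             strand_mean = 2.5),
                            seed = 100 + s)
    pairs <- sim$pairs
    expect_lte(nrow(pairs), 200L)
    keyed <- assign_families(pairs)
    oracle <- brute_force_partition(pairs)
    # same partition up to labelling
    expect_equal(dplyr::n_distinct(keyed$family_key),
                 dplyr::n_distinct(oracle))
    tab <- table(keyed$family_key, oracle)
    expect_true(all(colSums(tab > 0) == 1L))
    expect_true(all(rowSums(tab > 0) == 1L))
    # sum of family sizes = number of kept pairs
    fam <- dplyr::distinct(keyed, .data$family_key, .data$family_size)
    expect_equal(sum(fam$family_size), nrow(pairs))
  }
})

test_that("alignment filter drops unmapped/mate-unmapped/multi-mapped and orphans", {
  sim <- simulate_library(small_sim_config(n_molecules = 60,
                                           strand_dist = "fixed",
                                           strand_mean = 1), seed = 33)
  sam <- pairs_to_sam(sim$pairs)
  n_rec <- nrow(sam)

  # inject failures: 10 pairs mate-unmapped, 3 secondary records, 2 orphans
  qn <- unique(sam$qname)
  bad_pairs <- qn[1:10]
  sam$flag[sam$qname %in% bad_pairs] <-
    sam$flag[sam$qname %in% bad_pairs] + 8L
  clean_rows <- which(!(sam$qname %in% c(bad_pairs, qn[11:12])))[1:3]
  secondary <- sam[clean_rows, ]; secondary$flag <- secondary$flag + 256L
  sam <- dplyr::bind_rows(sam, secondary)
  orphan_rows <- which(sam$qname %in% qn[11:12] &
                         bitwAnd(sam$flag, 64L) > 0L)
  sam <- sam[-orphan_rows, ]

  kept <- filter_alignments(sam)
  dropped <- attr(kept, "dropped")
  expect_equal(dropped$n[dropped$reason == "mate-unmapped"], 20L)
  expect_equal(dropped$n[dropped$reason == "multi-alignment"], 3L)
  expect_equal(dropped$n[dropped$reason == "orphan"], 2L)
  # orphaning a pair costs both mates: the missing record and its mate
  expect_equal(nrow(kept), n_rec - 20L - 4L)

  # round-trip: SAM -> filtered -> paired reproduces the surviving pairs
  paired <- pair_alignments(kept)
  removed_ids <- sub("\\|.*$", "", c(bad_pairs, qn[11:12]))
  orig <- sim$pairs[!sim$pairs$id %in% removed_ids, ]
  m <- match(orig$id, paired$id)
  expect_false(anyNA(m))
  expect_equal(paired$seq1[m], orig$seq1)
  expect_equal(paired$pos2[m], orig$pos2)
  expect_equal(paired$strand[m], orig$strand)
  expect_equal(paired$barcode[m], orig$barcode)
})

test_that("pairing requires tagged names", {
  sim <- simulate_library(small_sim_config(n_molecules = 5,
                                           strand_dist = "fixed",
                                           strand_mean = 1), seed = 2)
  sam <- pairs_to_sam(sim$pairs)
  sam$qname <- sub("\\|.*$", "", sam$qname)
  expect_error(pair_alignments(sam), "barcode")
})

test_that("SAM text round-trips through read_sam/write_sam", {
  sim <- simulate_library(small_sim_config(n_molecules = 30), seed = 8)
  sam <- pairs_to_sam(sim$pairs)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, path, reference = sim$reference)
  back <- read_sam(path)
  expect_equal(as.data.frame(back), as.data.frame(sam), ignore_attr = TRUE)
  expect_true(any(grepl("^@SQ", attr(back, "header"))))
})
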