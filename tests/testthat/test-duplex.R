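# Duplex consensus formation and the merged unique-molecule table.

test_that("identical complementary consensuses yield an equal DCS", {
  fam <- make_family(2, id = "p")
  comp <- complement_pair(make_family(2, id = "n"))
  cons <- collapse_families(assign_families(dplyr::bind_rows(fam, comp)))
  plus <- cons[cons$strand == "+", ]; minus <- cons[cons$strand == "-", ]
  dcs <- form_dcs(plus, minus)
  expect_equal(dcs$provenance, "DCS")
  expect_equal(dcs$seq1, plus$seq1)
  expect_equal(dcs$seq2, plus$seq2)
  expect_equal(dcs$family_size, 4L)
  expect_equal(dcs$strand, "+")
  # the DCS name is the canonical duplex key: byte-stable across strands
  expect_equal(dcs$family_key, plus$duplex_key)
  expect_error(form_dcs(minus, plus), "complementary")
})

test_that("a strand-asymmetric artefact is masked in the DCS", {
  fam <- make_family(2, id = "p")
  fam$seq1 <- mutate_base(fam$seq1, 3L, "T")   # G>T on all plus reads
  comp <- complement_pair(make_family(2, id = "n"))
  cons <- collapse_families(assign_families(dplyr::bind_rows(fam, comp)))
  dcs <- form_dcs(cons[cons$strand == "+", ], cons[cons$strand == "-", ])
  expect_equal(substr(dcs$seq1, 3, 3), "N")
  expect_equal(substr(dcs$seq1, 4, 10), substr(comp$seq2[1], 4, 10))
  # a true variant present on both strands is retained
  fam2 <- make_family(2, id = "p2", barcode = "TTGG")
  fam2$seq1 <- mutate_base(fam2$seq1, 3L, "T")
  comp2 <- complement_pair(make_family(2, id = "n2", barcode = "TTGG"))
  comp2$seq2 <- mutate_base(comp2$seq2, 3L, "T")
  cons2 <- collapse_families(assign_families(dplyr::bind_rows(fam2, comp2)))
  dcs2 <- form_dcs(cons2[cons2$strand == "+", ],
                   cons2[cons2$strand == "-", ])
  expect_equal(substr(dcs2$seq1, 3, 3), "T")
})

test_that("strand pairing is a perfect matching with leftovers unpaired", {
  cons <- dplyr::bind_rows(
    collapse_families(assign_families(dplyr::bind_rows(
      make_family(2, id = "a", barcode = "AACC"),
      complement_pair(make_family(3, id = "ac", barcode = "AACC"))))),
    collapse_families(assign_families(
      make_family(2, id = "b", barcode = "GGTT", pos1 = 400L, pos2 = 450L)))
  )
  out <- pair_strands(cons)
  expect_equal(nrow(out$dcs), 1L)
  expect_equal(nrow(out$unpaired), 1L)
  expect_equal(out$unpaired$barcode, "GGTT")
  # an SSCS + its SC-corrected complementary singleton form a DCS
  mix <- collapse_families(assign_families(dplyr::bind_rows(
    make_family(2, id = "c", barcode = "CCGG", pos1 = 700L, pos2 = 750L),
    complement_pair(make_pair(id = "cc", barcode = "CCGG",
                              pos1 = 700L, pos2 = 750L)))))
  mix <- correct_singletons(mix)
  out2 <- pair_strands(mix)
  expect_equal(nrow(out2$dcs), 1L)
  expect_equal(sort(unique(mix$provenance)), c("SC_by_SSCS", "SSCS"))
  # without Singleton Correction eligibility the singleton cannot pair
  out3 <- pair_strands(collapse_families(assign_families(dplyr::bind_rows(
    make_family(2, id = "d", barcode = "TTAA", pos1 = 900L, pos2 = 950L),
    complement_pair(make_pair(id = "dc", barcode = "TTAA",
                              pos1 = 900L, pos2 = 950L))))),
    use_sc = FALSE)
  expect_equal(nrow(out3$dcs), 0L)
  expect_equal(nrow(out3$unpaired), 1L)
})

cons_merge_fixture <- function() {
  cons <- dplyr::bind_rows(
    collapse_families(assign_families(dplyr::bind_rows(
      make_family(2, id = "a", barcode = "AACC"),
      complement_pair(make_family(2, id = "ac", barcode = "AACC"))))),
    collapse_families(assign_families(
      make_family(2, id = "b", barcode = "GGTT", pos1 = 400L, pos2 = 450L))),
    collapse_families(assign_families(
      make_pair(id = "c", barcode = "CCAA", pos1 = 600L, pos2 = 650L)))
  )
  cons <- correct_singletons(cons)
  duplex <- pair_strands(cons)
  list(dcs = duplex$dcs, unpaired = duplex$unpaired,
       uncorr = cons[cons$provenance == "uncorrected_singleton", ])
}

test_that("merged unique table refuses duplicate molecule representation", {
  cons <- cons_merge_fixture()
  expect_error(merge_all_unique(cons$dcs, cons$dcs[0, ], cons$dcs),
               "represented more than once")
  merged <- merge_all_unique(cons$dcs, cons$unpaired, cons$uncorr)
  expect_equal(nrow(merged), nrow(cons$dcs) + nrow(cons$unpaired) +
                 nrow(cons$uncorr))
})

test_that("pipeline DCS count equals molecules sequenced on both strands", {
  sim <- simulate_library(small_sim_config(n_molecules = 400,
                                           strand_dist = "pois",
                                           strand_mean = 1.4), seed = 17)
  run_sc <- run_duplex_pipeline(sim$pairs, sc = TRUE)
  run_tr <- run_duplex_pipeline(sim$pairs, sc = FALSE)
  want <- truth_stream_counts(sim$truth)
  expect_equal(nrow(run_sc$dcs), want$dcs_sc)
  expect_equal(nrow(run_tr$dcs), want$dcs_traditional)
  # monotone benefit of rescue
  expect_gte(nrow(run_sc$dcs), nrow(run_tr$dcs))
  # molecules fully recovered appear exactly once in the merged table
  expect_equal(dplyr::n_distinct(run_sc$unique$duplex_key),
               nrow(run_sc$unique))
})

test_that("error-free duplex output reproduces every true molecule sequence", {
  sim <- simulate_library(small_sim_config(n_molecules = 120,
                                           strand_dist = "fixed",
                                           strand_mean = 2,
                                           seq_error_rate = 0,
                                           frac_below_q30 = 0), seed = 29)
  run <- run_duplex_pipeline(sim$pairs)
  expect_equal(nrow(run$dcs), nrow(sim$truth))
  keyed <- run$pairs
  mol <- keyed$molecule_id[match(run$dcs$duplex_key, keyed$duplex_key)]
  tr <- sim$truth[mol, ]
  off1 <- run$dcs$pos1 - tr$frag_start + 1L
  off2 <- run$dcs$pos2 - tr$frag_start + 1L
  expect_equal(run$dcs$seq1,
               substr(tr$true_seq, off1, off1 + nchar(run$dcs$seq1) - 1L))
  expect_equal(run$dcs$seq2,
               substr(tr$true_seq, off2, off2 + nchar(run$dcs$seq2) - 1L))
})
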