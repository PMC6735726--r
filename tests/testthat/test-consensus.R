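# Consensus base calling and family collapsing.

test_that("consensus base honours the >= cutoff boundary and quality gate", {
  cfg <- consensus_config()
  # proportion exactly 0.7 is called (rule is greater-than-or-equal)
  expect_equal(consensus_base(c(rep("A", 7), rep("G", 3)), rep(37L, 10),
                              cfg), "A")
  # 0.6 falls short
  expect_equal(consensus_base(c(rep("A", 6), rep("G", 4)), rep(37L, 10),
                              cfg), "N")
  # sub-Q30 bases are removed before the proportion is evaluated: the
  # two low-quality A reads drop out and the lone G is unanimous
  expect_equal(consensus_base(c("A", "A", "G"), c(29L, 29L, 35L), cfg), "G")
  # empty survivor set
  expect_equal(consensus_base(c("A", "A"), c(10L, 10L), cfg), "N")
  # tie can never reach a cutoff above 0.5
  expect_equal(consensus_base(c(rep("A", 5), rep("G", 5)), rep(37L, 10),
                              cfg), "N")
  # strict comparator additionally drops bases at exactly the threshold
  strict <- consensus_config(quality_strict = TRUE)
  col <- c(rep("A", 7), rep("G", 3))
  q <- c(rep(30L, 7), rep(35L, 3))
  expect_equal(consensus_base(col, q, cfg), "A")      # 7/10 survivors
  expect_equal(consensus_base(col, q, strict), "G")   # A's removed
})

test_that("raising the cutoff never converts an N into a base", {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(42, {
    for (i in 1:200) {
      col <- sample(bases, sample(2:8, 1), replace = TRUE)
      q <- sample(c(25L, 37L), length(col), replace = TRUE)
      lo <- consensus_base(col, q, consensus_config(consensus_cutoff = 0.6))
      hi <- consensus_base(col, q, consensus_config(consensus_cutoff = 0.9))
      if (lo == "N") expect_equal(hi, "N")
    }
  })
})

test_that("unanimous families collapse to the read; size-1 routes to singletons", {
  fam <- dplyr::bind_rows(make_family(3, id = "f"),
                          make_pair(id = "s", barcode = "GGTT"))
  cons <- collapse_families(assign_families(fam))
  expect_setequal(cons$provenance, c("singleton", "SSCS"))
  sscs <- cons[cons$provenance == "SSCS", ]
  expect_equal(sscs$seq1, fam$seq1[1])
  expect_equal(sscs$seq2, fam$seq2[1])
  expect_equal(sscs$family_size, 3L)
  # pairing tag carries barcode, ordered mapping, strand, and family size
  expect_match(sscs$pairing_tag, "^ACGT:toy:100:150:plus:")
  expect_match(sscs$pairing_tag, ":3$")
  streams <- route_families(cons)
  expect_equal(nrow(streams$sscs), 1L)
  expect_equal(nrow(streams$singletons), 1L)
})

test_that("a minority error in one member is absent from the SSCS", {
  # 3-of-4 agreement (0.75) clears the 0.7 cutoff: error fully removed
  fam <- make_family(4, id = "f")
  fam$seq1[2] <- mutate_base(fam$seq1[2], 4L, "A")  # T -> A at offset 4
  cons <- collapse_families(assign_families(fam))
  expect_equal(cons$seq1, make_pair()$seq1)
  # 2-of-3 agreement (0.67) falls short: position masked, error still
  # absent from the consensus
  fam3 <- make_family(3, id = "g", barcode = "TTAA")
  fam3$seq1[2] <- mutate_base(fam3$seq1[2], 4L, "A")
  cons3 <- collapse_families(assign_families(fam3))
  expect_equal(substr(cons3$seq1, 4, 4), "N")
  expect_equal(substr(cons3$seq1, 5, 5), substr(make_pair()$seq1, 5, 5))
})

test_that("ties and low-quality columns are masked with N, quality 0", {
  fam <- make_family(2, id = "f")
  fam$seq1[2] <- mutate_base(fam$seq1[2], 1L, "C")  # 1x A vs 1x C
  fam$qual1 <- c(paste0(strrep(Q37, 5), Q25, strrep(Q37, 4)),
                 paste0(strrep(Q37, 5), Q25, strrep(Q37, 4)))
  cons <- collapse_families(assign_families(fam))
  expect_equal(substr(cons$seq1, 1, 1), "N")   # tie
  expect_equal(substr(cons$seq1, 6, 6), "N")   # all bases below Q30
  expect_equal(substr(cons$qual1, 1, 1), "!")
  expect_equal(substr(cons$qual1, 6, 6), "!")
  # surviving positions keep the maximum agreeing quality
  expect_equal(substr(cons$qual1, 2, 2), Q37)
})

test_that("the vectorised collapse agrees with per-column consensus_base", {
  sim <- simulate_library(small_sim_config(n_molecules = 60,
                                           strand_dist = "ztpois",
                                           strand_mean = 3,
                                           seq_error_rate = 0.02,
                                           frac_below_q30 = 0.3), seed = 77)
  keyed <- assign_families(sim$pairs)
  cons <- collapse_families(keyed)
  sscs <- cons[cons$provenance == "SSCS", ]
  cfg <- consensus_config()
  for (i in seq_len(min(10L, nrow(sscs)))) {
    fam <- keyed[keyed$family_key == sscs$family_key[i], ]
    expected <- vapply(seq_len(nchar(fam$seq1[1])), function(p) {
      consensus_base(substr(fam$seq1, p, p),
                     utf8ToInt(paste(substr(fam$qual1, p, p),
                                     collapse = "")) - 33L, cfg)
    }, character(1))
    expect_equal(sscs$seq1[i], paste(expected, collapse = ""))
  }
})

test_that("with error-free reads every SSCS equals the true strand sequence", {
  sim <- simulate_library(small_sim_config(n_molecules = 150,
                                           strand_dist = "fixed",
                                           strand_mean = 3,
                                           seq_error_rate = 0,
                                           frac_below_q30 = 0), seed = 13)
  keyed <- assign_families(sim$pairs)
  cons <- collapse_families(keyed)
  expect_true(all(cons$provenance == "SSCS"))
  # map each SSCS back to its molecule and compare to the truth fragment
  mol <- keyed$molecule_id[match(cons$family_key, keyed$family_key)]
  tr <- sim$truth[mol, ]
  off1 <- cons$pos1 - tr$frag_start + 1L
  expect_equal(cons$seq1,
               substr(tr$true_seq, off1, off1 + nchar(cons$seq1) - 1L))
})

test_that("SSCS error rate is below the uncollapsed error rate", {
  sim <- simulate_library(small_sim_config(n_molecules = 400,
                                           strand_dist = "fixed",
                                           strand_mean = 3,
                                           seq_error_rate = 5e-3), seed = 55)
  run <- run_duplex_pipeline(sim$pairs, sc = FALSE)
  raw <- error_report(sim$pairs, sim$reference, sim$panel)
  sscs <- error_report(run$cons[run$cons$provenance == "SSCS", ],
                       sim$reference, sim$panel)
  expect_lt(sscs$error_rate, raw$error_rate)
})
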