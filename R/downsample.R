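# In-silico downsampling of paired reads and depth sweeps.

#' Downsample read pairs to a target fragment coverage
#'
#' Sampling is by template: each read pair (both mates together) is kept
#' with probability `target_cov / current_cov`, estimated from
#' [fragment_coverage()], so mates are never orphaned. The draw is
#' Bernoulli per template, unbiased, and deterministic given the seed;
#' the achieved coverage concentrates within a few percent of the target
#' at realistic depths.
#'
#' @param pairs Pair-level tibble.
#' @param target_cov Desired mean fragment coverage over `panel`.
#' @param panel Panel tibble (for coverage estimation).
#' @param seed Integer seed.
#' @return The sampled subset of `pairs` (row order preserved).
#' @export
downsample_pairs <- function(pairs, target_cov, panel, seed = 1L) {
  cur <- fragment_coverage(pairs, panel)
  if (target_cov > cur) {
    stop(sprintf("target coverage %.1f exceeds current coverage %.1f",
                 target_cov, cur), call. = FALSE)
  }
  frac <- target_cov / cur
  keep <- withr::with_seed(as.integer(seed),
                           stats::runif(nrow(pairs)) < frac)
  if (frac == 1) keep <- rep(TRUE, nrow(pairs))
  pairs[keep, ]
}

#' Sweep the pipeline across sequencing depths
#'
#' Downsamples the library to each target coverage, runs the full
#' pipeline with and without Singleton Correction on each draw, and
#' records the coverage report, so efficiency, recovery, singleton
#' fraction, and correction rate can be charted against depth.
#'
#' @param pairs Pair-level tibble (the full-depth library).
#' @param targets Numeric vector of target coverages, sorted descending.
#' @param panel Panel tibble.
#' @param repeats Independent draws per target.
#' @param seed Integer base seed; draw `(i, j)` uses `seed + 97 * i + j`.
#' @param config A [consensus_config()].
#' @return Long tibble: one row per (target, repeat, sc) with the
#'   [coverage_report()] columns.
#' @export
depth_sweep <- function(pairs, targets, panel, repeats = 10L, seed = 1L,
                        config = consensus_config()) {
  stopifnot(!is.unsorted(rev(targets)))
  grid <- tidyr::expand_grid(target = targets, rep = seq_len(repeats))
  purrr::pmap_dfr(grid, function(target, rep) {
    sub <- downsample_pairs(pairs, target, panel,
                            seed = as.integer(seed + 97 * match(
                              target, targets) + rep))
    purrr::map_dfr(c(TRUE, FALSE), function(use_sc) {
      run <- run_duplex_pipeline(sub, config = config, sc = use_sc)
      rep_tbl <- coverage_report(run, panel)
      dplyr::bind_cols(
        tibble::tibble(target = target, rep = rep, sc = use_sc),
        rep_tbl)
    })
  })
}
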