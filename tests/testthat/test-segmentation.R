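test_that("window profiles bin hit starts and conserve counts", {
  hits <- S4Vectors::DataFrame(scaffold = rep("s", 10L),
                               pos0 = as.integer(seq(0, 9000, by = 1000)))
  p <- windowProfile(hits, "s", length_bp = 10000L, window_bp = 10000L)
  expect_equal(length(windowCounts(p)), 1L)
  expect_equal(windowDensities(p), 1.0)        # 10 hits over 10 kb

  # all hits in the first half leave the second half at zero
  hits2 <- S4Vectors::DataFrame(scaffold = rep("s", 50L),
                                pos0 = sort(as.integer(
                                  withr::with_seed(51, sample(0:49999, 50L)))))
  p2 <- windowProfile(hits2, "s", length_bp = 100000L, window_bp = 10000L)
  expect_true(all(windowCounts(p2)[6:10] == 0L))
  expect_equal(sum(windowCounts(p2)), 50L)

  # short last window is normalised by its true length
  hits3 <- S4Vectors::DataFrame(scaffold = rep("s", 5L),
                                pos0 = c(0L, 1L, 2L, 10000L, 10001L))
  p3 <- windowProfile(hits3, "s", length_bp = 12000L, window_bp = 10000L)
  expect_equal(windowDensities(p3), c(3 / 10, 2 / 2))
  expect_error(windowProfile(hits3, "s", length_bp = 12000L,
                             window_bp = 500L), ">= 1000")
})

test_that("profile totals reconstruct the per-scaffold unique hits", {
  run <- sharedDefaultRun()
  for (sc in run$dens$scaffold[c(1L, 10L, 30L)]) {
    p <- windowProfile(run$ht, sc)
    expect_equal(sum(windowCounts(p)),
                 run$dens$unique_hits[run$dens$scaffold == sc])
    wlen <- diff(c(armAnchor:::.windowStarts(p), p@length_bp))
    expect_equal(round(sum(windowDensities(p) * wlen) / 1000),
                 run$dens$unique_hits[run$dens$scaffold == sc])
  }
})

test_that("gap detection needs both sparseness and span", {
  dense <- rep(300L, 10L)   # 30 hits/kb in 10 kb windows
  # 12 empty windows (120 kb) inside dense flanks
  p <- profileFromCounts(c(dense, rep(0L, 12L), dense))
  g <- detectGaps(p)
  expect_equal(length(g), 1L)
  expect_equal(g$span_bp, 120000L)
  expect_equal(GenomicRanges::start(g), 100001L)
  expect_false(g$terminal)
  expect_equal(g$mean_density_inside, 0)

  # 9 empty windows (90 kb) stay under the 100 kb minimum
  p9 <- profileFromCounts(c(dense, rep(0L, 9L), dense))
  expect_equal(length(detectGaps(p9)), 0L)

  # a terminal run is reported but flagged
  pt <- profileFromCounts(c(rep(0L, 15L), dense))
  gt <- detectGaps(pt)
  expect_true(gt$terminal)

  # near-zero (sub-cutoff) windows count as gap windows
  plow <- profileFromCounts(c(dense, rep(5L, 12L), dense))
  expect_equal(length(detectGaps(plow, sparse_cutoff = 1.0)), 1L)
  expect_equal(length(detectGaps(plow, sparse_cutoff = 0.4)), 0L)
})

test_that("region segmentation tiles the scaffold with alternating states", {
  dense <- 300L
  p <- profileFromCounts(c(rep(dense, 100L), rep(0L, 80L), rep(dense, 100L)))
  segs <- segmentRegions(p, dense_cutoff = 29.23)
  expect_equal(length(segs), 3L)
  expect_equal(segs$state, c("dense", "sparse", "dense"))
  expect_equal(GenomicRanges::start(segs), c(1L, 1000001L, 1800001L))
  expect_equal(GenomicRanges::end(segs), c(1000000L, 1800000L, 2800000L))

  pu <- profileFromCounts(rep(dense, 120L))
  su <- segmentRegions(pu, dense_cutoff = 29.23)
  expect_equal(length(su), 1L)
  expect_equal(su$state, "dense")
  expect_equal(GenomicRanges::width(su), 1200000L)
})

test_that("short discordant runs are absorbed and short regions merged", {
  dense <- 300L
  # two stray sparse windows inside a dense block are smoothed away
  prof <- profileFromCounts(c(rep(dense, 60L), rep(0L, 2L), rep(dense, 60L)))
  expect_equal(length(segmentRegions(prof, 29.23)), 1L)
  # three in a row exceed max_discordant = 2 but fall below min_region_bp,
  # so they merge into the longer neighbour afterwards
  prof3 <- profileFromCounts(c(rep(dense, 60L), rep(0L, 3L), rep(dense, 60L)))
  expect_equal(length(segmentRegions(prof3, 29.23)), 1L)
  # ... unless the sparse stretch is long enough to stand as a region
  prof_big <- profileFromCounts(c(rep(dense, 60L), rep(0L, 60L),
                                  rep(dense, 60L)))
  expect_equal(length(segmentRegions(prof_big, 29.23)), 3L)
})

test_that("segmentation tiles random profiles exactly", {
  for (seed in 1:8) {
    counts <- withr::with_seed(100 + seed, {
      n <- sample(30:200, 1L)
      as.integer(rpois(n, sample(c(2, 50, 300), n, replace = TRUE)))
    })
    p <- profileFromCounts(counts)
    segs <- segmentRegions(p, dense_cutoff = 10,
                           min_region_bp = 50000L)
    expect_equal(GenomicRanges::start(segs)[1L], 1L)
    expect_equal(GenomicRanges::end(segs)[length(segs)], p@length_bp)
    if (length(segs) > 1L) {
      expect_true(all(GenomicRanges::start(segs)[-1L] ==
                        GenomicRanges::end(segs)[-length(segs)] + 1L))
      expect_true(all(segs$state[-1L] != segs$state[-length(segs)]))
    }
  }
})

test_that("large gaps lie inside sparse regions when cutoffs agree", {
  counts <- c(rep(300L, 80L), rep(0L, 70L), rep(300L, 80L))
  p <- profileFromCounts(counts)
  gaps <- detectGaps(p, sparse_cutoff = 29.23)
  segs <- segmentRegions(p, dense_cutoff = 29.23, max_discordant = 0L)
  big <- gaps[gaps$span_bp >= 500000L]
  sparse <- segs[segs$state == "sparse"]
  for (j in seq_along(big)) {
    inside <- any(GenomicRanges::start(sparse) <= GenomicRanges::start(big)[j] &
                    GenomicRanges::end(sparse) >= GenomicRanges::end(big)[j])
    expect_true(inside)
  }
})

test_that("hybrid candidates need both an on-arm call and an internal gap", {
  calls <- S4Vectors::DataFrame(
    scaffold = c("hyb", "clean", "off"),
    category = factor(c("confirmed-on-arm", "newly-assigned",
                        "under-threshold"),
                      levels = armAnchor:::.CATEGORIES))
  gaps <- GenomicRanges::GRanges(
    c("hyb", "off"), IRanges::IRanges(c(200001L, 1L), c(320000L, 150000L)),
    span_bp = c(120000L, 150000L),
    mean_density_inside = c(0, 0),
    terminal = c(FALSE, TRUE))
  rep_ <- flagHybrids(calls, gaps)
  expect_equal(as.character(rep_$candidates$scaffold), "hyb")
  expect_equal(rep_$n_on_arm, 2L)
  expect_equal(rep_$fraction_flagged, 0.5)
  # an under-threshold scaffold is never flagged, gap or not
  expect_false("off" %in% rep_$candidates$scaffold)

  # 3 flagged among 20 on-arm scaffolds reports the 15% fraction
  calls20 <- S4Vectors::DataFrame(
    scaffold = sprintf("s%02d", 1:20),
    category = factor(rep("confirmed-on-arm", 20L),
                      levels = armAnchor:::.CATEGORIES))
  gaps3 <- GenomicRanges::GRanges(
    sprintf("s%02d", 1:3), IRanges::IRanges(100001L, 220000L),
    span_bp = 120000L, mean_density_inside = 0, terminal = FALSE)
  expect_equal(flagHybrids(calls20, gaps3)$fraction_flagged, 0.15)
})

test_that("an implanted hybrid join is recovered as a coverage gap", {
  cfg <- simConfig(seed = 61, n_scaffolds = 12L,
                   scaffold_length_range = c(50000L, 150000L),
                   n_reads = 40000L, n_hybrid_scaffolds = 1L,
                   hybrid_segment_min = 100000L,
                   boundary_taper_width = 200000L)
  model <- buildGenome(cfg)
  ht <- mapReads(simulateReads(model), model)
  info <- scaffoldInfo(model)
  hyb <- info$scaffold[info$label == "hybrid"]
  gaps <- detectGaps(windowProfile(ht, hyb))
  truth_off <- hybridTruth(model)
  truth_off <- truth_off[truth_off$segment == "off-arm"]
  expect_gte(length(gaps), 1L)
  ov <- GenomicRanges::start(gaps) <= GenomicRanges::end(truth_off) &
    GenomicRanges::end(gaps) >= GenomicRanges::start(truth_off)
  expect_true(any(ov))
  ev <- evaluateAgainstTruth(
    classifyScaffolds(scaffoldDensity(ht),
                      calibrateThreshold(scaffoldDensity(ht),
                                         anchor_id = borderScaffold(model))),
    info, gaps, hybridTruth(model))
  expect_equal(ev$hybrid_sensitivity, 1.0)
  expect_lte(ev$mean_breakpoint_error_bp, 10000)
})

test_that("repeat-induced multimapping does not fake large gaps", {
  # triple the default repeat copy number at reduced scale
  for (seed in 71:73) {
    cfg <- simConfig(seed = seed, n_scaffolds = 20L,
                     scaffold_length_range = c(50000L, 110000L),
                     n_reads = 40000L, boundary_taper_width = 160000L,
                     repeat_copy_number = 30L)
    model <- buildGenome(cfg)
    ht <- mapReads(simulateReads(model), model)
    info <- scaffoldInfo(model)
    on_arm <- setdiff(info$scaffold[info$label == "on-arm"],
                      borderScaffold(model))
    false_gaps <- 0L
    for (sc in on_arm)
      false_gaps <- false_gaps + length(detectGaps(windowProfile(ht, sc)))
    expect_equal(false_gaps, 0L)
  }
})
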