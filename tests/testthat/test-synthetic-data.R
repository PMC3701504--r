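test_that("identical configurations give byte-identical genome and read files", {
  cfg <- smallSimConfig(seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    m <- buildGenome(cfg)
    writeSimulation(m, simulateReads(m), d)
  }
  for (f in c("genome.fasta", "reads.fastq", "truth.tsv", "scaffolds.tsv",
              "priors.tsv", "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("genome structure follows the configuration", {
  cfg <- smallSimConfig(seed = 12)
  model <- buildGenome(cfg)
  info <- scaffoldInfo(model)
  expect_equal(nrow(info), cfg@n_scaffolds)
  expect_false(any(info$label == "hybrid"))  # disabled feature
  expect_equal(sum(info$is_border), 1L)
  expect_equal(info$label[info$is_border], "on-arm")
  expect_true(all(
    info$length[!info$is_border] >= cfg@scaffold_length_range[1L] &
      info$length[!info$is_border] <= cfg@scaffold_length_range[2L]))
  expect_identical(unname(scaffoldLengths(model)),
                   unname(Biostrings::width(scaffoldSeqs(model))))
})

test_that("repeat units are present verbatim in multiple scaffolds", {
  cfg <- smallSimConfig(seed = 13, repeat_copy_number = 20L,
                        repeat_unit_length = 200L)
  model <- buildGenome(cfg)
  rep_gr <- repeatRegions(model)
  found <- FALSE
  for (fam in unique(rep_gr$family)) {
    g <- rep_gr[rep_gr$family == fam]
    if (length(unique(as.character(GenomicRanges::seqnames(g)))) < 2L) next
    units <- vapply(seq_along(g), function(j) {
      sc <- as.character(GenomicRanges::seqnames(g))[j]
      as.character(Biostrings::subseq(scaffoldSeqs(model)[[sc]],
                                      GenomicRanges::start(g)[j],
                                      GenomicRanges::end(g)[j]))
    }, character(1L))
    # a 200-mer duplicated verbatim across >= 2 scaffolds
    dup <- units[duplicated(units) | duplicated(units, fromLast = TRUE)]
    sc_of_dup <- as.character(GenomicRanges::seqnames(g))[units %in% dup]
    if (length(unique(sc_of_dup)) >= 2L) found <- TRUE
  }
  expect_true(found)
})

test_that("hybrid scaffolds concatenate labelled segments around a recorded breakpoint", {
  cfg <- simConfig(seed = 14, n_scaffolds = 8L,
                   scaffold_length_range = c(120000L, 200000L),
                   n_reads = 1000L, n_hybrid_scaffolds = 2L,
                   hybrid_segment_min = 100000L,
                   boundary_taper_width = 200000L)
  model <- buildGenome(cfg)
  info <- scaffoldInfo(model)
  expect_equal(sum(info$label == "hybrid"), 2L)
  hyb <- hybridTruth(model)
  for (sc in unique(as.character(GenomicRanges::seqnames(hyb)))) {
    segs <- hyb[as.character(GenomicRanges::seqnames(hyb)) == sc]
    expect_equal(length(segs), 2L)
    expect_setequal(segs$segment, c("on-arm", "off-arm"))
    L <- info$length[info$scaffold == sc]
    expect_true(all(GenomicRanges::width(segs) >= cfg@hybrid_segment_min))
    expect_equal(sum(GenomicRanges::width(segs)), L)
    bp <- unique(segs$breakpoint)
    expect_length(bp, 1L)
    expect_gt(bp, 0L)
    expect_lt(bp, L)
  }
})

test_that("configs whose hybrid segments cannot fit are rejected", {
  expect_error(simConfig(n_hybrid_scaffolds = 1L,
                         hybrid_segment_min = 400000L),
               "cannot fit")
  expect_error(simConfig(n_hybrid_scaffolds = 1L,
                         hybrid_segment_min = 50000L),
               "100000")
})

test_that("read counts, truth records and flags conserve", {
  cfg <- smallSimConfig(seed = 15)
  sim <- simulateReads(buildGenome(cfg))
  expect_equal(length(readSet(sim)), cfg@n_reads)
  expect_equal(nrow(truthTable(sim)), cfg@n_reads)
  expect_true(all(Biostrings::width(readSet(sim)) == cfg@read_length))

  sim0 <- simulateReads(buildGenome(smallSimConfig(seed = 15,
                                                   contamination_rate = 0)))
  expect_false(any(truthTable(sim0)$is_contaminant))
})

test_that("contamination fraction is binomial around its rate", {
  cfg <- smallSimConfig(seed = 7, n_reads = 10000L,
                        contamination_rate = 0.05)
  sim <- simulateReads(buildGenome(cfg))
  frac <- mean(truthTable(sim)$is_contaminant)
  sd3 <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(frac - 0.05), sd3)
})

test_that("every chimeric read carries a primer k-mer at full chimera rate", {
  cfg <- smallSimConfig(seed = 16, n_reads = 500L,
                        primer_chimera_rate = 1.0, error_rate = 0)
  sim <- simulateReads(buildGenome(cfg))
  expect_true(all(truthTable(sim)$is_chimera))
  scr <- screenPrimers(readSet(sim), min_match_len = 11L)
  expect_true(all(scr$positive))
})

test_that("truth-based density oracle does plain arithmetic", {
  cfg <- smallSimConfig(seed = 17)
  model <- buildGenome(cfg)
  info <- scaffoldInfo(model)
  # fabricated truth: 1000 reads on one scaffold, none elsewhere
  truth <- S4Vectors::DataFrame(scaffold = rep(info$scaffold[1L], 1000L))
  d <- truthExpectedDensity(model, truth)
  expect_equal(d$expected_hits[1L], 1000L)
  expect_equal(d$hits_per_kb[1L], 1000 / (info$length[1L] / 1000))
  expect_true(all(d$hits_per_kb[-1L] == 0))
})

test_that("arm enrichment in truth matches the contamination odds", {
  run <- sharedDefaultRun()
  truth <- truthTable(run$sim)
  info <- scaffoldInfo(run$model)
  on_len <- sum(info$length[info$label == "on-arm"])
  off_len <- sum(info$length[info$label == "off-arm"])
  d_on <- sum(!truth$is_contaminant) / (on_len / 1000)
  d_off <- sum(truth$is_contaminant) / (off_len / 1000)
  cc <- run$config@contamination_rate
  expected_ratio <- (1 - cc) / cc * (off_len / on_len)
  expect_lt(abs(d_on / d_off - expected_ratio) / expected_ratio, 0.20)
  # and enrichment holds per-scaffold on average
  dens <- truthExpectedDensity(run$model, truth)
  expect_gt(mean(dens$hits_per_kb[info$label == "on-arm"]),
            mean(dens$hits_per_kb[info$label == "off-arm"]))
})

test_that("read density declines monotonically into the laser-cut taper", {
  run <- sharedDefaultRun()
  truth <- truthTable(run$sim)
  info <- scaffoldInfo(run$model)
  border <- borderScaffold(run$model)
  L <- info$length[info$scaffold == border]
  w <- run$config@boundary_taper_width
  pos <- truth$pos0[truth$scaffold == border]
  bin_w <- w / 10
  # distance of each read start from the boundary at the scaffold end
  dist <- pmin(L - pos, L - 1L)
  bins <- floor(dist / bin_w)
  counts <- as.integer(table(factor(bins, levels = sort(unique(bins)))))
  dist_rank <- sort(unique(bins))
  ct <- suppressWarnings(
    stats::cor.test(dist_rank, counts, method = "kendall",
                    alternative = "greater"))
  expect_lt(ct$p.value, 0.01)
})
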