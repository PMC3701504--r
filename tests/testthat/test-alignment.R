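test_that("brute-force enumeration finds constructed alignments", {
  genome <- toyGenome(21)
  g1 <- as.character(genome[[1L]])

  # a unique 20-mer of the first scaffold, exact matching only
  read <- substr(g1, 101, 120)
  hits <- enumerateAlignments(read, genome, v = 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$scaffold, "toy_1")
  expect_equal(hits$pos0, 100L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)

  # a unit present at three sites is found at (at least) all three
  unit <- substr(g1, 501, 580)
  seqs <- as.character(genome)
  substr(seqs[2L], 1001, 1080) <- unit
  substr(seqs[3L], 2001, 2080) <- unit
  genome3 <- Biostrings::DNAStringSet(seqs)
  hits3 <- enumerateAlignments(unit, genome3, v = 2L)
  expect_gte(nrow(hits3), 3L)

  # exactly three substitutions is outside the v = 2 budget
  read80 <- withr::with_seed(22, mutateRead(substr(g1, 301, 380), 3L))
  expect_equal(nrow(enumerateAlignments(read80, genome, v = 2L)), 0L)
  # ... but inside a v = 3 budget
  expect_gte(nrow(enumerateAlignments(read80, genome, v = 3L)), 1L)

  expect_error(enumerateAlignments("ACGTX", genome), "characters")
})

test_that("uniqueness filtering is decided by multiplicity, not best hit", {
  one <- S4Vectors::DataFrame(scaffold = "s", pos0 = 0L, strand = "+",
                              mismatches = 2L)
  expect_equal(nrow(uniqueFilter(one)), 1L)      # a 2-mismatch hit is kept
  two <- S4Vectors::DataFrame(scaffold = c("s", "t"), pos0 = c(0L, 5L),
                              strand = c("+", "+"), mismatches = c(0L, 2L))
  expect_equal(nrow(uniqueFilter(two)), 0L)      # perfect hit dies with the read
  expect_equal(nrow(uniqueFilter(two, m = 2L)), 2L)
  expect_equal(nrow(uniqueFilter(two[0L, ])), 0L)
})

test_that("mapper agrees with the brute-force oracle read by read", {
  genome <- toyGenome(23, n_scaffolds = 2L, len = 10000L)
  g1 <- as.character(genome[[1L]])
  reads <- withr::with_seed(24, {
    starts <- sample.int(10000L - 80L, 150L)
    from_genome <- substring(as.character(genome)[sample(1:2, 150L, TRUE)],
                             starts, starts + 79L)
    mutated <- vapply(from_genome[1:60],
                      function(r) mutateRead(r, sample(1:4, 1L)),
                      character(1L), USE.NAMES = FALSE)
    unname(c(from_genome[61:150], mutated, randomReads(30L, 80L)))
  })
  ht <- mapReads(reads, genome, v = 2L)
  st <- readStatus(ht)
  hits <- hitRecords(ht)
  for (i in seq_along(reads)) {
    oracle <- uniqueFilter(enumerateAlignments(reads[i], genome, v = 2L))
    status <- as.character(st$status[i])
    if (nrow(oracle) == 1L) {
      expect_equal(status, "unique", label = paste("read", i))
      h <- hits[hits$read_id == st$read_id[i], ]
      expect_equal(unname(c(h$scaffold, h$strand)),
                   unname(c(oracle$scaffold, oracle$strand)))
      expect_equal(c(h$pos0, h$mismatches), c(oracle$pos0, oracle$mismatches))
    } else {
      raw <- enumerateAlignments(reads[i], genome, v = 2L)
      expect_equal(status, if (nrow(raw) == 0L) "unmapped" else "multi",
                   label = paste("read", i))
    }
  }
})

test_that("mapper counters conserve and respect the identity bound", {
  run <- sharedDefaultRun()
  cnt <- hitCounters(run$ht)
  expect_equal(cnt[["mapped_unique"]] + cnt[["suppressed_multi"]],
               cnt[["mapped_any"]])
  expect_equal(cnt[["mapped_any"]] + cnt[["unmapped"]],
               cnt[["total_reads"]])
  expect_equal(cnt[["total_reads"]], run$config@n_reads)
  mm <- hitRecords(run$ht)$mismatches
  expect_true(all(mm <= 2L))
  identity <- (run$config@read_length - mm) / run$config@read_length
  expect_true(all(identity >= 0.975))  # 2/80 mismatches = 97.5% identity
})

test_that("unique-hit counts are invariant under reverse-complementing everything", {
  genome <- toyGenome(25, n_scaffolds = 2L, len = 6000L)
  reads <- withr::with_seed(26, {
    starts <- sample.int(6000L - 80L, 300L)
    unname(substring(as.character(genome)[sample(1:2, 300L, TRUE)],
                     starts, starts + 79L))
  })
  ht_fwd <- mapReads(reads, genome, v = 2L)
  genome_rc <- Biostrings::reverseComplement(genome)
  reads_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  ht_rc <- mapReads(reads_rc, genome_rc, v = 2L)
  expect_equal(hitCounters(ht_fwd)[["mapped_unique"]],
               hitCounters(ht_rc)[["mapped_unique"]])
  expect_equal(hitCounters(ht_fwd)[["suppressed_multi"]],
               hitCounters(ht_rc)[["suppressed_multi"]])
})

test_that("raising the mismatch budget never loses alignable reads", {
  genome <- toyGenome(27, n_scaffolds = 2L, len = 6000L)
  reads <- withr::with_seed(28, {
    starts <- sample.int(6000L - 80L, 200L)
    raw <- substring(as.character(genome)[sample(1:2, 200L, TRUE)],
                     starts, starts + 79L)
    vapply(raw, function(r) mutateRead(r, sample(0:3, 1L)), character(1L),
           USE.NAMES = FALSE)
  })
  prev <- -1L
  for (v in 0:3) {
    cnt <- hitCounters(mapReads(reads, genome, v = v))
    expect_gte(cnt[["mapped_any"]], prev)
    prev <- cnt[["mapped_any"]]
  }
})

test_that("against a repeat-free genome every mapped read is unique at v = 0", {
  genome <- toyGenome(29, n_scaffolds = 1L, len = 8000L)
  reads <- withr::with_seed(30, {
    starts <- sample.int(8000L - 80L, 200L)
    substring(as.character(genome[[1L]]), starts, starts + 79L)
  })
  cnt <- hitCounters(mapReads(reads, genome, v = 0L))
  expect_equal(cnt[["mapped_unique"]], cnt[["mapped_any"]])
})

test_that("N bases count as mismatches everywhere", {
  genome <- toyGenome(31, n_scaffolds = 1L, len = 4000L)
  clean <- substr(as.character(genome[[1L]]), 201, 280)
  with1N <- clean; substr(with1N, 10, 10) <- "N"
  with3N <- clean
  for (q in c(5, 40, 70)) substr(with3N, q, q) <- "N"
  ht <- mapReads(c(clean, with1N, with3N), genome, v = 2L)
  st <- as.character(readStatus(ht)$status)
  expect_equal(st, c("unique", "unique", "unmapped"))
  hits <- hitRecords(ht)
  expect_equal(hits$mismatches, c(0L, 1L))
})

test_that("reads longer than every scaffold are rejected", {
  genome <- Biostrings::DNAStringSet(c(s = "ACGTACGTAC"))
  expect_error(mapReads(paste(rep("ACGT", 10), collapse = ""), genome),
               "longer than every scaffold")
})

test_that("primer screen requires a workable k-mer length and primers", {
  expect_error(screenPrimers("ACGT", min_match_len = 7L), ">= 8")
  expect_error(screenPrimers("ACGT", Biostrings::DNAStringSet()), "empty")
})

test_that("primer screen hits exact inserts at the match-length boundary", {
  primers <- defaultPrimers()
  p1 <- as.character(primers[[1L]])
  backbone <- withr::with_seed(32, randomReads(1L, 80L))
  pos11 <- backbone
  substr(pos11, 1, 11) <- substr(p1, 5, 15)     # 11 nt insert: positive
  pos10 <- backbone
  substr(pos10, 1, 10) <- substr(p1, 5, 14)     # 10 nt insert: negative
  rc11 <- backbone                               # reverse-complement insert
  substr(rc11, 70, 80) <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(substr(p1, 5, 15))))
  scr <- screenPrimers(c(pos11, pos10, rc11), primers, min_match_len = 11L)
  expect_equal(scr$positive, c(TRUE, FALSE, TRUE))
  expect_equal(scr$n_primer_positive, 2L)
  expect_lte(scr$n_primer_positive, scr$n_unmapped)
})

test_that("primer-positive fraction tracks the chimera rate on unmappable reads", {
  n <- 2000L
  reads <- withr::with_seed(33, {
    r <- randomReads(n, 80L)  # random reads: unmappable, primer-free
    is_chim <- seq_len(n) <= 0.30 * n
    p <- as.character(defaultPrimers()[[1L]])
    for (i in which(is_chim)) {
      ins <- sample(11:30, 1L)
      substr(r[i], 1, ins) <- substr(p, 1, ins)
    }
    r
  })
  scr <- screenPrimers(reads, min_match_len = 11L)
  frac <- scr$n_primer_positive / n
  expect_lt(abs(frac - 0.30), 3 * sqrt(0.3 * 0.7 / n))
})
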