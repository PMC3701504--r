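# Shared fixtures, built once per test run.

.shared <- new.env(parent = emptyenv())

# One full-scale run under the default study conditions (seed 1); several
# files check different aspects of the same run, so it is cached.
sharedDefaultRun <- function() {
  if (is.null(.shared$default_run)) {
    cfg <- simConfig(seed = 1L)
    model <- buildGenome(cfg)
    sim <- simulateReads(model)
    ht <- mapReads(sim, model)
    .shared$default_run <- list(config = cfg, model = model, sim = sim,
                                ht = ht, dens = scaffoldDensity(ht))
  }
  .shared$default_run
}

# A small named random genome for alignment unit tests.
toyGenome <- function(seed, n_scaffolds = 3L, len = 4000L) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_scaffolds), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1L))
    Biostrings::DNAStringSet(setNames(seqs, sprintf("toy_%d", seq_len(n_scaffolds))))
  })
}

# Substitute k random positions of a read with a different base.
mutateRead <- function(read, k) {
  pos <- sample.int(nchar(read), k)
  for (q in pos) {
    old <- substr(read, q, q)
    substr(read, q, q) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  read
}

randomReads <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

# Coverage profile built directly from window counts (window_bp wide,
# last window full-width).
profileFromCounts <- function(counts, window_bp = 10000L,
                              scaffold = "synth") {
  new("CoverageProfile", scaffold = scaffold,
      length_bp = as.integer(length(counts) * window_bp),
      window_bp = as.integer(window_bp),
      counts = as.integer(counts),
      densities = counts / (window_bp / 1000))
}

smallSimConfig <- function(seed, ...) {
  args <- list(seed = seed, n_scaffolds = 10L,
               scaffold_length_range = c(20000L, 40000L),
               n_reads = 8000L, boundary_taper_width = 50000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}
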