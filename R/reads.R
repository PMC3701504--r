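#' @importFrom Biostrings reverseComplement readDNAStringSet width
NULL

# offset added to the user seed so the read simulator and the genome
# builder consume distinct, reproducible streams
.READ_SEED_OFFSET <- 1000003L

#' Built-in amplification/adapter primer sequences (synthetic)
#'
#' Two fixed 48 nt sequences standing in for the amplification-primer and
#' sequencing-adapter contaminants that end up on the ends of
#' whole-genome-amplified fragments. They are synthetic stand-ins, not
#' vendor sequences; any primer set can be supplied instead wherever
#' these are used. Also shipped as
#' `system.file("extdata", "primers_synthetic.fasta", package = "armAnchor")`.
#'
#' @return a named `DNAStringSet` of length 2.
#' @examples
#' defaultPrimers()
#' @export
defaultPrimers <- function() {
  DNAStringSet(c(
    wga_primer_synthetic =
      "GTCAGTACGGCTTAAGCCTGAGTCCAGTTCAGGACCTAGGATACGCGT",
    seq_adapter_synthetic =
      "CTAGGTTGACCAGCTAAGGTCGATCCTGAACGTTAGCAGTCCATGCAA"))
}

# sample fragment-start positions (0-based) on the border scaffold under
# the linear taper: weight(d) = min(d/w, 1) where d is the distance from
# the fragment start to the boundary at the scaffold end
.sampleTaperStarts <- function(k, L, rl, w) {
  if (w <= 0L) return(as.integer(floor(runif(k, 0, L - rl + 1))))
  lo <- rl
  if (w >= L) {
    d <- sqrt(lo^2 + runif(k) * (L^2 - lo^2))
  } else {
    ramp_mass <- (w^2 - lo^2) / (2 * w)
    flat_mass <- L - w
    in_ramp <- runif(k) < ramp_mass / (ramp_mass + flat_mass)
    d <- numeric(k)
    nr <- sum(in_ramp)
    d[in_ramp] <- sqrt(lo^2 + runif(nr) * (w^2 - lo^2))
    d[!in_ramp] <- runif(k - nr, w, L)
  }
  pmin(pmax(as.integer(floor(L - d)), 0L), L - rl)
}

# effective sampling mass of the border scaffold (continuous approximation
# of the summed taper weights over eligible fragment starts)
.taperMass <- function(L, rl, w) {
  if (w <= 0L) return(L - rl + 1)
  if (w >= L) return((L^2 - rl^2) / (2 * w))
  (L - w) + (w^2 - rl^2) / (2 * w)
}

#' Simulate a microdissected-arm read set with per-read truth
#'
#' Emulates the sequencing experiment downstream of laser microdissection
#' and whole-genome amplification. Reads are drawn from on-arm scaffolds
#' with probability `1 - contamination_rate` and from off-arm scaffolds
#' otherwise (for hybrid scaffolds only the on-arm segment is an eligible
#' on-arm source; off-arm segments of hybrids receive no reads, standing
#' for sequence whose true home is elsewhere in the genome). Amplification
#' duplication bias is modelled as a pool of `n_reads / 2` fragments per
#' class, each carrying a lognormal(0, `wga_lognormal_sigma`) weight;
#' reads resample fragments proportionally to weight, so duplicated reads
#' share their start position. Within `boundary_taper_width` of the
#' laser-cut boundary (the far end of the designated border scaffold),
#' sampling probability declines linearly to zero. Substitution errors
#' are applied at `error_rate` per base; a `primer_chimera_rate` fraction
#' of reads then has a prefix or suffix (random choice) overwritten by at
#' least `min_primer_insert` nt of a primer sequence (primer bases are
#' inserted verbatim: they are clonal amplification product, not
#' template). Every read gets exactly one truth record; truth positions
#' are 0-based forward-strand starts.
#'
#' @param model a [GenomeModel] from [buildGenome()].
#' @param config a [SimConfig]; defaults to the one stored in `model`.
#' @param primers `DNAStringSet` of primer sequences used for chimeric
#'   read ends; defaults to [defaultPrimers()].
#' @return a [SimulatedReads] object.
#' @examples
#' cfg <- simConfig(seed = 2, n_scaffolds = 6,
#'                  scaffold_length_range = c(5000L, 8000L),
#'                  n_reads = 500, boundary_taper_width = 2000L,
#'                  repeat_family_count = 0L)
#' sim <- simulateReads(buildGenome(cfg))
#' sim
#' head(truthTable(sim))
#' @export
simulateReads <- function(model, config = model@config,
                          primers = defaultPrimers()) {
  stopifnot(is(model, "GenomeModel"), is(config, "SimConfig"))
  validObject(config)
  withr::with_seed(config@seed + .READ_SEED_OFFSET,
                   .simulateReadsImpl(model, config, primers))
}

.simulateReadsImpl <- function(model, config, primers) {
  info <- scaffoldInfo(model)
  rl <- config@read_length
  n <- config@n_reads
  c_rate <- config@contamination_rate
  seqs_chr <- as.character(scaffoldSeqs(model))
  border <- borderScaffold(model)

  # eligible source intervals: scaffold, lo/hi (0-based start bounds),
  # sampling mass, and whether the border taper applies
  src <- list()
  addSrc <- function(scaffold, lo, hi, class, taper = FALSE, mass = NULL) {
    if (hi < lo) return()
    if (is.null(mass)) mass <- hi - lo + 1
    src[[length(src) + 1L]] <<- list(scaffold = scaffold, lo = lo, hi = hi,
                                     class = class, taper = taper,
                                     mass = mass)
  }
  for (i in seq_len(nrow(info))) {
    sc <- info$scaffold[i]; L <- info$length[i]
    if (info$label[i] == "on-arm") {
      if (!is.na(border) && sc == border) {
        addSrc(sc, 0L, L - rl, "on", taper = TRUE,
               mass = .taperMass(L, rl, config@boundary_taper_width))
      } else {
        addSrc(sc, 0L, L - rl, "on")
      }
    } else if (info$label[i] == "off-arm") {
      addSrc(sc, 0L, L - rl, "off")
    } else {  # hybrid: only the on-arm segment feeds the on-arm pool
      seg <- hybridTruth(model)
      seg <- seg[as.character(seqnames(seg)) == sc & seg$segment == "on-arm"]
      for (j in seq_along(seg))
        addSrc(sc, start(seg)[j] - 1L, end(seg)[j] - rl, "on")
    }
  }
  cls <- vapply(src, `[[`, character(1L), "class")
  if (!any(cls == "on"))
    stop("no on-arm scaffold (or hybrid on-arm segment) to sample reads from")
  if (c_rate > 0 && !any(cls == "off"))
    stop("contamination requested but no off-arm scaffold exists")

  sampleFragments <- function(k, class) {
    pool <- src[cls == class]
    mass <- vapply(pool, `[[`, numeric(1L), "mass")
    pick <- sample.int(length(pool), k, replace = TRUE, prob = mass)
    pos <- integer(k)
    for (j in unique(pick)) {
      sel <- pick == j
      iv <- pool[[j]]
      if (iv$taper) {
        L <- iv$hi + rl  # border scaffold length
        pos[sel] <- .sampleTaperStarts(sum(sel), L, rl,
                                       config@boundary_taper_width)
      } else {
        pos[sel] <- as.integer(floor(runif(sum(sel), iv$lo, iv$hi + 1)))
      }
    }
    list(scaffold = vapply(pool, `[[`, character(1L), "scaffold")[pick],
         pos = pos,
         strand = sample(c("+", "-"), k, replace = TRUE),
         weight = if (config@wga_lognormal_sigma > 0)
           rlnorm(k, 0, config@wga_lognormal_sigma) else rep(1, k))
  }

  f_on <- max(1L, as.integer(round(n * (1 - c_rate) / 2)))
  frag_on <- sampleFragments(f_on, "on")
  frag_off <- NULL
  if (c_rate > 0) {
    f_off <- max(1L, as.integer(round(n * c_rate / 2)))
    frag_off <- sampleFragments(f_off, "off")
  }

  contaminant <- as.logical(rbinom(n, 1L, c_rate))
  n_off <- sum(contaminant)
  idx_on <- sample.int(f_on, n - n_off, replace = TRUE, prob = frag_on$weight)
  scaffold <- character(n); pos <- integer(n); str <- character(n)
  scaffold[!contaminant] <- frag_on$scaffold[idx_on]
  pos[!contaminant] <- frag_on$pos[idx_on]
  str[!contaminant] <- frag_on$strand[idx_on]
  if (n_off > 0L) {
    idx_off <- sample.int(length(frag_off$pos), n_off, replace = TRUE,
                          prob = frag_off$weight)
    scaffold[contaminant] <- frag_off$scaffold[idx_off]
    pos[contaminant] <- frag_off$pos[idx_off]
    str[contaminant] <- frag_off$strand[idx_off]
  }

  # template extraction (forward window), then reverse-complement minus reads
  reads <- character(n)
  for (sc in unique(scaffold)) {
    sel <- scaffold == sc
    reads[sel] <- substring(seqs_chr[sc], pos[sel] + 1L, pos[sel] + rl)
  }
  minus <- str == "-"
  if (any(minus))
    reads[minus] <- as.character(reverseComplement(DNAStringSet(reads[minus])))

  # per-base substitution errors on the sequenced read, vectorised by
  # read position (each erroneous base becomes one of the other three)
  if (config@error_rate > 0) {
    n_err_total <- rbinom(1L, n * rl, config@error_rate)
    mask <- sort(sample.int(n * rl, n_err_total))
    if (length(mask)) {
      er <- (mask - 1L) %/% rl + 1L
      eq <- (mask - 1L) %% rl + 1L
      for (q in unique(eq)) {
        rows <- er[eq == q]
        old <- substr(reads[rows], q, q)
        shift <- sample.int(3L, length(rows), replace = TRUE)
        substr(reads[rows], q, q) <- .DNA[(match(old, .DNA) - 1L + shift) %% 4L + 1L]
      }
    }
  }

  # primer chimeras: overwrite a read end with verbatim primer sequence
  chimera <- if (config@primer_chimera_rate >= 1) rep(TRUE, n) else
    runif(n) < config@primer_chimera_rate
  if (any(chimera)) {
    if (length(primers) == 0L) stop("primer set is empty")
    prim_chr <- as.character(primers)
    max_ins <- min(rl %/% 2L, min(nchar(prim_chr)))
    if (max_ins < config@min_primer_insert)
      stop("primers shorter than min_primer_insert")
    for (i in which(chimera)) {
      ins <- .sampleVec(config@min_primer_insert:max_ins, 1L)
      pr <- prim_chr[[sample.int(length(prim_chr), 1L)]]
      ps <- sample.int(nchar(pr) - ins + 1L, 1L)
      piece <- substr(pr, ps, ps + ins - 1L)
      if (sample(c(TRUE, FALSE), 1L)) {
        substr(reads[i], 1L, ins) <- piece
      } else {
        substr(reads[i], rl - ins + 1L, rl) <- piece
      }
    }
  }

  ids <- sprintf("r%07d", seq_len(n))
  lab <- ifelse(contaminant, "off-arm", "on-arm")
  truth <- DataFrame(read_id = ids, scaffold = scaffold, pos0 = pos,
                     strand = str, label = lab,
                     is_chimera = chimera, is_contaminant = contaminant)
  new("SimulatedReads",
      reads = DNAStringSet(setNames(reads, ids)),
      truth = truth, config = config)
}

#' Expected per-scaffold hit density from the simulation truth
#'
#' Oracle statistic for parameter-recovery tests: counts truth origins
#' per scaffold (contaminant and chimeric reads are counted at their true
#' origins) and divides by scaffold length in kb. This is what the mapped
#' density would be with a perfect, lossless mapper.
#'
#' @param model a [GenomeModel].
#' @param truth a truth `DataFrame` (from [truthTable()]) or a
#'   [SimulatedReads] object.
#' @return a `DataFrame` with columns `scaffold`, `length`,
#'   `expected_hits`, `hits_per_kb`, one row per scaffold (zero-read
#'   scaffolds included).
#' @export
truthExpectedDensity <- function(model, truth) {
  stopifnot(is(model, "GenomeModel"))
  if (is(truth, "SimulatedReads")) truth <- truthTable(truth)
  info <- scaffoldInfo(model)
  cnt <- table(factor(truth$scaffold, levels = info$scaffold))
  DataFrame(scaffold = info$scaffold,
            length = info$length,
            expected_hits = as.integer(cnt),
            hits_per_kb = as.numeric(cnt) / (info$length / 1000))
}

#' Emulated prior scaffold placements (meiotic/physical map)
#'
#' Generates the prior-placement table a real analysis would take from a
#' meiotic linkage map plus physical (in situ hybridisation) anchors: the
#' border scaffold is physically anchored to the target arm; a fraction
#' of the remaining on-arm scaffolds carry (correct) meiotic placements,
#' and `n_misplaced` of those are deliberately assigned to a wrong arm to
#' emulate map errors that the density analysis should flag for
#' reassignment; hybrid scaffolds carry target-arm markers; off-arm
#' scaffolds are split between other-arm placements and `"unmapped"`.
#'
#' @param model a [GenomeModel].
#' @param target_arm arm label used for the dissected arm (default
#'   `"7p"`).
#' @param mapped_fraction fraction of non-border on-arm scaffolds with a
#'   meiotic placement.
#' @param n_misplaced number of truly on-arm scaffolds given a wrong
#'   prior arm.
#' @param other_arms pool of wrong-arm labels.
#' @return a `DataFrame` with columns `scaffold`, `assigned_location`,
#'   `source`.
#' @export
priorPlacements <- function(model, target_arm = "7p",
                            mapped_fraction = 0.6, n_misplaced = 2L,
                            other_arms = c("7q", "8q", "3p")) {
  stopifnot(is(model, "GenomeModel"))
  withr::with_seed(model@config@seed + 7L, {
    info <- scaffoldInfo(model)
    loc <- rep("unmapped", nrow(info))
    srcv <- rep("meiotic", nrow(info))
    border <- which(info$is_border)
    on_idx <- setdiff(which(info$label == "on-arm"), border)
    hyb_idx <- which(info$label == "hybrid")
    off_idx <- which(info$label == "off-arm")

    loc[border] <- target_arm
    srcv[border] <- "physical"
    n_map <- round(mapped_fraction * length(on_idx))
    mapped <- sort(.sampleVec(on_idx, n_map))
    loc[mapped] <- target_arm
    n_mis <- min(as.integer(n_misplaced), length(mapped))
    if (n_mis > 0L) {
      mis <- sort(.sampleVec(mapped, n_mis))
      loc[mis] <- .sampleVec(other_arms, n_mis, replace = TRUE)
    }
    loc[hyb_idx] <- target_arm
    if (length(off_idx)) {
      n_off_map <- round(mapped_fraction * length(off_idx))
      off_mapped <- sort(.sampleVec(off_idx, n_off_map))
      loc[off_mapped] <- .sampleVec(other_arms, n_off_map, replace = TRUE)
    }
    DataFrame(scaffold = info$scaffold, assigned_location = loc,
              source = srcv)
  })
}
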