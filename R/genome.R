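#' @importFrom withr with_seed
#' @importFrom stats runif rbinom rlnorm setNames median
#' @importFrom IRanges IRanges
NULL

.DNA <- c("A", "C", "G", "T")

.randomDna <- function(n) {
  paste(sample(.DNA, n, replace = TRUE), collapse = "")
}

# sample() safe against the length-1 "sample from 1:x" surprise
.sampleVec <- function(x, k, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), k, replace = replace, prob = prob)]
}

#' Generate a synthetic multi-scaffold genome with known truth
#'
#' Builds the scaffold universe the microdissection analysis runs
#' against: `n_scaffolds` scaffolds of i.i.d. uniform base composition,
#' a fraction of which carry the true label `"on-arm"` (the dissected
#' arm), plus three structured features. Repeat families are identical
#' units copied verbatim into multiple scaffolds of both labels, so reads
#' from their interiors map to several locations and are suppressed by
#' the uniqueness filter. Hybrid scaffolds are concatenations of one
#' on-arm and one off-arm segment (each at least
#' `hybrid_segment_min` bp, in random order) with the join coordinate
#' recorded as truth -- the misassembly signature the gap detector is
#' meant to recover. One on-arm scaffold is designated the laser-boundary
#' (border) scaffold: read sampling tapers off toward its far end, and it
#' serves as the calibration anchor downstream. Its length is fixed at
#' the midpoint of `scaffold_length_range` so the taper geometry is
#' reproducible across configurations.
#'
#' The generator is fully driven by `config@seed`: identical
#' configurations give byte-identical genomes.
#'
#' @param config a [SimConfig].
#' @return a [GenomeModel].
#' @examples
#' model <- buildGenome(simConfig(seed = 1, n_scaffolds = 8,
#'                                scaffold_length_range = c(5000L, 10000L),
#'                                n_reads = 100, boundary_taper_width = 2000L,
#'                                repeat_family_count = 1L,
#'                                repeat_copy_number = 4L))
#' model
#' scaffoldInfo(model)
#' @export
buildGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withr::with_seed(config@seed, .buildGenomeImpl(config))
}

.buildGenomeImpl <- function(config) {
  n <- config@n_scaffolds
  rng <- config@scaffold_length_range
  ids <- sprintf("scaffold_%03d", seq_len(n))

  n_hyb <- config@n_hybrid_scaffolds
  n_on <- min(n - n_hyb, max(0L, as.integer(round(config@arm_fraction * n))))

  label <- rep("off-arm", n)
  hyb_idx <- if (n_hyb > 0L) sort(sample.int(n, n_hyb)) else integer()
  label[hyb_idx] <- "hybrid"
  rest <- setdiff(seq_len(n), hyb_idx)
  on_idx <- sort(.sampleVec(rest, n_on))
  label[on_idx] <- "on-arm"

  len <- as.integer(floor(runif(n, rng[1L], rng[2L] + 1)))
  # deterministic border geometry: the anchor scaffold gets the midpoint length
  border_idx <- if (n_on > 0L) on_idx[1L] else NA_integer_
  if (!is.na(border_idx)) len[border_idx] <- as.integer(round(mean(rng)))

  # hybrid segment geometry: one on-arm segment + one off-arm segment,
  # lengths uniform in [hybrid_segment_min, max(range)], order random
  hyb_segs <- vector("list", length(hyb_idx))
  if (n_hyb > 0L) {
    seg_len <- function()
      as.integer(floor(runif(1L, config@hybrid_segment_min, rng[2L] + 1)))
    for (k in seq_along(hyb_idx)) {
      i <- hyb_idx[k]
      l_on <- seg_len()
      l_off <- seg_len()
      on_first <- sample(c(TRUE, FALSE), 1L)
      len[i] <- l_on + l_off
      bp0 <- if (on_first) l_on else l_off          # 0-based join coordinate
      hyb_segs[[k]] <- list(
        scaffold = ids[i], breakpoint = bp0,
        seg_start = c(1L, bp0 + 1L),
        seg_end = c(bp0, len[i]),
        seg_label = if (on_first) c("on-arm", "off-arm")
                    else c("off-arm", "on-arm"))
    }
  }

  seqs <- vapply(len, .randomDna, character(1L))

  # repeat families: identical units overwritten into random scaffolds;
  # for hybrid scaffolds a copy stays inside a single segment
  rep_scaf <- character()
  rep_start <- integer()
  rep_family <- character()
  if (config@repeat_family_count > 0L && config@repeat_copy_number > 0L) {
    for (f in seq_len(config@repeat_family_count)) {
      unit <- .randomDna(config@repeat_unit_length)
      ul <- config@repeat_unit_length
      for (cp in seq_len(config@repeat_copy_number)) {
        i <- sample.int(n, 1L, prob = len)
        if (label[i] == "hybrid") {
          hs <- hyb_segs[[match(i, hyb_idx)]]
          s <- sample(1:2, 1L)
          lo <- hs$seg_start[s]
          hi <- hs$seg_end[s] - ul + 1L
        } else {
          lo <- 1L
          hi <- len[i] - ul + 1L
        }
        if (hi < lo) next
        p <- as.integer(floor(runif(1L, lo, hi + 1)))
        substr(seqs[i], p, p + ul - 1L) <- unit
        rep_scaf <- c(rep_scaf, ids[i])
        rep_start <- c(rep_start, p)
        rep_family <- c(rep_family, sprintf("repfam_%02d", f))
      }
    }
  }

  info <- DataFrame(scaffold = ids, length = len, label = label,
                    is_border = seq_len(n) == border_idx &
                      !is.na(border_idx))
  repeats <- GRanges(rep_scaf,
                     IRanges(rep_start,
                             width = rep(config@repeat_unit_length,
                                         length(rep_start))),
                     family = rep_family)
  if (n_hyb > 0L) {
    hybrids <- GRanges(
      rep(vapply(hyb_segs, `[[`, character(1L), "scaffold"), each = 2L),
      IRanges(unlist(lapply(hyb_segs, `[[`, "seg_start")),
              unlist(lapply(hyb_segs, `[[`, "seg_end"))),
      segment = unlist(lapply(hyb_segs, `[[`, "seg_label")),
      breakpoint = rep(vapply(hyb_segs, `[[`, integer(1L), "breakpoint"),
                       each = 2L))
  } else {
    hybrids <- GRanges()
  }

  new("GenomeModel",
      seqs = DNAStringSet(setNames(seqs, ids)),
      info = info, repeats = repeats, hybrids = hybrids, config = config)
}
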