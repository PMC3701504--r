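#' @import methods
#' @importFrom S4Vectors DataFrame isSingleNumber isSingleString
#' @importFrom Biostrings DNAStringSet
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom BiocGenerics width start end strand
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' Simulation configuration for the microdissection experiment emulator
#'
#' Holds every tunable of the synthetic-data generator: genome geometry
#' (number of scaffolds, length range, fraction of scaffolds on the
#' dissected arm), read production (read length, read count, per-base
#' substitution error rate), the artefacts of whole-genome amplification
#' (lognormal per-fragment amplification dispersion, primer-chimera rate,
#' minimum primer insert length), off-target contamination, repeat
#' structure (family count, copy number, unit length), implanted hybrid
#' scaffolds, and the laser-boundary taper width. Construct with
#' [simConfig()]; the defaults are the desk-scale study conditions used
#' throughout the package.
#'
#' @slot seed integer; drives every random draw of the generator.
#' @slot n_scaffolds integer number of scaffolds (hybrids included).
#' @slot scaffold_length_range integer pair, scaffold lengths in bp.
#' @slot arm_fraction fraction of scaffolds labelled on-arm.
#' @slot read_length read length in bp (default 80).
#' @slot n_reads number of reads to emit.
#' @slot contamination_rate fraction of reads drawn from off-arm scaffolds.
#' @slot error_rate per-base substitution probability.
#' @slot wga_lognormal_sigma sdlog of the per-fragment amplification factor.
#' @slot primer_chimera_rate fraction of reads carrying a primer substring.
#' @slot min_primer_insert minimum primer insert length in nt (default 11).
#' @slot repeat_family_count,repeat_copy_number,repeat_unit_length repeat
#'   structure: number of distinct families, identical copies per family,
#'   and unit length in bp.
#' @slot n_hybrid_scaffolds number of implanted misassembled scaffolds.
#' @slot hybrid_segment_min minimum length in bp of each hybrid segment.
#' @slot boundary_taper_width width in bp of the linear laser-cut taper.
#' @seealso [simConfig()], [buildGenome()], [simulateReads()]
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", slots = c(
  seed = "integer",
  n_scaffolds = "integer",
  scaffold_length_range = "integer",
  arm_fraction = "numeric",
  read_length = "integer",
  n_reads = "integer",
  contamination_rate = "numeric",
  error_rate = "numeric",
  wga_lognormal_sigma = "numeric",
  primer_chimera_rate = "numeric",
  min_primer_insert = "integer",
  repeat_family_count = "integer",
  repeat_copy_number = "integer",
  repeat_unit_length = "integer",
  n_hybrid_scaffolds = "integer",
  hybrid_segment_min = "integer",
  boundary_taper_width = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  frac <- c(arm_fraction = object@arm_fraction,
            contamination_rate = object@contamination_rate,
            error_rate = object@error_rate,
            primer_chimera_rate = object@primer_chimera_rate)
  bad <- frac < 0 | frac > 1
  if (any(bad))
    msg <- c(msg, paste0("fractions must lie in [0,1]: ",
                         paste(names(frac)[bad], collapse = ", ")))
  if (length(object@scaffold_length_range) != 2L ||
      any(object@scaffold_length_range <= 0L) ||
      diff(object@scaffold_length_range) < 0L)
    msg <- c(msg, "scaffold_length_range must be an ascending positive pair")
  if (object@read_length < object@min_primer_insert)
    msg <- c(msg, "read_length must be >= min_primer_insert")
  if (object@read_length > object@scaffold_length_range[1L])
    msg <- c(msg, "read_length exceeds the shortest allowed scaffold")
  if (object@n_scaffolds < 1L || object@n_reads < 1L)
    msg <- c(msg, "n_scaffolds and n_reads must be positive")
  if (object@n_hybrid_scaffolds < 0L ||
      object@n_hybrid_scaffolds >= object@n_scaffolds)
    msg <- c(msg, "n_hybrid_scaffolds must be in [0, n_scaffolds)")
  if (object@n_hybrid_scaffolds > 0L) {
    if (object@hybrid_segment_min < 100000L)
      msg <- c(msg, paste0("hybrid_segment_min must be >= 100000 bp so that ",
                           "implanted joins are detectable as large coverage gaps"))
    if (object@hybrid_segment_min > object@scaffold_length_range[2L])
      msg <- c(msg, "hybrid segments cannot fit scaffold_length_range")
  }
  if (object@wga_lognormal_sigma < 0)
    msg <- c(msg, "wga_lognormal_sigma must be >= 0")
  if (object@boundary_taper_width < 0L)
    msg <- c(msg, "boundary_taper_width must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic genome with arm-label, repeat and misassembly truth
#'
#' A multi-scaffold genome produced by [buildGenome()]. Scaffold sequences
#' live in a [Biostrings::DNAStringSet]; per-scaffold metadata (length,
#' true arm label, border designation) in a [S4Vectors::DataFrame];
#' repeat-unit placements and hybrid-scaffold segment truth in
#' [GenomicRanges::GRanges]. The truth slots exist only because the genome
#' is simulated: they are what downstream classification and gap calls are
#' scored against.
#'
#' @slot seqs `DNAStringSet` of scaffold sequences, named by scaffold id.
#' @slot info `DataFrame` with columns `scaffold`, `length`, `label`
#'   (`"on-arm"`, `"off-arm"` or `"hybrid"`) and `is_border` (the
#'   designated laser-boundary scaffold used as calibration anchor).
#' @slot repeats `GRanges` of implanted repeat-unit copies (mcol `family`).
#' @slot hybrids `GRanges` of hybrid-scaffold segments (mcols `segment`
#'   with value `"on-arm"`/`"off-arm"`, and `breakpoint`, the 0-based join
#'   coordinate), two ranges per hybrid scaffold.
#' @slot config the [SimConfig] the genome was built from.
#' @aliases GenomeModel-class
#' @exportClass GenomeModel
setClass("GenomeModel", slots = c(
  seqs = "DNAStringSet",
  info = "DataFrame",
  repeats = "GRanges",
  hybrids = "GRanges",
  config = "SimConfig"
))

setValidity("GenomeModel", function(object) {
  msg <- character()
  ids <- object@info$scaffold
  if (anyDuplicated(ids))
    msg <- c(msg, "scaffold ids must be unique")
  if (!identical(names(object@seqs), as.character(ids)))
    msg <- c(msg, "sequence names must match info$scaffold")
  if (!all(object@info$label %in% c("on-arm", "off-arm", "hybrid")))
    msg <- c(msg, "labels must be on-arm/off-arm/hybrid")
  len <- setNames(object@info$length, ids)
  for (gr in list(object@repeats, object@hybrids)) {
    if (length(gr) == 0L) next
    s <- as.character(GenomicRanges::seqnames(gr))
    if (!all(s %in% ids)) {
      msg <- c(msg, "interval annotations reference unknown scaffolds")
      next
    }
    if (any(GenomicRanges::start(gr) < 1L) ||
        any(GenomicRanges::end(gr) > len[s]))
      msg <- c(msg, "interval annotations exceed scaffold bounds")
  }
  if (length(object@hybrids)) {
    bp <- object@hybrids$breakpoint
    s <- as.character(GenomicRanges::seqnames(object@hybrids))
    if (any(bp <= 0L) || any(bp >= len[s]))
      msg <- c(msg, "hybrid breakpoints must be strictly inside the scaffold")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated read set with per-read truth
#'
#' Output of [simulateReads()]: the emitted reads plus one truth record
#' per read (origin scaffold, 0-based origin position, source-segment arm
#' label, strand, chimera and contaminant flags). Read ids encode nothing;
#' the truth table is authoritative.
#'
#' @slot reads `DNAStringSet`, one entry per read, named by read id.
#' @slot truth `DataFrame` with columns `read_id`, `scaffold`, `pos0`,
#'   `strand`, `label`, `is_chimera`, `is_contaminant`.
#' @slot config the [SimConfig] used.
#' @aliases SimulatedReads-class
#' @exportClass SimulatedReads
setClass("SimulatedReads", slots = c(
  reads = "DNAStringSet",
  truth = "DataFrame",
  config = "SimConfig"
))

setValidity("SimulatedReads", function(object) {
  msg <- character()
  if (length(object@reads) != nrow(object@truth))
    msg <- c(msg, "each emitted read needs exactly one truth record")
  if (!identical(names(object@reads), as.character(object@truth$read_id)))
    msg <- c(msg, "read names must match truth$read_id in order")
  if (length(msg)) msg else TRUE
})

#' Table of uniquely mapping reads under the multiplicity filter
#'
#' The atom of all downstream statistics: for every input read, its fate
#' under the uniqueness filter (`unique`, `multi`, i.e. suppressed for
#' mapping to more than `m` locations, or `unmapped`), and for uniquely
#' mapped reads the single retained alignment (scaffold, 0-based leftmost
#' position on forward coordinates, strand, mismatch count). Aggregate
#' counters satisfy `mapped_unique + suppressed_multi = mapped_any` and
#' `mapped_any + unmapped = total_reads`.
#'
#' @slot hits `DataFrame` with columns `read_id`, `scaffold`, `pos0`,
#'   `strand`, `mismatches`; one row per uniquely mapped read.
#' @slot status `DataFrame` with columns `read_id` and `status`
#'   (factor `unique`/`multi`/`unmapped`), one row per input read.
#' @slot counters named integer vector: `total_reads`, `mapped_any`,
#'   `mapped_unique`, `suppressed_multi`, `unmapped`.
#' @slot scaffold_lengths named integer vector of reference lengths.
#' @slot read_length integer; NA when read lengths were mixed.
#' @slot params named list echoing the filter settings (`v`, `m`).
#' @seealso [mapReads()], [ingestSam()], [hitRecords()], [hitCounters()]
#' @aliases UniqueHitTable-class
#' @exportClass UniqueHitTable
setClass("UniqueHitTable", slots = c(
  hits = "DataFrame",
  status = "DataFrame",
  counters = "integer",
  scaffold_lengths = "integer",
  read_length = "integer",
  params = "list"
))

setValidity("UniqueHitTable", function(object) {
  msg <- character()
  cnt <- object@counters
  need <- c("total_reads", "mapped_any", "mapped_unique",
            "suppressed_multi", "unmapped")
  if (!all(need %in% names(cnt))) {
    msg <- c(msg, "missing counters")
  } else {
    if (cnt["mapped_unique"] + cnt["suppressed_multi"] != cnt["mapped_any"])
      msg <- c(msg, "mapped_unique + suppressed_multi must equal mapped_any")
    if (cnt["mapped_any"] + cnt["unmapped"] != cnt["total_reads"])
      msg <- c(msg, "mapped_any + unmapped must equal total_reads")
    if (nrow(object@hits) != cnt["mapped_unique"])
      msg <- c(msg, "hits must hold exactly one row per uniquely mapped read")
    if (nrow(object@status) != cnt["total_reads"])
      msg <- c(msg, "status must hold one row per input read")
  }
  if (nrow(object@hits) &&
      !all(object@hits$scaffold %in% names(object@scaffold_lengths)))
    msg <- c(msg, "hit on unknown scaffold")
  if (length(msg)) msg else TRUE
})

#' Windowed unique-hit coverage profile of one scaffold
#'
#' Non-overlapping fixed-width windows along a scaffold with the number of
#' unique read starts per window and the corresponding density in hits/kb
#' (the last window may be short; its density is normalised by its true
#' length). Produced by [windowProfile()]; consumed by [detectGaps()] and
#' [segmentRegions()].
#'
#' @slot scaffold scaffold id.
#' @slot length_bp scaffold length in bp.
#' @slot window_bp window width in bp.
#' @slot counts integer unique-hit count per window.
#' @slot densities numeric hits/kb per window.
#' @aliases CoverageProfile-class
#' @exportClass CoverageProfile
setClass("CoverageProfile", slots = c(
  scaffold = "character",
  length_bp = "integer",
  window_bp = "integer",
  counts = "integer",
  densities = "numeric"
))

setValidity("CoverageProfile", function(object) {
  msg <- character()
  nw <- ceiling(object@length_bp / object@window_bp)
  if (length(object@counts) != nw || length(object@densities) != nw)
    msg <- c(msg, "counts/densities must cover the scaffold exactly")
  if (any(object@counts < 0L))
    msg <- c(msg, "negative window counts")
  if (length(msg)) msg else TRUE
})

#' Calibrated hits/kb threshold for on-arm assignment
#'
#' A density threshold either read off a physically anchored scaffold
#' (anchor mode: the anchor's own hits/kb, the lowest acceptable value
#' since the anchor is known to lie on the dissected arm) or computed as
#' the mean density of a genomic region (region-mean mode: total unique
#' hits in the region divided by region length in kb). Built by
#' [calibrateThreshold()].
#'
#' @slot mode `"anchor-scaffold"` or `"region-mean"`.
#' @slot value threshold in hits/kb (> 0).
#' @slot anchor_id anchor scaffold id, or `NA` in region-mean mode.
#' @slot region `GRanges` of the calibration region, or `NULL`.
#' @aliases ThresholdSpec-class
#' @exportClass ThresholdSpec
setClass("ThresholdSpec", slots = c(
  mode = "character",
  value = "numeric",
  anchor_id = "character",
  region = "GRangesOrNULL"
))

setValidity("ThresholdSpec", function(object) {
  msg <- character()
  if (!object@mode %in% c("anchor-scaffold", "region-mean"))
    msg <- c(msg, "mode must be anchor-scaffold or region-mean")
  if (!isSingleNumber(object@value) || object@value <= 0)
    msg <- c(msg, "threshold value must be a single positive number")
  if (length(msg)) msg else TRUE
})
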