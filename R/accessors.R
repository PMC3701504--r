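#' Accessors for the core classes
#'
#' Extract the components of [GenomeModel], [SimulatedReads],
#' [UniqueHitTable], [CoverageProfile] and [ThresholdSpec] objects without
#' touching slots directly.
#'
#' @param x an object of the documented class.
#' @return the requested component (see individual descriptions).
#' @name accessors
NULL

#' @describeIn accessors scaffold sequences as a `DNAStringSet`.
#' @export
setGeneric("scaffoldSeqs", function(x) standardGeneric("scaffoldSeqs"))

#' @describeIn accessors per-scaffold metadata `DataFrame`
#'   (`scaffold`, `length`, `label`, `is_border`).
#' @export
setGeneric("scaffoldInfo", function(x) standardGeneric("scaffoldInfo"))

#' @describeIn accessors named integer vector of scaffold lengths.
#' @export
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))

#' @describeIn accessors `GRanges` of implanted repeat copies.
#' @export
setGeneric("repeatRegions", function(x) standardGeneric("repeatRegions"))

#' @describeIn accessors `GRanges` of hybrid-scaffold segment truth.
#' @export
setGeneric("hybridTruth", function(x) standardGeneric("hybridTruth"))

#' @describeIn accessors id of the designated laser-boundary (anchor)
#'   scaffold.
#' @export
setGeneric("borderScaffold", function(x) standardGeneric("borderScaffold"))

#' @describeIn accessors simulated reads as a `DNAStringSet`.
#' @export
setGeneric("readSet", function(x) standardGeneric("readSet"))

#' @describeIn accessors per-read truth `DataFrame`.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @describeIn accessors per-read retained alignments `DataFrame`.
#' @export
setGeneric("hitRecords", function(x) standardGeneric("hitRecords"))

#' @describeIn accessors named aggregate counters of a hit table.
#' @export
setGeneric("hitCounters", function(x) standardGeneric("hitCounters"))

#' @describeIn accessors per-read mapping status `DataFrame`.
#' @export
setGeneric("readStatus", function(x) standardGeneric("readStatus"))

#' @describeIn accessors window densities (hits/kb) of a profile.
#' @export
setGeneric("windowDensities", function(x) standardGeneric("windowDensities"))

#' @describeIn accessors window unique-hit counts of a profile.
#' @export
setGeneric("windowCounts", function(x) standardGeneric("windowCounts"))

#' @describeIn accessors calibrated threshold value in hits/kb.
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname accessors
setMethod("scaffoldSeqs", "GenomeModel", function(x) x@seqs)

#' @rdname accessors
setMethod("scaffoldInfo", "GenomeModel", function(x) x@info)

#' @rdname accessors
setMethod("scaffoldLengths", "GenomeModel", function(x)
  setNames(as.integer(x@info$length), x@info$scaffold))

#' @rdname accessors
setMethod("scaffoldLengths", "UniqueHitTable", function(x) x@scaffold_lengths)

#' @rdname accessors
setMethod("repeatRegions", "GenomeModel", function(x) x@repeats)

#' @rdname accessors
setMethod("hybridTruth", "GenomeModel", function(x) x@hybrids)

#' @rdname accessors
setMethod("borderScaffold", "GenomeModel", function(x) {
  b <- x@info$scaffold[x@info$is_border]
  if (length(b)) as.character(b[1L]) else NA_character_
})

#' @rdname accessors
setMethod("readSet", "SimulatedReads", function(x) x@reads)

#' @rdname accessors
setMethod("truthTable", "SimulatedReads", function(x) x@truth)

#' @rdname accessors
setMethod("hitRecords", "UniqueHitTable", function(x) x@hits)

#' @rdname accessors
setMethod("hitCounters", "UniqueHitTable", function(x) x@counters)

#' @rdname accessors
setMethod("readStatus", "UniqueHitTable", function(x) x@status)

#' @rdname accessors
setMethod("windowDensities", "CoverageProfile", function(x) x@densities)

#' @rdname accessors
setMethod("windowCounts", "CoverageProfile", function(x) x@counts)

#' @rdname accessors
setMethod("thresholdValue", "ThresholdSpec", function(x) x@value)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      object@n_scaffolds, "scaffolds,",
      paste0("[", object@scaffold_length_range[1L], "-",
             object@scaffold_length_range[2L], "] bp,"),
      object@n_reads, "reads of", object@read_length, "bp\n")
  cat("  arm_fraction", object@arm_fraction,
      "| contamination", object@contamination_rate,
      "| error", object@error_rate,
      "| chimera", object@primer_chimera_rate, "\n")
  cat("  WGA sigma", object@wga_lognormal_sigma,
      "| hybrids", object@n_hybrid_scaffolds,
      "| taper", object@boundary_taper_width, "bp",
      "| seed", object@seed, "\n")
})

setMethod("show", "GenomeModel", function(object) {
  tab <- table(object@info$label)
  cat("GenomeModel:", nrow(object@info), "scaffolds (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  cat("  total", sum(object@info$length), "bp;",
      length(object@repeats), "repeat copies;",
      "border scaffold:", borderScaffold(object), "\n")
})

setMethod("show", "SimulatedReads", function(object) {
  cat("SimulatedReads:", length(object@reads), "reads of",
      object@config@read_length, "bp\n")
  cat("  contaminant:", sum(object@truth$is_contaminant),
      "| chimeric:", sum(object@truth$is_chimera), "\n")
})

setMethod("show", "UniqueHitTable", function(object) {
  cnt <- object@counters
  pct <- function(k) sprintf("%.1f%%", 100 * k / max(1L, cnt["total_reads"]))
  cat("UniqueHitTable (v=", object@params$v, ", m=", object@params$m,
      "): ", cnt["total_reads"], " reads\n", sep = "")
  cat("  mapped_any       ", cnt["mapped_any"], " (", pct(cnt["mapped_any"]), ")\n", sep = "")
  cat("  mapped_unique    ", cnt["mapped_unique"], " (", pct(cnt["mapped_unique"]), ")\n", sep = "")
  cat("  suppressed_multi ", cnt["suppressed_multi"], " (", pct(cnt["suppressed_multi"]), ")\n", sep = "")
  cat("  unmapped         ", cnt["unmapped"], " (", pct(cnt["unmapped"]), ")\n", sep = "")
})

setMethod("show", "CoverageProfile", function(object) {
  cat("CoverageProfile of", object@scaffold, ":",
      length(object@counts), "windows of", object@window_bp, "bp (",
      object@length_bp, "bp total)\n")
  cat("  density hits/kb: min", round(min(object@densities), 2),
      "median", round(stats::median(object@densities), 2),
      "max", round(max(object@densities), 2), "\n")
})

setMethod("show", "ThresholdSpec", function(object) {
  cat("ThresholdSpec:", round(object@value, 2), "hits/kb [", object@mode, "]")
  if (!is.na(object@anchor_id)) cat(" anchor:", object@anchor_id)
  cat("\n")
})
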