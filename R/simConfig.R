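#' Create a simulation configuration
#'
#' Builds a validated [SimConfig]. The defaults describe the desk-scale
#' study conditions used throughout the package: a 60-scaffold genome
#' with lengths uniform in 50--300 kb, a quarter of scaffolds on the
#' dissected arm, 200,000 reads of 80 bp, 5% off-arm contamination, 0.5%
#' per-base substitution error, lognormal(0, 1) per-fragment
#' amplification, 10% primer-chimera reads screened at 11 nt, five repeat
#' families of ten identical 500 bp copies, no hybrid scaffolds, and a
#' 350 kb laser-boundary taper. Identical configurations yield
#' byte-identical generator output.
#'
#' @param seed integer seed driving all generator randomness.
#' @param n_scaffolds number of scaffolds (hybrids included).
#' @param scaffold_length_range length-2 integer vector, bp.
#' @param arm_fraction fraction of scaffolds labelled on-arm.
#' @param read_length read length in bp.
#' @param n_reads number of reads to emit.
#' @param contamination_rate fraction of reads drawn from off-arm
#'   scaffolds.
#' @param error_rate per-base substitution probability.
#' @param wga_lognormal_sigma sdlog of the per-fragment amplification
#'   factor (0 disables duplication bias).
#' @param primer_chimera_rate fraction of reads whose end is replaced by
#'   amplification-primer sequence.
#' @param min_primer_insert minimum primer insert length in nt.
#' @param repeat_family_count number of distinct repeat families.
#' @param repeat_copy_number identical copies per family.
#' @param repeat_unit_length repeat unit length in bp.
#' @param n_hybrid_scaffolds number of implanted misassembled scaffolds.
#' @param hybrid_segment_min minimum bp of each hybrid segment; must be at
#'   least 100 kb so implanted joins show up as large coverage gaps.
#' @param boundary_taper_width bp over which sampling probability declines
#'   linearly to zero at the laser-cut boundary.
#' @return a [SimConfig] object.
#' @examples
#' cfg <- simConfig(seed = 1, n_scaffolds = 10, n_reads = 1000)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      n_scaffolds = 60L,
                      scaffold_length_range = c(50000L, 300000L),
                      arm_fraction = 0.25,
                      read_length = 80L,
                      n_reads = 200000L,
                      contamination_rate = 0.05,
                      error_rate = 0.005,
                      wga_lognormal_sigma = 1.0,
                      primer_chimera_rate = 0.10,
                      min_primer_insert = 11L,
                      repeat_family_count = 5L,
                      repeat_copy_number = 10L,
                      repeat_unit_length = 500L,
                      n_hybrid_scaffolds = 0L,
                      hybrid_segment_min = 200000L,
                      boundary_taper_width = 350000L) {
  new("SimConfig",
      seed = as.integer(seed),
      n_scaffolds = as.integer(n_scaffolds),
      scaffold_length_range = as.integer(scaffold_length_range),
      arm_fraction = as.numeric(arm_fraction),
      read_length = as.integer(read_length),
      n_reads = as.integer(n_reads),
      contamination_rate = as.numeric(contamination_rate),
      error_rate = as.numeric(error_rate),
      wga_lognormal_sigma = as.numeric(wga_lognormal_sigma),
      primer_chimera_rate = as.numeric(primer_chimera_rate),
      min_primer_insert = as.integer(min_primer_insert),
      repeat_family_count = as.integer(repeat_family_count),
      repeat_copy_number = as.integer(repeat_copy_number),
      repeat_unit_length = as.integer(repeat_unit_length),
      n_hybrid_scaffolds = as.integer(n_hybrid_scaffolds),
      hybrid_segment_min = as.integer(hybrid_segment_min),
      boundary_taper_width = as.integer(boundary_taper_width))
}
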