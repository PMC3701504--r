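#' @importFrom Biostrings writeXStringSet BStringSet
#' @importFrom utils write.table read.delim packageVersion
#' @importFrom yaml write_yaml read_yaml
#' @importFrom rtracklayer export
#' @importFrom GenomicRanges seqinfo
NULL

.writeTsv <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

.configAsList <- function(config) {
  sl <- slotNames(config)
  out <- lapply(sl, function(s) {
    v <- slot(config, s)
    if (length(v) > 1L) as.list(v) else v
  })
  names(out) <- sl
  out
}

#' Write a simulation to disk in standard formats
#'
#' Materialises a [GenomeModel] and [SimulatedReads] pair as the plain
#' files an external pipeline run would consume: genome FASTA (60-column
#' wrap), reads FASTQ (Phred+33, constant quality `I`), truth TSV
#' (0-based positions), hybrid-truth BED (0-based half-open off-arm
#' segment intervals plus full segment annotation in the name column),
#' per-scaffold truth-label TSV, prior-placement TSV and a YAML echo of
#' the configuration.
#'
#' @param model a [GenomeModel].
#' @param sim a [SimulatedReads], or `NULL` to write the genome side
#'   only.
#' @param dir output directory (created if missing).
#' @param priors optional prior-placement `DataFrame` (defaults to
#'   [priorPlacements()] of the model).
#' @return named character vector of the files written, invisibly.
#' @export
writeSimulation <- function(model, sim = NULL, dir,
                            priors = priorPlacements(model)) {
  stopifnot(is(model, "GenomeModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             scaffolds = file.path(dir, "scaffolds.tsv"),
             priors = file.path(dir, "priors.tsv"),
             hybrid_truth = file.path(dir, "hybrid_truth.bed"),
             config = file.path(dir, "config.yaml"))
  writeXStringSet(scaffoldSeqs(model), paths["genome"], width = 60L)
  .writeTsv(scaffoldInfo(model), paths["scaffolds"])
  .writeTsv(priors, paths["priors"])
  hyb <- hybridTruth(model)
  hyb_df <- if (length(hyb)) {
    data.frame(chrom = as.character(seqnames(hyb)),
               start = start(hyb) - 1L, end = end(hyb),
               name = paste0(hyb$segment, ";breakpoint=", hyb$breakpoint))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
  }
  write.table(hyb_df, paths["hybrid_truth"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(.configAsList(model@config), paths["config"])
  if (!is.null(sim)) {
    stopifnot(is(sim, "SimulatedReads"))
    paths <- c(paths,
               reads = file.path(dir, "reads.fastq"),
               truth = file.path(dir, "truth.tsv"))
    reads <- readSet(sim)
    quals <- BStringSet(rep(paste(rep("I", sim@config@read_length),
                                  collapse = ""), length(reads)))
    writeXStringSet(reads, paths["reads"], format = "fastq",
                    qualities = quals)
    .writeTsv(truthTable(sim), paths["truth"])
  }
  invisible(paths)
}

#' Read a hybrid-truth BED written by [writeSimulation()]
#'
#' @param path BED path (0-based half-open; name column
#'   `label;breakpoint=bp0`).
#' @return a `GRanges` with mcols `segment` and `breakpoint`, matching
#'   [hybridTruth()].
#' @export
readHybridTruth <- function(path) {
  df <- tryCatch(read.delim(path, header = FALSE,
                            col.names = c("chrom", "start", "end", "name")),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L)
    return(GRanges(seqnames = character(), IRanges(),
                   segment = character(), breakpoint = integer()))
  GRanges(df$chrom, IRanges(df$start + 1L, df$end),
          segment = sub(";.*$", "", df$name),
          breakpoint = as.integer(sub(".*breakpoint=", "", df$name)))
}

# bedGraph of one or more coverage profiles
.writeBedGraph <- function(profiles, path) {
  grl <- lapply(profiles, function(p) {
    GRanges(rep(p@scaffold, length(p@counts)),
            IRanges(.windowStarts(p) + 1L, .windowEnds(p)),
            score = round(p@densities, 4))
  })
  gr <- suppressWarnings(do.call(c, unname(grl)))
  rtracklayer::export(gr, unname(path), format = "bedGraph")
  invisible(path)
}

# BED with name = state/label, score = mean density x10 truncated
.writeBed <- function(gr, path, name, density) {
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
  out$name <- if (length(out)) as.character(name) else character()
  out$score <- if (length(out))
    pmin(1000L, as.integer(trunc(density * 10))) else integer()
  rtracklayer::export(out, unname(path), format = "bed")
  invisible(path)
}
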