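#' Assemble a pipeline configuration
#'
#' Collects the file paths and parameters of a full analysis run into a
#' validated list. Parameter defaults are the study settings used
#' throughout the package: mismatch budget `v = 2` with multiplicity
#' `m = 1` (the >97.5% identity unique-hit filter for 80 bp reads),
#' 11 nt primer screen, 10 kb windows, 1 hit/kb sparse cutoff, 100 kb
#' minimum gap, 500 kb minimum region with up to 2 discordant windows
#' absorbed, and anchor-mode thresholding.
#'
#' @param genome path to the reference FASTA.
#' @param reads path to the reads FASTQ (or `NULL` when `sam` is given).
#' @param sam optional path to precomputed single-end SAM alignments;
#'   when supplied the built-in mapper is skipped.
#' @param priors optional path to a prior-placement TSV with columns
#'   `scaffold`, `assigned_location`, `source`.
#' @param primers optional path to a primer FASTA for the unmapped-read
#'   screen; defaults to the built-in synthetic primer set.
#' @param out_dir output directory.
#' @param v,m uniqueness-filter parameters.
#' @param min_match_len primer-screen match length in nt.
#' @param window_bp,sparse_cutoff,min_gap_bp,min_region_bp,max_discordant
#'   coverage-profile and segmentation parameters.
#' @param threshold_mode `"anchor-scaffold"` or `"region-mean"`.
#' @param anchor_id anchor scaffold id (anchor mode). `NULL` selects the
#'   border scaffold named in a `scaffolds.tsv` next to the genome, if
#'   one exists.
#' @param region region string `"scaffold:start-end"` (1-based,
#'   region-mean mode).
#' @param target_arm prior label of the dissected arm.
#' @param sam_policy uniqueness policy for SAM ingestion.
#' @param seed integer seed recorded in the manifest.
#' @return a named list of class `armAnchorConfig`.
#' @export
pipelineConfig <- function(genome, reads = NULL, sam = NULL,
                           priors = NULL, primers = NULL, out_dir,
                           v = 2L, m = 1L, min_match_len = 11L,
                           window_bp = 10000L, sparse_cutoff = 1.0,
                           min_gap_bp = 100000L, min_region_bp = 500000L,
                           max_discordant = 2L,
                           threshold_mode = c("anchor-scaffold",
                                              "region-mean"),
                           anchor_id = NULL, region = NULL,
                           target_arm = "7p",
                           sam_policy = c("record-count", "tag"),
                           seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  sam_policy <- match.arg(sam_policy)
  if (is.null(reads) && is.null(sam))
    stop("supply reads (FASTQ) or sam (alignments)")
  cfg <- list(genome = genome, reads = reads, sam = sam, priors = priors,
              primers = primers, out_dir = out_dir,
              v = as.integer(v), m = as.integer(m),
              min_match_len = as.integer(min_match_len),
              window_bp = as.integer(window_bp),
              sparse_cutoff = as.numeric(sparse_cutoff),
              min_gap_bp = as.integer(min_gap_bp),
              min_region_bp = as.integer(min_region_bp),
              max_discordant = as.integer(max_discordant),
              threshold_mode = threshold_mode,
              anchor_id = anchor_id, region = region,
              target_arm = target_arm, sam_policy = sam_policy,
              seed = as.integer(seed))
  class(cfg) <- "armAnchorConfig"
  cfg
}

.parseRegion <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L)
    stop("region must look like 'scaffold:start-end' (1-based)")
  GRanges(m[2L], IRanges(as.integer(m[3L]), as.integer(m[4L])))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full arm-assignment pipeline
#'
#' Executes, in order: read mapping with the uniqueness filter (or SAM
#' ingestion), primer screening of the unmapped reads, per-scaffold
#' density, threshold calibration, scaffold classification, category
#' summary, per-scaffold coverage profiles, gap detection, dense/sparse
#' segmentation and the hybrid-candidate report. All results are written
#' to `out_dir` as TSV/BED/bedGraph plus a `manifest.yaml` (config echo,
#' package version, seed, counters) that makes re-runs byte-identical;
#' nothing in the outputs depends on wall-clock time.
#'
#' @param config a list from [pipelineConfig()].
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with the in-memory stage results
#'   (`hit_table`, `primer_screen`, `densities`, `threshold`, `calls`,
#'   `summary`, `profiles`, `gaps`, `segments`, `hybrids`, `files`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "armAnchorConfig"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- .stage("load-genome", readDNAStringSet(config$genome))

  if (!is.null(config$sam)) {
    say("ingesting SAM alignments")
    ht <- .stage("ingest-sam", ingestSam(config$sam,
                                         policy = config$sam_policy))
    if (length(scaffoldLengths(ht)) < length(genome))
      ht@scaffold_lengths <- setNames(width(genome), names(genome))
    reads <- NULL
  } else {
    say("mapping reads (v=", config$v, ", m=", config$m, ")")
    reads <- .stage("load-reads",
                    readDNAStringSet(config$reads, format = "fastq"))
    ht <- .stage("map", mapReads(reads, genome, v = config$v,
                                 m = config$m))
  }

  screen <- NULL
  if (!is.null(reads)) {
    say("screening unmapped reads for primer sequence")
    unm <- reads[readStatus(ht)$status == "unmapped"]
    primers <- if (is.null(config$primers)) defaultPrimers()
               else readDNAStringSet(config$primers)
    screen <- .stage("primer-screen",
                     if (length(unm)) screenPrimers(unm, primers,
                                                    config$min_match_len)
                     else NULL)
  }

  say("computing per-scaffold densities")
  dens <- .stage("density", scaffoldDensity(ht))

  say("calibrating threshold (", config$threshold_mode, ")")
  thr <- .stage("threshold", {
    if (config$threshold_mode == "anchor-scaffold") {
      anchor <- config$anchor_id
      if (is.null(anchor)) {
        scaff_tsv <- file.path(dirname(config$genome), "scaffolds.tsv")
        if (file.exists(scaff_tsv)) {
          si <- read.delim(scaff_tsv)
          if (any(si$is_border)) anchor <- si$scaffold[si$is_border][1L]
        }
      }
      if (is.null(anchor))
        stop("anchor-scaffold mode needs anchor_id")
      calibrateThreshold(dens, anchor_id = anchor)
    } else {
      calibrateThreshold(hits = ht, region = .parseRegion(config$region))
    }
  })

  priors <- NULL
  if (!is.null(config$priors))
    priors <- .stage("load-priors", read.delim(config$priors))

  say("classifying scaffolds against ", round(thresholdValue(thr), 2),
      " hits/kb")
  calls <- .stage("classify",
                  classifyScaffolds(dens, thr, priors,
                                    target_arm = config$target_arm))
  summ <- .stage("summarize", summarizeCategories(calls, ht))

  say("profiling coverage, detecting gaps, segmenting")
  sl <- scaffoldLengths(ht)
  profiles <- .stage("profile", lapply(names(sl), function(sc)
    windowProfile(ht, sc, window_bp = config$window_bp)))
  names(profiles) <- names(sl)
  gaps <- .stage("gaps", {
    gl <- lapply(profiles, detectGaps, sparse_cutoff = config$sparse_cutoff,
                 min_gap_bp = config$min_gap_bp)
    suppressWarnings(do.call(c, unname(gl)))
  })
  segs <- .stage("segments", {
    gl <- lapply(profiles, segmentRegions,
                 dense_cutoff = thresholdValue(thr),
                 min_region_bp = config$min_region_bp,
                 max_discordant = config$max_discordant)
    suppressWarnings(do.call(c, unname(gl)))
  })
  hybrids <- .stage("hybrids", flagHybrids(calls, gaps))

  say("writing outputs to ", config$out_dir)
  files <- .stage("write", {
    od <- config$out_dir
    f <- c(hits = file.path(od, "hits.tsv"),
           density = file.path(od, "density.tsv"),
           calls = file.path(od, "calls.tsv"),
           summary = file.path(od, "summary.tsv"),
           profile = file.path(od, "profile.bedgraph"),
           gaps = file.path(od, "gaps.bed"),
           segments = file.path(od, "segments.bed"),
           hybrids = file.path(od, "hybrids.tsv"),
           manifest = file.path(od, "manifest.yaml"))
    .writeTsv(hitRecords(ht), f["hits"])
    .writeTsv(dens, f["density"])
    .writeTsv(calls, f["calls"])
    .writeTsv(summ, f["summary"])
    .writeBedGraph(profiles, f["profile"])
    .writeBed(gaps, f["gaps"],
              name = if (length(gaps))
                ifelse(gaps$terminal, "terminal-gap", "gap") else character(),
              density = if (length(gaps))
                gaps$mean_density_inside else numeric())
    .writeBed(segs, f["segments"],
              name = if (length(segs)) segs$state else character(),
              density = if (length(segs)) segs$mean_density else numeric())
    hyb_df <- merge(as.data.frame(hybrids$candidates),
                    data.frame(scaffold = as.character(seqnames(hybrids$gaps)),
                               gap_start0 = start(hybrids$gaps) - 1L,
                               gap_end0 = end(hybrids$gaps),
                               gap_mean_density =
                                 hybrids$gaps$mean_density_inside),
                    by = "scaffold", all.x = TRUE)
    .writeTsv(hyb_df, f["hybrids"])
    if (!is.null(screen))
      .writeTsv(data.frame(n_unmapped = screen$n_unmapped,
                           n_primer_positive = screen$n_primer_positive,
                           min_match_len = screen$min_match_len,
                           primer = names(screen$per_primer),
                           primer_positive = as.integer(screen$per_primer)),
                file.path(od, "primer_screen.tsv"))
    manifest <- list(
      package = "armAnchor",
      version = as.character(packageVersion("armAnchor")),
      seed = config$seed,
      config = config[setdiff(names(config), "out_dir")],
      threshold = list(mode = thr@mode,
                       value = thresholdValue(thr),
                       anchor_id = thr@anchor_id),
      counters = as.list(hitCounters(ht)),
      hybrid_fraction = hybrids$fraction_flagged)
    yaml::write_yaml(manifest, f["manifest"])
    f
  })

  invisible(list(hit_table = ht, primer_screen = screen, densities = dens,
                 threshold = thr, calls = calls, summary = summ,
                 profiles = profiles, gaps = gaps, segments = segs,
                 hybrids = hybrids, files = files))
}

#' Score pipeline output against simulation truth
#'
#' Compares scaffold calls to the generator's true labels and gap calls
#' to the implanted hybrid joins. A scaffold counts as called on-arm
#' when its category is `confirmed-on-arm`, `newly-assigned` or
#' `reassignment-candidate`; truth-positive scaffolds are those labelled
#' `"on-arm"` (hybrid scaffolds, which are part on-arm by construction,
#' are excluded from the scaffold-level metric and scored separately).
#' A hybrid join is detected when any gap call on the hybrid scaffold
#' overlaps the true off-arm segment; its breakpoint error is the
#' distance between the gap edge facing the on-arm segment and the true
#' join coordinate.
#'
#' @param calls classification table ([classifyScaffolds()] output or
#'   the written `calls.tsv` read back).
#' @param truth_labels `DataFrame`/`data.frame` with columns `scaffold`
#'   and `label` (from [scaffoldInfo()] or `scaffolds.tsv`).
#' @param gaps optional `GRanges` of gap calls.
#' @param hybrid_truth optional `GRanges` from [hybridTruth()] or
#'   [readHybridTruth()].
#' @return a list with `precision`, `recall`, `f1`,
#'   `hybrid_sensitivity`, `mean_breakpoint_error_bp` and `per_hybrid`.
#' @export
evaluateAgainstTruth <- function(calls, truth_labels, gaps = NULL,
                                 hybrid_truth = NULL) {
  i <- match(calls$scaffold, truth_labels$scaffold)
  if (anyNA(i))
    stop("truth labels missing for: ",
         paste(calls$scaffold[is.na(i)], collapse = ", "))
  lab <- as.character(truth_labels$label[i])
  pred <- calls$category %in% c("confirmed-on-arm", "newly-assigned",
                                "reassignment-candidate")
  keep <- lab != "hybrid"
  tp <- sum(pred[keep] & lab[keep] == "on-arm")
  fp <- sum(pred[keep] & lab[keep] != "on-arm")
  fn <- sum(!pred[keep] & lab[keep] == "on-arm")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_

  hyb_sens <- NA_real_
  mean_bp_err <- NA_real_
  per_hyb <- NULL
  if (!is.null(hybrid_truth) && length(hybrid_truth)) {
    off <- hybrid_truth[hybrid_truth$segment == "off-arm"]
    det <- logical(length(off))
    err <- rep(NA_real_, length(off))
    for (j in seq_along(off)) {
      sc <- as.character(seqnames(off))[j]
      g <- if (is.null(gaps)) GRanges() else
        gaps[as.character(seqnames(gaps)) == sc]
      if (length(g) == 0L) next
      ov <- start(g) <= end(off)[j] & end(g) >= start(off)[j]
      if (!any(ov)) next
      det[j] <- TRUE
      bp0 <- off$breakpoint[j]
      # gap edge facing the on-arm side vs the true join coordinate
      edge <- if (start(off)[j] == 1L) end(g)[ov] else start(g)[ov] - 1L
      err[j] <- min(abs(edge - bp0))
    }
    hyb_sens <- mean(det)
    mean_bp_err <- if (any(det)) mean(err[det]) else NA_real_
    per_hyb <- DataFrame(scaffold = as.character(seqnames(off)),
                         off_start0 = start(off) - 1L,
                         off_end0 = end(off),
                         breakpoint0 = off$breakpoint,
                         detected = det,
                         breakpoint_error_bp = err)
  }
  list(precision = precision, recall = recall, f1 = f1,
       hybrid_sensitivity = hyb_sens,
       mean_breakpoint_error_bp = mean_bp_err,
       per_hybrid = per_hyb)
}

#' Render the written pipeline outputs as an aligned-text report
#'
#' Formats the category summary, the densest newly-assigned scaffolds
#' and the hybrid-candidate list from the TSV files a pipeline run
#' wrote. Every number is read from the files; nothing is recomputed,
#' so the report always matches the TSVs cell for cell.
#'
#' @param out_dir directory written by [runPipeline()].
#' @param top_n how many newly-assigned scaffolds to list.
#' @param path optional file to write the report to
#'   (`file.path(out_dir, "report.txt")` by default; `NA` to skip
#'   writing).
#' @return the report lines, invisibly.
#' @export
renderReport <- function(out_dir, top_n = 10L,
                         path = file.path(out_dir, "report.txt")) {
  summ <- read.delim(file.path(out_dir, "summary.tsv"))
  calls <- read.delim(file.path(out_dir, "calls.tsv"))
  lines <- c("Unique-hit accounting by scaffold category",
             "------------------------------------------")
  w1 <- max(nchar(summ$category)) + 2L
  lines <- c(lines, sprintf(paste0("%-", w1, "s%12s%10s"),
                            "category", "hits", "%"))
  lines <- c(lines, sprintf(paste0("%-", w1, "s%12d%10.2f"),
                            summ$category, as.integer(summ$unique_hits),
                            summ$percent))
  newly <- calls[calls$category == "newly-assigned", , drop = FALSE]
  lines <- c(lines, "", sprintf(
    "Newly assigned scaffolds (previously unmapped, above threshold): %d",
    nrow(newly)))
  if (nrow(newly)) {
    newly <- newly[order(-newly$hits_per_kb), , drop = FALSE]
    top <- utils::head(newly, top_n)
    lines <- c(lines,
               sprintf("  %-16s%12s%12s", "scaffold", "length_bp",
                       "hits_per_kb"),
               sprintf("  %-16s%12d%12.2f", top$scaffold, top$length_bp,
                       top$hits_per_kb))
  } else {
    lines <- c(lines, "  (none)")
  }
  hyb_path <- file.path(out_dir, "hybrids.tsv")
  if (file.exists(hyb_path)) {
    hyb <- read.delim(hyb_path)
    lines <- c(lines, "", sprintf("Hybrid-scaffold candidates: %d",
                                  length(unique(hyb$scaffold))))
    if (nrow(hyb))
      lines <- c(lines, sprintf("  %s gap %d-%d (%.2f hits/kb inside)",
                                hyb$scaffold, hyb$gap_start0, hyb$gap_end0,
                                hyb$gap_mean_density))
  }
  if (!is.na(path)) writeLines(lines, path)
  invisible(lines)
}
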