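#' Per-scaffold unique-hit density (hits/kb)
#'
#' The central enrichment statistic: the number of uniquely mapping
#' reads whose start falls on a scaffold, divided by scaffold length in
#' kilobases. Every scaffold with a known length gets a record,
#' including zero-hit scaffolds; length is the full assembled length (N
#' runs included).
#'
#' @param hits a [UniqueHitTable], or a `DataFrame`/`data.frame` of hit
#'   records with a `scaffold` column.
#' @param scaffold_lengths named vector of scaffold lengths in bp;
#'   defaults to the lengths stored in the hit table.
#' @return a `DataFrame` with columns `scaffold`, `length_bp`,
#'   `unique_hits`, `hits_per_kb`.
#' @examples
#' d <- scaffoldDensity(
#'   S4Vectors::DataFrame(scaffold = rep("s1", 170)),
#'   c(s1 = 10000L, s2 = 5000L))
#' d   # 17 hits/kb on s1, 0 on s2
#' @export
scaffoldDensity <- function(hits, scaffold_lengths = NULL) {
  if (is(hits, "UniqueHitTable")) {
    if (is.null(scaffold_lengths)) scaffold_lengths <- scaffoldLengths(hits)
    hits <- hitRecords(hits)
  }
  if (is.null(scaffold_lengths))
    stop("scaffold_lengths must be supplied when hits is a plain table")
  unknown <- setdiff(unique(hits$scaffold), names(scaffold_lengths))
  if (length(unknown))
    stop("hit on unknown scaffold: ", paste(unknown, collapse = ", "))
  cnt <- table(factor(hits$scaffold, levels = names(scaffold_lengths)))
  DataFrame(scaffold = names(scaffold_lengths),
            length_bp = as.integer(scaffold_lengths),
            unique_hits = as.integer(cnt),
            hits_per_kb = as.numeric(cnt) /
              (as.numeric(scaffold_lengths) / 1000))
}

#' Calibrate the on-arm density threshold
#'
#' Two calibration modes. Anchor mode reads the threshold off a scaffold
#' of known physical location at the edge of the dissected region: the
#' anchor's own hits/kb is the lowest density still compatible with an
#' on-arm location, so it becomes the threshold (and the anchor itself
#' passes, as the comparison downstream is inclusive). Region-mean mode
#' divides the total unique hits falling in a genomic region by the
#' region length in kb -- the calibration used when the reference is a
#' chromosome-scale superscaffold whose dissected-arm portion is known
#' approximately.
#'
#' @param densities `DataFrame` from [scaffoldDensity()] (anchor mode).
#' @param anchor_id anchor scaffold id (anchor mode).
#' @param hits a [UniqueHitTable] (region-mean mode).
#' @param region a `GRanges` of one or more calibration intervals
#'   (region-mean mode).
#' @param region_hits,region_bp alternatively, the total unique-hit
#'   count and region length in bp for a region whose hits were counted
#'   elsewhere (region-mean mode arithmetic form).
#' @return a [ThresholdSpec].
#' @examples
#' calibrateThreshold(region_hits = 1753800, region_bp = 60e6)  # 29.23
#' @export
calibrateThreshold <- function(densities = NULL, anchor_id = NULL,
                               hits = NULL, region = NULL,
                               region_hits = NULL, region_bp = NULL) {
  if (!is.null(anchor_id)) {
    stopifnot(!is.null(densities))
    i <- match(anchor_id, densities$scaffold)
    if (is.na(i))
      stop("anchor scaffold not found: ", anchor_id)
    val <- densities$hits_per_kb[i]
    if (val <= 0)
      stop("anchor scaffold ", anchor_id,
           " has zero density: uninformative anchor")
    return(new("ThresholdSpec", mode = "anchor-scaffold", value = val,
               anchor_id = as.character(anchor_id), region = NULL))
  }
  if (!is.null(region_hits) && !is.null(region_bp)) {
    return(new("ThresholdSpec", mode = "region-mean",
               value = region_hits / (region_bp / 1000),
               anchor_id = NA_character_, region = region))
  }
  if (!is.null(hits) && !is.null(region)) {
    stopifnot(is(hits, "UniqueHitTable"), is(region, "GRanges"))
    h <- hitRecords(hits)
    n <- 0L
    for (j in seq_along(region)) {
      sc <- as.character(seqnames(region))[j]
      n <- n + sum(h$scaffold == sc &
                     h$pos0 >= start(region)[j] - 1L &
                     h$pos0 < end(region)[j])
    }
    bp <- sum(width(region))
    if (bp == 0L) stop("empty calibration region")
    return(new("ThresholdSpec", mode = "region-mean",
               value = n / (bp / 1000),
               anchor_id = NA_character_, region = region))
  }
  stop("supply either (densities, anchor_id), (hits, region) or ",
       "(region_hits, region_bp)")
}

.CATEGORIES <- c("confirmed-on-arm", "reassignment-candidate",
                 "newly-assigned", "prior-conflict", "under-threshold")

#' Classify scaffolds against the threshold and their prior placements
#'
#' Applies the decision table behind the arm-assignment analysis. A
#' scaffold is above threshold iff its density is at least the
#' calibrated value (inclusive: the anchor itself is physically on-arm).
#' Crossing that flag with the scaffold's prior map placement gives the
#' category: above threshold with a prior on the target arm is
#' `confirmed-on-arm`; above threshold but previously unmapped is
#' `newly-assigned`; above threshold with a prior elsewhere is a
#' `reassignment-candidate` (the map placement, not the density, is the
#' suspect); below threshold with a target-arm prior is a
#' `prior-conflict` (density contradicts the map); everything else below
#' threshold is `under-threshold` (treated as off-arm). Scaffolds
#' without a prior record are treated as unmapped, with a message.
#'
#' @param densities `DataFrame` from [scaffoldDensity()].
#' @param threshold a [ThresholdSpec], or a single hits/kb value.
#' @param priors `DataFrame`/`data.frame` with columns `scaffold` and
#'   `assigned_location` (e.g. from [priorPlacements()]), or `NULL` to
#'   treat every scaffold as unmapped.
#' @param target_arm prior label counting as "already on the dissected
#'   arm" (default `"7p"`).
#' @return a `DataFrame` with the density columns plus `prior`,
#'   `above_threshold` and `category`.
#' @export
classifyScaffolds <- function(densities, threshold, priors = NULL,
                              target_arm = "7p") {
  thr <- if (is(threshold, "ThresholdSpec")) threshold@value
         else as.numeric(threshold)
  stopifnot(length(thr) == 1L, thr > 0)
  prior <- rep("unmapped", nrow(densities))
  if (!is.null(priors)) {
    i <- match(densities$scaffold, priors$scaffold)
    if (anyNA(i))
      message(sum(is.na(i)),
              " scaffold(s) without prior record treated as unmapped")
    prior[!is.na(i)] <- as.character(priors$assigned_location[i[!is.na(i)]])
  }
  above <- densities$hits_per_kb >= thr
  category <- ifelse(above,
                     ifelse(prior == target_arm, "confirmed-on-arm",
                            ifelse(prior == "unmapped", "newly-assigned",
                                   "reassignment-candidate")),
                     ifelse(prior == target_arm, "prior-conflict",
                            "under-threshold"))
  out <- densities
  out$prior <- prior
  out$above_threshold <- above
  out$category <- factor(category, levels = .CATEGORIES)
  out
}

#' Category accounting table from raw hit counts
#'
#' Low-level arithmetic behind the published-style summary tables: given
#' named part counts and the total number of unique hits, computes each
#' part's percentage as `100 * part / total` rounded to two decimals
#' (plus a one-decimal display column) and appends a residual row so the
#' raw counts conserve exactly, then a total row.
#'
#' @param counts named numeric vector of per-category unique-hit counts.
#' @param total total unique hits (default `sum(counts)`; when larger,
#'   the difference goes into the residual row).
#' @param residual_label name for the residual row.
#' @return a `DataFrame` with columns `category`, `unique_hits`,
#'   `percent` (2 dp) and `percent_1dp`.
#' @examples
#' categoryTable(
#'   c(`7p-mapped` = 2638303, `reassigned` = 135487, `new` = 880547),
#'   total = 3900340, residual_label = "under-threshold")
#' @export
categoryTable <- function(counts, total = sum(counts),
                          residual_label = "residual") {
  stopifnot(!is.null(names(counts)), total >= sum(counts))
  resid <- total - sum(counts)
  cat_names <- c(names(counts), residual_label)
  vals <- c(as.numeric(counts), resid)
  pct <- round(100 * vals / total, 2)
  DataFrame(category = c(cat_names, "all"),
            unique_hits = c(vals, total),
            percent = c(pct, 100),
            percent_1dp = round(c(100 * vals / total, 100), 1))
}

#' Summarize classification categories as a hit-accounting table
#'
#' Aggregates unique hits over the scaffold categories from
#' [classifyScaffolds()] and expresses each as a percentage of all
#' unique hits. When the full [UniqueHitTable] is supplied its
#' `mapped_unique` counter is used as the total, and any hits on
#' scaffolds absent from the calls land in a residual row so the counts
#' conserve exactly.
#'
#' @param calls output of [classifyScaffolds()].
#' @param hits optional [UniqueHitTable] providing the authoritative
#'   total.
#' @return a `DataFrame` as in [categoryTable()], one row per category
#'   (in fixed order) plus residual and total rows.
#' @export
summarizeCategories <- function(calls, hits = NULL) {
  parts <- vapply(split(calls$unique_hits, calls$category), sum,
                  numeric(1L))
  parts <- parts[.CATEGORIES]
  names(parts) <- .CATEGORIES
  parts[is.na(parts)] <- 0
  total <- if (is(hits, "UniqueHitTable"))
    as.numeric(hitCounters(hits)["mapped_unique"]) else sum(parts)
  categoryTable(parts, total = total, residual_label = "uncalled")
}
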