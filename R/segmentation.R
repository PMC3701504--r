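#' Windowed unique-hit coverage profile
#'
#' Bins the unique-hit start positions of one scaffold into
#' non-overlapping windows of `window_bp` and reports per-window counts
#' and densities in hits/kb. The final window may be shorter than
#' `window_bp`; its density is normalised by its true length, so the
#' profile total always reconstructs the scaffold's unique-hit count.
#'
#' @param hits a [UniqueHitTable] or a hit `DataFrame` with columns
#'   `scaffold` and `pos0`.
#' @param scaffold scaffold id to profile.
#' @param length_bp scaffold length in bp; defaults to the length stored
#'   in the hit table.
#' @param window_bp window width in bp (default 10000; minimum 1000).
#' @return a [CoverageProfile].
#' @export
windowProfile <- function(hits, scaffold, length_bp = NULL,
                          window_bp = 10000L) {
  if (window_bp < 1000L) stop("window_bp must be >= 1000")
  if (is(hits, "UniqueHitTable")) {
    if (is.null(length_bp)) {
      sl <- scaffoldLengths(hits)
      if (!scaffold %in% names(sl))
        stop("unknown scaffold: ", scaffold)
      length_bp <- sl[[scaffold]]
    }
    hits <- hitRecords(hits)
  }
  if (is.null(length_bp)) stop("length_bp must be supplied")
  pos <- hits$pos0[hits$scaffold == scaffold]
  if (any(pos < 0L | pos >= length_bp))
    stop("hit positions outside [0, length_bp) for ", scaffold)
  nw <- as.integer(ceiling(length_bp / window_bp))
  cnt <- tabulate(pos %/% window_bp + 1L, nbins = nw)
  wlen <- rep(window_bp, nw)
  wlen[nw] <- length_bp - (nw - 1L) * window_bp
  new("CoverageProfile", scaffold = as.character(scaffold),
      length_bp = as.integer(length_bp), window_bp = as.integer(window_bp),
      counts = as.integer(cnt), densities = cnt / (wlen / 1000))
}

.windowStarts <- function(profile) {
  (seq_along(profile@counts) - 1L) * profile@window_bp
}

.windowEnds <- function(profile) {
  pmin(seq_along(profile@counts) * profile@window_bp, profile@length_bp)
}

#' Detect large unique-hit coverage gaps
#'
#' Finds maximal runs of consecutive windows whose density is below
#' `sparse_cutoff` and whose total span is at least `min_gap_bp`. Gaps
#' this large inside an otherwise read-dense scaffold are the signature
#' of a misassembled (hybrid) scaffold: the gapped stretch derives from
#' another chromosomal region, so the dissected arm contributes no
#' unique reads there. Gaps touching a scaffold end are flagged
#' `terminal` -- a terminal decline can also be produced by the laser
#' cutting path or a trivially truncated assembly -- but are still
#' reported.
#'
#' @param profile a [CoverageProfile].
#' @param sparse_cutoff density in hits/kb below which a window counts
#'   as read-absent (default 1.0, the off-arm ceiling).
#' @param min_gap_bp minimum reportable gap span in bp (default 100000).
#' @return a `GRanges` (1-based) with metadata columns `span_bp`,
#'   `mean_density_inside` and `terminal`.
#' @export
detectGaps <- function(profile, sparse_cutoff = 1.0, min_gap_bp = 100000L) {
  stopifnot(is(profile, "CoverageProfile"))
  sparse <- profile@densities < sparse_cutoff
  r <- rle(sparse)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  ws <- .windowStarts(profile)
  we <- .windowEnds(profile)
  keep <- which(r$values)
  out <- list()
  for (j in keep) {
    s_bp <- ws[starts_i[j]]
    e_bp <- we[ends_i[j]]
    span <- e_bp - s_bp
    if (span < min_gap_bp) next
    wsel <- starts_i[j]:ends_i[j]
    out[[length(out) + 1L]] <- data.frame(
      start = s_bp + 1L, end = e_bp,
      span_bp = span,
      mean_density_inside = sum(profile@counts[wsel]) / (span / 1000),
      terminal = starts_i[j] == 1L || ends_i[j] == length(sparse))
  }
  if (length(out) == 0L)
    return(GRanges(seqnames = character(), IRanges(),
                   span_bp = integer(), mean_density_inside = numeric(),
                   terminal = logical()))
  df <- do.call(rbind, out)
  GRanges(rep(profile@scaffold, nrow(df)),
          IRanges(df$start, df$end),
          span_bp = as.integer(df$span_bp),
          mean_density_inside = df$mean_density_inside,
          terminal = df$terminal)
}

#' Segment a scaffold into read-dense and read-sparse regions
#'
#' Labels each window dense or sparse against `dense_cutoff`, absorbs
#' interior runs of up to `max_discordant` contrary windows into their
#' surroundings (published region bounds are visibly smoothed; a small
#' run-length tolerance stands in for that), then merges any region
#' shorter than `min_region_bp` into a neighbour -- the longer one, the
#' leftmost on ties -- until all regions meet the minimum. The result
#' tiles `[0, length)` exactly with alternating states.
#'
#' @param profile a [CoverageProfile].
#' @param dense_cutoff density in hits/kb at or above which a window is
#'   dense (typically the calibrated threshold value).
#' @param min_region_bp minimum region span in bp (default 500000).
#' @param max_discordant maximum run of contrary windows absorbed inside
#'   a region (default 2).
#' @return a `GRanges` (1-based) tiling the scaffold, with metadata
#'   columns `state` (`"dense"`/`"sparse"`) and `mean_density`.
#' @export
segmentRegions <- function(profile, dense_cutoff, min_region_bp = 500000L,
                           max_discordant = 2L) {
  stopifnot(is(profile, "CoverageProfile"), dense_cutoff > 0)
  dense <- profile@densities >= dense_cutoff
  nw <- length(dense)

  # absorb short interior contrary runs (shortest first, leftmost on tie)
  repeat {
    r <- rle(dense)
    if (length(r$lengths) <= 1L) break
    interior <- seq_along(r$lengths)[-c(1L, length(r$lengths))]
    cand <- interior[r$lengths[interior] <= max_discordant]
    if (length(cand) == 0L) break
    j <- cand[which.min(r$lengths[cand])]
    e <- cumsum(r$lengths)
    idx <- (e[j] - r$lengths[j] + 1L):e[j]
    dense[idx] <- !r$values[j]
  }

  ws <- .windowStarts(profile)
  we <- .windowEnds(profile)
  segSpans <- function(r) {
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    we[e] - ws[s]
  }

  # enforce the minimum region span (smallest first, leftmost on tie)
  repeat {
    r <- rle(dense)
    if (length(r$lengths) <= 1L) break
    span <- segSpans(r)
    small <- which(span < min_region_bp)
    if (length(small) == 0L) break
    j <- small[which.min(span[small])]
    e <- cumsum(r$lengths)
    idx <- (e[j] - r$lengths[j] + 1L):e[j]
    # merge into the longer neighbour, leftmost on tie
    left <- if (j > 1L) span[j - 1L] else -1
    right <- if (j < length(span)) span[j + 1L] else -1
    takeLeft <- left >= right
    dense[idx] <- r$values[if (takeLeft) j - 1L else j + 1L]
  }

  r <- rle(dense)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  md <- vapply(seq_along(s), function(j) {
    wsel <- s[j]:e[j]
    sum(profile@counts[wsel]) / ((we[e[j]] - ws[s[j]]) / 1000)
  }, numeric(1L))
  GRanges(rep(profile@scaffold, length(s)),
          IRanges(ws[s] + 1L, we[e]),
          state = ifelse(r$values, "dense", "sparse"),
          mean_density = md)
}

#' Flag hybrid-scaffold candidates from calls and gap evidence
#'
#' A scaffold is a hybrid (misassembly) candidate when it is above the
#' on-arm density threshold -- so most of it genuinely belongs to the
#' dissected arm -- and nevertheless contains at least one large
#' coverage gap. Terminal gaps are excluded by default because a
#' terminal density decline can be the laser cutting path rather than a
#' bad join; set `include_terminal = TRUE` to count them. The report
#' lists every qualifying gap interval (probe-design targets for
#' physical validation) and the fraction of on-arm-called scaffolds
#' that are flagged.
#'
#' @param calls output of [classifyScaffolds()].
#' @param gaps a `GRanges` of gap calls (concatenated [detectGaps()]
#'   output across scaffolds).
#' @param include_terminal also count gaps touching scaffold ends.
#' @return a list with `candidates` (`DataFrame` of flagged scaffolds
#'   and their gap counts), `gaps` (the qualifying gap intervals on
#'   flagged scaffolds), `n_on_arm` (number of on-arm-called scaffolds)
#'   and `fraction_flagged`.
#' @export
flagHybrids <- function(calls, gaps, include_terminal = FALSE) {
  on_arm <- calls$scaffold[calls$category %in%
                             c("confirmed-on-arm", "newly-assigned",
                               "reassignment-candidate")]
  g <- gaps
  if (!include_terminal && length(g)) g <- g[!g$terminal]
  g <- g[as.character(seqnames(g)) %in% on_arm]
  cand <- unique(as.character(seqnames(g)))
  n_gaps <- if (length(cand))
    as.integer(table(factor(as.character(seqnames(g)), levels = cand)))
  else integer()
  list(candidates = DataFrame(scaffold = cand, n_gaps = n_gaps),
       gaps = g,
       n_on_arm = length(on_arm),
       fraction_flagged = if (length(on_arm))
         length(cand) / length(on_arm) else NA_real_)
}
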