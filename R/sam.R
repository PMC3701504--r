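#' Serialize a hit table as minimal single-end SAM
#'
#' Writes one record per input read: uniquely mapped reads as aligned
#' records (1-based `POS`, full-length match CIGAR, `NM` mismatch tag and
#' `NH:i:1`), and unmapped reads as flag-4 records. Reads suppressed by
#' the multiplicity filter are written as flag-4 records carrying an
#' `XM:i` tag -- the aligner convention for "alignments existed but were
#' suppressed" -- so that the aggregate counters survive a round trip
#' through [ingestSam()]. Sequences and qualities are written as `*`.
#'
#' @param x a [UniqueHitTable].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [ingestSam()]
#' @export
writeSam <- function(x, path) {
  stopifnot(is(x, "UniqueHitTable"))
  sl <- scaffoldLengths(x)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sl), as.integer(sl)))
  st <- readStatus(x)
  hits <- hitRecords(x)
  L <- x@read_length
  cigar <- if (is.na(L)) "*" else sprintf("%dM", L)
  rec <- character(nrow(st))
  uq <- st$status == "unique"
  if (any(uq)) {
    h <- hits[match(st$read_id[uq], hits$read_id), , drop = FALSE]
    rec[uq] <- paste(h$read_id, ifelse(h$strand == "-", 16L, 0L),
                     h$scaffold, h$pos0 + 1L, 255L, cigar, "*", 0L, 0L,
                     "*", "*", sprintf("NM:i:%d", h$mismatches), "NH:i:1",
                     sep = "\t")
  }
  if (any(!uq)) {
    tags <- ifelse(st$status[!uq] == "multi",
                   sprintf("\tXM:i:%d", x@params$m + 1L), "")
    rec[!uq] <- paste0(paste(st$read_id[!uq], 4L, "*", 0L, 0L, "*", "*",
                             0L, 0L, "*", "*", sep = "\t"), tags)
  }
  writeLines(c(header, rec), path)
  invisible(path)
}

.cigarReadLength <- function(cigar) {
  if (cigar == "*") return(NA_integer_)
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (ops[1L] == -1L) return(NA_integer_)
  pieces <- regmatches(cigar, gregexpr("\\d+[MIS=X]", cigar))[[1L]]
  sum(as.integer(sub("[MIS=X]$", "", pieces)))
}

#' Ingest single-end SAM alignments under a uniqueness policy
#'
#' Builds a [UniqueHitTable] from external aligner output instead of the
#' built-in mapper. Records are grouped by read id; under the
#' `"record-count"` policy a read is unique iff exactly one
#' non-secondary, non-supplementary aligned record exists for it, and
#' suppressed as multi-mapping if more than one does; under the `"tag"`
#' policy the aligned record's `NH:i` multiplicity tag decides
#' (`NH == 1` unique, `NH > 1` multi). Flag-4 records carrying an `XM:i`
#' tag (the aligner's own way of reporting reads suppressed by a
#' multiplicity limit) are counted as suppressed, not unmapped, under
#' either policy. Mismatch counts are taken from `NM:i` tags when
#' present. Reference lengths come from `@SQ` header lines, or are
#' inferred from the rightmost alignment per scaffold if no header is
#' present.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @param policy `"record-count"` (default; multiplicity tags differ
#'   across aligners) or `"tag"`.
#' @return a [UniqueHitTable].
#' @export
ingestSam <- function(sam, policy = c("record-count", "tag")) {
  policy <- match.arg(policy)
  lines <- if (length(sam) == 1L && file.exists(sam)) readLines(sam) else sam

  sq <- grep("^@SQ\t", lines, value = TRUE)
  sl <- integer()
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:(\\d+).*", "\\1", sq))
    sl <- setNames(ln, sn)
  }

  body_idx <- which(!startsWith(lines, "@"))
  n_rec <- length(body_idx)
  body <- lines[body_idx]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    j <- which(nf < 11L)[1L]
    stop("malformed SAM line ", body_idx[j],
         ": expected at least 11 fields, got ", nf[j])
  }
  fld <- function(k) vapply(parts, `[[`, character(1L), k)
  qname <- fld(1L)
  flag <- suppressWarnings(as.integer(fld(2L)))
  rname <- fld(3L)
  pos <- suppressWarnings(as.integer(fld(4L)))
  if (anyNA(flag) || anyNA(pos)) {
    j <- which(is.na(flag) | is.na(pos))[1L]
    stop("malformed SAM line ", body_idx[j], ": non-numeric FLAG or POS")
  }
  seqf <- fld(10L)
  rlen <- ifelse(seqf != "*", nchar(seqf), NA_integer_)
  no_seq <- which(seqf == "*")
  if (length(no_seq)) {
    cig <- fld(6L)
    rlen[no_seq] <- vapply(cig[no_seq], .cigarReadLength, integer(1L),
                           USE.NAMES = FALSE)
  }
  tagInt <- function(tag) {
    m <- regexpr(paste0("\t", tag, ":i:-?[0-9]+"), body)
    out <- rep(NA_integer_, n_rec)
    hit <- m > 0L
    out[hit] <- as.integer(substring(body[hit], m[hit] + nchar(tag) + 4L,
                                     m[hit] + attr(m, "match.length")[hit] - 1L))
    out
  }
  nm <- tagInt("NM")
  nh <- tagInt("NH")
  xm <- !is.na(tagInt("XM"))

  aligned <- bitwAnd(flag, 4L) == 0L
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  ids <- unique(qname)

  known_len <- rlen[!is.na(rlen)]
  if (length(unique(known_len)) > 1L) {
    warning("mixed read lengths in SAM input; lengths recorded per read")
    read_length <- NA_integer_
  } else {
    read_length <- if (length(known_len)) unique(known_len) else NA_integer_
  }

  use <- aligned & primary
  cnt_by_read <- table(factor(qname[use], levels = ids))
  status <- character(length(ids))
  if (policy == "record-count") {
    status[cnt_by_read == 0L] <- "unmapped"
    status[cnt_by_read == 1L] <- "unique"
    status[cnt_by_read > 1L] <- "multi"
  } else {
    nh_by_read <- rep(NA_integer_, length(ids))
    first_use <- use & !duplicated(qname)
    nh_by_read[match(qname[first_use], ids)] <- nh[first_use]
    status[cnt_by_read == 0L] <- "unmapped"
    status[cnt_by_read >= 1L & !is.na(nh_by_read) & nh_by_read > 1L] <- "multi"
    status[cnt_by_read >= 1L & (is.na(nh_by_read) | nh_by_read == 1L) &
             cnt_by_read == 1L] <- "unique"
    status[status == ""] <- "multi"
  }
  # flag-4 records with the suppressed-multiplicity tag
  sup <- qname[!aligned & xm]
  status[ids %in% sup & status == "unmapped"] <- "multi"

  uq <- ids[status == "unique"]
  # index of the single primary aligned record per unique read
  idx <- match(uq, qname[use])
  rows <- which(use)[idx]
  hits <- DataFrame(read_id = uq,
                    scaffold = rname[rows],
                    pos0 = pos[rows] - 1L,
                    strand = ifelse(bitwAnd(flag[rows], 16L) > 0L, "-", "+"),
                    mismatches = nm[rows])
  if (length(sl) == 0L && nrow(hits)) {
    rl_for <- if (is.na(read_length)) 0L else read_length
    sl <- vapply(split(hits$pos0 + rl_for, hits$scaffold), max, numeric(1L))
    sl <- setNames(as.integer(sl), names(sl))
  }
  status_df <- DataFrame(read_id = ids,
                         status = factor(status,
                                         levels = c("unique", "multi",
                                                    "unmapped")))
  if (is.na(read_length) && n_rec)
    status_df$length <- rlen[match(ids, qname)]
  .newHitTable(hits, status_df, sl, read_length,
               v = NA_integer_, m = 1L)
}
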