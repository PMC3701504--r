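#' @importFrom Biostrings DNAString matchPattern neditStartingAt PDict
#'   vcountPDict
#' @useDynLib armAnchor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.asGenomeSeqs <- function(genome) {
  if (is(genome, "GenomeModel")) return(scaffoldSeqs(genome))
  if (is(genome, "DNAStringSet")) return(genome)
  if (isSingleString(genome)) return(readDNAStringSet(genome))
  stop("genome must be a GenomeModel, DNAStringSet or FASTA path")
}

.asReadSet <- function(reads) {
  if (is(reads, "SimulatedReads")) return(readSet(reads))
  if (is(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    return(readDNAStringSet(reads, format = "fastq"))
  if (is.character(reads)) return(DNAStringSet(reads))
  stop("reads must be a SimulatedReads, DNAStringSet, FASTQ path or character vector")
}

.checkReadAlphabet <- function(read) {
  if (grepl("[^ACGTNacgtn]", read))
    stop("read contains characters other than A/C/G/T/N")
}

#' Exhaustively enumerate Hamming alignments of one read
#'
#' Brute-force reference implementation of the mapping contract: tests
#' every position of every scaffold on both strands and returns all
#' locations where the read (or its reverse complement) matches with at
#' most `v` mismatches, counted as Hamming distance with no indels.
#' Intended as the independent oracle for [mapReads()] at small scale
#' (total genome around a megabase or less); it scans the full genome
#' per read. Positions are 0-based leftmost coordinates on the forward
#' strand for both orientations.
#'
#' @param read a single read as character or `DNAString` (A/C/G/T/N
#'   only).
#' @param genome a [GenomeModel], `DNAStringSet` or FASTA path.
#' @param v maximum number of mismatches (default 2).
#' @return a `DataFrame` with columns `scaffold`, `pos0`, `strand`,
#'   `mismatches`, one row per alignment, ordered by scaffold then
#'   position.
#' @seealso [uniqueFilter()], [mapReads()]
#' @export
enumerateAlignments <- function(read, genome, v = 2L) {
  read <- as.character(read)
  stopifnot(length(read) == 1L)
  .checkReadAlphabet(read)
  seqs <- .asGenomeSeqs(genome)
  pats <- list("+" = DNAString(read),
               "-" = reverseComplement(DNAString(read)))
  out <- list()
  for (s in seq_along(seqs)) {
    subject <- seqs[[s]]
    for (st in names(pats)) {
      m <- matchPattern(pats[[st]], subject, max.mismatch = v,
                        with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0L) next
      starts <- start(m)
      mm <- neditStartingAt(pats[[st]], subject, starting.at = starts,
                            with.indels = FALSE, fixed = TRUE)
      out[[length(out) + 1L]] <- DataFrame(
        scaffold = rep(names(seqs)[s], length(starts)),
        pos0 = starts - 1L,
        strand = rep(st, length(starts)),
        mismatches = as.integer(mm))
    }
  }
  if (length(out) == 0L)
    return(DataFrame(scaffold = character(), pos0 = integer(),
                     strand = character(), mismatches = integer()))
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$pos0, res$strand), , drop = FALSE]
}

#' Multiplicity-based uniqueness filter
#'
#' Implements the aligner's `-m` semantics on the alignments of a single
#' read: if the read has more than `m` alignments within the mismatch
#' budget it is suppressed entirely -- multiplicity, not relative
#' mismatch count, decides, so a read with one perfect and one
#' two-mismatch location is discarded just the same. With the default
#' `m = 1` the result is the "unique hits" set: zero or one alignment
#' per read.
#'
#' @param hits `DataFrame` of alignments of one read, as returned by
#'   [enumerateAlignments()].
#' @param m maximum reportable multiplicity (default 1).
#' @return the input rows if at most `m` of them exist, otherwise an
#'   empty `DataFrame` (read suppressed).
#' @export
uniqueFilter <- function(hits, m = 1L) {
  if (nrow(hits) > m) hits[0L, , drop = FALSE] else hits
}

#' Map reads with the uniqueness filter (built-in mapper)
#'
#' End-to-end equivalent of [enumerateAlignments()] followed by
#' [uniqueFilter()] for every read, implemented with a pigeonhole seed
#' index so the default synthetic scale (hundreds of thousands of reads
#' against a ~10 Mb genome) runs in seconds: the read is split into
#' `v + 1` disjoint segments, at least one of which must match exactly
#' under at most `v` mismatches, so candidate locations come from exact
#' k-mer lookups and are verified in full. Any base compared against N
#' counts as a mismatch. Reads with more than `m` alignments are
#' suppressed (counted in `suppressed_multi`); only `m = 1` is supported
#' here, matching the hit-table contract of at most one alignment per
#' read.
#'
#' @param reads a `DNAStringSet`, [SimulatedReads], FASTQ path or
#'   character vector; all reads must share one length.
#' @param genome a [GenomeModel], `DNAStringSet` or FASTA path.
#' @param v maximum mismatches per alignment (default 2; for 80 bp reads
#'   this is the 97.5% identity filter).
#' @param m maximum reportable multiplicity (must be 1).
#' @return a [UniqueHitTable].
#' @examples
#' genome <- DNAStringSet(c(chr = paste(
#'   sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")))
#' reads <- DNAStringSet(substring(as.character(genome), c(1, 101), c(40, 140)))
#' mapReads(reads, genome, v = 0)
#' @export
mapReads <- function(reads, genome, v = 2L, m = 1L) {
  if (m != 1L)
    stop("the built-in mapper supports m = 1 only (one retained hit per read)")
  rset <- .asReadSet(reads)
  seqs <- .asGenomeSeqs(genome)
  if (length(rset) == 0L) stop("no reads supplied")
  wd <- unique(width(rset))
  if (length(wd) != 1L)
    stop("reads must all have the same length; found lengths ",
         paste(wd, collapse = ", "))
  if (wd > max(width(seqs)))
    stop("reads are longer than every scaffold")
  res <- cpp_map_reads(as.character(seqs), as.character(rset),
                       as.integer(v), as.integer(wd))
  ids <- names(rset)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(rset))
  if (anyDuplicated(ids)) {
    warning("duplicated read ids; making them unique")
    ids <- make.unique(ids)
  }
  status <- factor(c("unmapped", "unique", "multi")[res$status + 1L],
                   levels = c("unique", "multi", "unmapped"))
  keep <- res$status == 1L
  hits <- DataFrame(
    read_id = ids[keep],
    scaffold = names(seqs)[res$scaffold[keep]],
    pos0 = res$pos0[keep],
    strand = c("+", "-")[res$strand[keep]],
    mismatches = res$mismatches[keep])
  .newHitTable(hits, DataFrame(read_id = ids, status = status),
               setNames(width(seqs), names(seqs)), wd, v = v, m = m)
}

.newHitTable <- function(hits, status, scaffold_lengths, read_length,
                         v, m) {
  tab <- table(status$status)
  counters <- c(
    total_reads = nrow(status),
    mapped_any = as.integer(tab["unique"] + tab["multi"]),
    mapped_unique = as.integer(tab["unique"]),
    suppressed_multi = as.integer(tab["multi"]),
    unmapped = as.integer(tab["unmapped"]))
  new("UniqueHitTable", hits = hits, status = status,
      counters = counters,
      scaffold_lengths = setNames(as.integer(scaffold_lengths),
                                  names(scaffold_lengths)),
      read_length = as.integer(read_length),
      params = list(v = as.integer(v), m = as.integer(m)))
}

#' Screen unmapped reads for primer contamination
#'
#' A read is primer-positive if it contains, as an exact substring, any
#' stretch of at least `min_match_len` nt of any primer or of its
#' reverse complement. Detection enumerates every `min_match_len`-mer of
#' the primers (both orientations) and matches the set against the reads
#' in one pass.
#'
#' @param unmapped_reads reads to screen: `DNAStringSet`, character
#'   vector or FASTQ path.
#' @param primers primer sequences: `DNAStringSet` or FASTA path;
#'   defaults to [defaultPrimers()].
#' @param min_match_len minimum exact match length in nt (default 11;
#'   must be at least 8 for the k-mer screen to be meaningful).
#' @return a list with elements `n_unmapped`, `n_primer_positive`,
#'   `min_match_len`, `per_primer` (named integer vector of
#'   positive-read counts per primer) and `positive` (logical vector,
#'   one entry per read).
#' @export
screenPrimers <- function(unmapped_reads, primers = defaultPrimers(),
                          min_match_len = 11L) {
  if (min_match_len < 8L)
    stop("min_match_len must be >= 8")
  if (is.character(primers) && length(primers) == 1L && file.exists(primers))
    primers <- readDNAStringSet(primers)
  if (!is(primers, "DNAStringSet")) primers <- DNAStringSet(primers)
  if (length(primers) == 0L) stop("primer set is empty")
  if (any(width(primers) < min_match_len))
    stop("all primers must be at least min_match_len long")
  reads <- .asReadSet(unmapped_reads)
  if (is.null(names(primers)))
    names(primers) <- sprintf("primer_%d", seq_along(primers))

  kmerise <- function(s) {
    n <- nchar(s) - min_match_len + 1L
    substring(s, seq_len(n), seq_len(n) + min_match_len - 1L)
  }
  km <- lapply(seq_along(primers), function(i) {
    p <- as.character(primers[[i]])
    unique(c(kmerise(p),
             kmerise(as.character(reverseComplement(primers[[i]])))))
  })
  all_km <- unlist(km)
  owner <- rep(names(primers), lengths(km))
  dedup <- !duplicated(all_km)
  pd <- PDict(DNAStringSet(all_km[dedup]))
  cnt <- vcountPDict(pd, reads)  # patterns x reads
  hit_any <- colSums(cnt) > 0L

  per_primer <- vapply(names(primers), function(nm) {
    rows <- which(owner[dedup] == nm |
                    all_km[dedup] %in% all_km[owner == nm])
    sum(colSums(cnt[rows, , drop = FALSE]) > 0L)
  }, integer(1L))

  list(n_unmapped = length(reads),
       n_primer_positive = sum(hit_any),
       min_match_len = as.integer(min_match_len),
       per_primer = per_primer,
       positive = as.logical(hit_any))
}
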