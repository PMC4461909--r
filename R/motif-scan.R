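#' Scan a sequence for matches to a degenerate motif
#'
#' Exact full-length matching of an IUPAC consensus against a nucleotide
#' sequence.  Every position where a concrete expansion of the pattern
#' matches is reported, including overlapping matches.  Ambiguity codes in
#' the *subject* (e.g. `N` in masked regions) never match any pattern
#' position.
#'
#' @param seq A single sequence: character string, [Biostrings::DNAString],
#'   or one-element `DNAStringSet`.  Case-insensitive; `U` is read as `T`.
#' @param pattern A [degenerate_pattern] or IUPAC string.
#' @param strand_mode `"forward"` (default; appropriate for CDS/transcript
#'   scans) or `"both"`.  Reverse-strand hits carry coordinates on the
#'   forward sequence and report the matched word as read on the minus
#'   strand.
#' @param seq_id Identifier recorded in the hit table.
#' @return A data frame of hits sorted by `start`: `seq_id`, `start`
#'   (0-based), `end` (0-based half-open), `word`, `pattern_id`, `strand`.
#' @examples
#' scan_sequence("CAAGACAAGG", "CAAGR")  # hits at starts 0 and 5
#' @export
scan_sequence <- function(seq, pattern, strand_mode = c("forward", "both"),
                          seq_id = "seq") {
  strand_mode <- match.arg(strand_mode)
  pattern <- degenerate_pattern(pattern)
  if (is(seq, "XStringSet")) {
    stopifnot(length(seq) == 1L)
    if (!is.null(names(seq)) && missing(seq_id)) seq_id <- names(seq)[1]
    seq <- seq[[1]]
  }
  seq <- .normalize_seq(seq)
  m <- pattern$length
  pbits <- pattern_bits(pattern)
  empty <- data.frame(
    seq_id = character(), start = integer(), end = integer(),
    word = character(), pattern_id = character(), strand = character(),
    stringsAsFactors = FALSE
  )
  L <- nchar(seq)
  if (L < m) return(empty)

  hit_df <- function(s, starts, strand) {
    if (!length(starts)) return(empty)
    data.frame(
      seq_id = seq_id, start = starts, end = starts + m,
      word = toupper(substring(s, starts + 1L, starts + m)),
      pattern_id = pattern$pattern_id, strand = strand,
      stringsAsFactors = FALSE
    )
  }

  fwd <- hit_df(seq, cpp_scan_bits(seq_bits(seq), pbits), "+")
  if (strand_mode == "both") {
    rc <- reverse_complement(seq)
    starts_rc <- cpp_scan_bits(seq_bits(rc), pbits)
    rev <- hit_df(rc, starts_rc, "-")
    if (nrow(rev)) {
      # map minus-strand coordinates back onto the forward sequence
      rev$start <- L - (starts_rc + m)
      rev$end <- rev$start + m
    }
    fwd <- rbind(fwd, rev)
  }
  fwd <- fwd[order(fwd$start, fwd$strand), , drop = FALSE]
  rownames(fwd) <- NULL
  fwd
}

#' Densest fixed-width window over a set of motif hits
#'
#' Finds the length-`w` window fully containing the most hits, sliding by
#' 1 nt over every start position.  A hit belongs to a window iff its whole
#' span lies inside; overlapping hits each count once.  Ties are broken
#' toward the smallest window start.
#'
#' @param hits Hit table from [scan_sequence()] (one sequence).
#' @param w Window length in nt; must be at least the hit (pattern) length.
#' @param seq_len Length of the scanned sequence.
#' @return A `window_cluster`: list with `window_start` (0-based),
#'   `window_len`, `count`, and `hit_indices` (rows of `hits` inside the
#'   best window).
#' @export
max_window_count <- function(hits, w, seq_len) {
  stopifnot(w >= 1L, seq_len >= 0L)
  if (nrow(hits)) {
    if (any(hits$end - hits$start > w)) {
      stop("window length w is smaller than the pattern length")
    }
    if (is.unsorted(hits$start)) hits <- hits[order(hits$start), , drop = FALSE]
  }
  max_start <- max(0L, seq_len - as.integer(w))
  best <- list(window_start = 0L, window_len = as.integer(w),
               count = 0L, hit_indices = integer(0))
  class(best) <- "window_cluster"
  if (!nrow(hits)) return(best)
  # a hit (start, end) fits windows starting in [end - w, start]
  lo <- pmax(0L, hits$end - as.integer(w))
  hi <- pmin(hits$start, max_start)
  keep <- lo <= hi
  if (!any(keep)) return(best)
  # max coverage is first attained at 0 or at some interval left edge
  cand <- sort(unique(c(0L, lo[keep])))
  counts <- vapply(cand, function(s) sum(lo <= s & s <= hi), integer(1))
  s <- cand[which.max(counts)]
  best$window_start <- s
  best$count <- max(counts)
  best$hit_indices <- which(hits$start >= s & hits$end <= s + w)
  best
}

#' @export
print.window_cluster <- function(x, ...) {
  cat(sprintf("window_cluster: %d hit(s) in [%d, %d)\n",
              x$count, x$window_start, x$window_start + x$window_len))
  invisible(x)
}

#' Screen a transcriptome for windowed motif clusters
#'
#' Scans every sequence for a degenerate motif and retains those carrying at
#' least `k` copies inside some window of `w` nt (the enrichment criterion
#' used to judge TRA/TRA2-like and RBP1-like cluster significance; the
#' classical settings are 6 copies in 224 bp for the TRA/TRA2 consensus and
#' 8 copies in 546 bp for the RBP1 type-B consensus).
#'
#' @param x Multi-FASTA path or a [Biostrings::DNAStringSet].
#' @param pattern A [degenerate_pattern] or IUPAC string.
#' @param k Minimum copies in a window for retention.
#' @param w Window length (nt).
#' @param strand_mode Passed to [scan_sequence()].
#' @return Data frame with one row per sequence: `seq_id`, `total_hits`,
#'   `best_window_start` (0-based), `best_window_count`, `retained`.
#'   The per-sequence hit tables are attached as attribute `"hits"`.
#' @export
screen_transcripts <- function(x, pattern, k = 6L, w = 224L,
                               strand_mode = "forward") {
  stopifnot(k >= 1L)
  pattern <- degenerate_pattern(pattern)
  if (w < pattern$length) stop("window length w must be >= pattern length")
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    read_fasta(x)
  } else if (is(x, "DNAStringSet")) {
    x
  } else {
    stop("x must be a FASTA path or a DNAStringSet")
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  all_hits <- vector("list", length(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    hits <- scan_sequence(s, pattern, strand_mode = strand_mode, seq_id = ids[i])
    all_hits[[i]] <<- hits
    bw <- max_window_count(hits, w, nchar(s))
    data.frame(
      seq_id = ids[i], total_hits = nrow(hits),
      best_window_start = bw$window_start, best_window_count = bw$count,
      retained = bw$count >= k, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(all_hits) <- ids
  attr(out, "hits") <- all_hits
  out
}

#' Write motif hits as BED6
#'
#' Standard BED coordinates (0-based half-open); the score column carries the
#' number of mismatches to the consensus, which is always 0 for exact
#' degenerate matching.
#'
#' @param hits Hit table from [scan_sequence()] (any number of sequences,
#'   row-bound).
#' @param path Output file.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(
    chrom = hits$seq_id, start = hits$start, end = hits$end,
    name = hits$pattern_id, score = 0L, strand = hits$strand,
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a transcriptome screen summary as TSV
#'
#' Human-facing report; `best_window_start` is converted to 1-based.
#'
#' @param screen Result of [screen_transcripts()].
#' @param path Output file.
#' @export
write_screen_tsv <- function(screen, path) {
  out <- screen
  out$best_window_start <- out$best_window_start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
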