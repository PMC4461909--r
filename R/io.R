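#' Read a multi-FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] with friendlier error
#' context; an empty file yields an empty set with a warning rather than an
#' error.  CRLF line endings parse identically to LF.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet]; names are the record ids (first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  res <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      lines <- tryCatch(readLines(path, warn = FALSE), error = function(e2) character())
      if (!any(nzchar(trimws(lines)))) {
        warning("empty FASTA file: ", path)
        return(Biostrings::DNAStringSet())
      }
      stop("malformed FASTA '", path, "': ", conditionMessage(e))
    }
  )
  if (length(res)) {
    names(res) <- sub("\\s.*$", "", names(res))
  } else {
    warning("empty FASTA file: ", path)
  }
  res
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`28.25 -> 28.3`), matching how
#' percentages are conventionally printed; base R's `round()` rounds ties
#' to even.
#'
#' @param x Numeric vector (non-negative use case).
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Per-junction splice-usage percentages
#'
#' Converts junction-read (or amplicon) counts into percentages per
#' junction, e.g. the share of reads using an alternate-donor extension
#' versus the canonical donor.  Percentages are reported to 1 decimal,
#' half-up, and sum to 100 within rounding.
#'
#' @param table Data frame with columns `junction`, `class` (e.g.
#'   `"extension"` / `"canonical"`) and `count` (`>= 0`); an optional
#'   `library_id` column subdivides junctions by library.
#' @return The input with added `total` and `percent` columns.
#' @examples
#' splice_usage(data.frame(junction = "e4-e5",
#'                         class = c("extension", "canonical"),
#'                         count = c(47, 119)))
#' @export
splice_usage <- function(table) {
  stopifnot(all(c("junction", "class", "count") %in% names(table)),
            all(table$count >= 0))
  key <- if ("library_id" %in% names(table)) {
    paste(table$library_id, table$junction, sep = "\r")
  } else {
    table$junction
  }
  totals <- tapply(table$count, key, sum)
  if (any(totals == 0)) stop("zero total count for junction(s): ",
                             paste(names(totals)[totals == 0], collapse = ", "))
  table$total <- as.vector(totals[key])
  table$percent <- round_half_up(100 * table$count / table$total, 1)
  table
}

#' Write and re-read a TSV table
#'
#' Plain-text table I/O used by all report writers; round-trips unchanged.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` the data frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
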