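## IUPAC nucleotide ambiguity classes and bitmask encodings.
##
## Bases are encoded as bits (A=1, C=2, G=4, T=8); a degenerate symbol is the
## OR of its class, and a pattern position matches a subject base iff the two
## masks intersect.  Subject ambiguity codes (N etc.) are encoded as 0 so that
## they never match any pattern position: masked regions cannot seed spurious
## clusters.

IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.iupac_bits <- vapply(IUPAC_CLASSES, function(b) sum(.base_bit[b]), integer(1))

# subject-side encoding: concrete bases only, everything else is 0 (no match)
.subject_bits <- c(
  A = 1L, a = 1L, C = 2L, c = 2L, G = 4L, g = 4L,
  T = 8L, t = 8L, U = 8L, u = 8L
)

.normalize_seq <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  chartr("Uu", "Tt", x)
}

seq_bits <- function(seq) {
  chars <- strsplit(.normalize_seq(seq), "", fixed = TRUE)[[1]]
  b <- unname(.subject_bits[chars])
  b[is.na(b)] <- 0L
  b
}

#' Define a degenerate (IUPAC) sequence pattern
#'
#' A `degenerate_pattern` is an ordered IUPAC consensus such as the TRA/TRA2
#' binding site `NMDNCRWNCWAYM`; each position names a class of bases and the
#' pattern's *degeneracy* is the product of the per-position class sizes.
#'
#' @param pattern A single string of IUPAC codes
#'   (`A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`; `U` is treated as `T`,
#'   case-insensitive).
#' @param pattern_id Short label used in hit tables; defaults to the pattern
#'   string itself.
#' @return An object of class `degenerate_pattern` with elements
#'   `pattern_id`, `symbols`, `length` and `degeneracy`.
#' @examples
#' p <- degenerate_pattern("CAAGR")
#' p$degeneracy  # 2
#' @export
degenerate_pattern <- function(pattern, pattern_id = pattern) {
  if (inherits(pattern, "degenerate_pattern")) return(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(chartr("Uu", "Tt", pattern))
  if (nchar(pattern) < 1L) stop("pattern must have length >= 1")
  symbols <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(symbols, names(IUPAC_CLASSES))
  if (length(bad)) {
    stop("invalid IUPAC symbol(s) in pattern: ", paste(unique(bad), collapse = ", "))
  }
  structure(
    list(
      pattern_id = as.character(pattern_id),
      symbols = symbols,
      length = length(symbols),
      degeneracy = prod(lengths(IUPAC_CLASSES[symbols]))
    ),
    class = "degenerate_pattern"
  )
}

#' @export
print.degenerate_pattern <- function(x, ...) {
  cat(sprintf(
    "degenerate_pattern '%s': %s (%d nt, %d concrete words)\n",
    x$pattern_id, paste(x$symbols, collapse = ""), x$length, x$degeneracy
  ))
  invisible(x)
}

pattern_bits <- function(pattern) {
  pattern <- degenerate_pattern(pattern)
  unname(.iupac_bits[pattern$symbols])
}

#' Expand a degenerate pattern into its concrete words
#'
#' Enumerates every ACGT word matching the consensus ("broken down into all
#' possible constituents").  The number of words equals the pattern's
#' degeneracy.
#'
#' @inheritParams degenerate_pattern
#' @return Character vector of distinct ACGT words, sorted.
#' @examples
#' expand_pattern("CAAGR")             # CAAGA, CAAGG
#' length(expand_pattern("NGAAGAWN"))  # 32
#' @export
expand_pattern <- function(pattern) {
  pattern <- degenerate_pattern(pattern)
  grid <- expand.grid(IUPAC_CLASSES[pattern$symbols],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(do.call(paste0, grid))
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(.normalize_seq(seq))))
}
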