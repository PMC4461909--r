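# Independent oracles kept deliberately naive: regex-over-expansions
# scanning, exhaustive window evaluation, and full sequence enumeration for
# the occurrence-count null.  They share no code path with the package
# kernels they check.

# overlapping exact matches via perl lookahead over the expansion set
naive_scan_starts <- function(seq, pattern) {
  words <- expand_pattern(pattern)
  rx <- paste0("(?=(", paste(words, collapse = "|"), "))")
  m <- gregexpr(rx, toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# exhaustive evaluation of every window start
brute_window <- function(hits, w, seq_len) {
  best_count <- 0L; best_start <- 0L
  for (s in 0:max(0L, seq_len - w)) {
    cnt <- sum(hits$start >= s & hits$end <= s + w)
    if (cnt > best_count) { best_count <- cnt; best_start <- s }
  }
  list(window_start = best_start, count = best_count)
}

# exact occurrence distribution by enumerating all 4^L sequences
enum_distribution <- function(pattern, L, background = background_model()) {
  pat <- degenerate_pattern(pattern)
  m <- pat$length
  bases <- c("A", "C", "G", "T")
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  freq <- as.numeric(background)
  logp <- matrix(log(freq)[grid], nrow = nrow(grid))
  pseq <- exp(rowSums(logp))
  allowed <- lapply(pat$symbols,
                    function(s) bases %in% cisplice:::IUPAC_CLASSES[[s]])
  cnt <- rep(0L, nrow(grid))
  if (L >= m) {
    for (i in 1:(L - m + 1)) {
      ok <- rep(TRUE, nrow(grid))
      for (j in 1:m) ok <- ok & allowed[[j]][grid[, i + j - 1]]
      cnt <- cnt + ok
    }
  }
  tapply(pseq, factor(cnt, levels = 0:max(cnt)), sum, default = 0)
}

random_pattern <- function(len, max_degeneracy = 64) {
  syms <- names(cisplice:::IUPAC_CLASSES)
  repeat {
    p <- paste(sample(syms, len, replace = TRUE), collapse = "")
    if (degenerate_pattern(p)$degeneracy <= max_degeneracy) return(p)
  }
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
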