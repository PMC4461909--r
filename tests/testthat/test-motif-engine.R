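test_that("pattern expansion enumerates exactly the degeneracy", {
  expect_setequal(expand_pattern("CAAGR"), c("CAAGA", "CAAGG"))
  expect_length(expand_pattern("NGAAGAWN"), 32L)
  p <- degenerate_pattern("NMDNCRWNCWAYM")
  expect_identical(p$degeneracy, 12288)
  words <- expand_pattern(p)
  expect_length(words, 12288L)
  expect_length(unique(words), 12288L)
  # every word matches the pattern position-wise
  sub <- sample(words, 50)
  expect_true(all(vapply(sub, function(w) {
    nrow(scan_sequence(w, p)) == 1L
  }, logical(1))))
  expect_error(degenerate_pattern("ACGX"), "invalid IUPAC")
  expect_error(degenerate_pattern(""), "length")
})

test_that("scanning reports all overlapping matches with exact coordinates", {
  hits <- scan_sequence("CAAGACAAGG", "CAAGR")
  expect_identical(hits$start, c(0L, 5L))
  expect_identical(hits$word, c("CAAGA", "CAAGG"))
  hits <- scan_sequence("ATCTGGA", "ATCYNNA")
  expect_identical(hits$start, 0L)
  expect_identical(nrow(scan_sequence("", "CAAGR")), 0L)
  # case-insensitive, U as T
  expect_identical(nrow(scan_sequence("caagu", "CAAGR")), 0L)
  expect_identical(nrow(scan_sequence("caaga", "CAAGR")), 1L)
  # subject ambiguity codes never match
  expect_identical(nrow(scan_sequence("CANGA", "CAAGR")), 0L)
  expect_identical(nrow(scan_sequence("NNNNN", "NNNNN")), 0L)
})

test_that("scanning equals regex-over-expansions on random sequences", {
  set.seed(101)
  for (i in 1:1000) {
    pat <- random_pattern(sample(3:8, 1))
    seq <- random_dna(sample(10:60, 1))
    expect_identical(scan_sequence(seq, pat)$start, naive_scan_starts(seq, pat),
                     info = paste(pat, seq))
  }
})

test_that("reverse-strand hits are forward scans of the reverse complement", {
  set.seed(7)
  for (i in 1:50) {
    pat <- random_pattern(5)
    seq <- random_dna(80)
    both <- scan_sequence(seq, pat, strand_mode = "both")
    rev_hits <- both[both$strand == "-", ]
    rc <- cisplice:::reverse_complement(seq)
    expected <- naive_scan_starts(rc, pat)
    expect_setequal(80L - (rev_hits$start + 5L), expected)
  }
  # forward hits unchanged by strand mode
  seq <- "CAAGACAAGG"
  fwd <- scan_sequence(seq, "CAAGR")
  both <- scan_sequence(seq, "CAAGR", strand_mode = "both")
  expect_identical(both[both$strand == "+", ]$start, fwd$start)
})

test_that("max_window_count finds the densest window (vs exhaustive search)", {
  mk_hits <- function(starts, len = 5L) {
    n <- length(starts)
    data.frame(seq_id = rep("s", n), start = starts, end = starts + len,
               word = rep("x", n), pattern_id = rep("p", n),
               strand = rep("+", n))
  }
  bw <- max_window_count(mk_hits(c(0L, 50L, 100L)), w = 120, seq_len = 200)
  expect_identical(bw$count, 3L)
  expect_identical(bw$window_start, 0L)
  # overlapping hits each count once
  bw <- max_window_count(mk_hits(c(10L, 12L)), w = 224, seq_len = 500)
  expect_identical(bw$count, 2L)
  expect_error(max_window_count(mk_hits(0L, len = 10L), w = 5, seq_len = 100),
               "pattern length")
  # randomized agreement with brute force, and monotonicity in w
  set.seed(33)
  for (i in 1:100) {
    seq_len <- 300L
    starts <- sort(sample(0:(seq_len - 6L), sample(0:12, 1)))
    hits <- mk_hits(starts, len = 6L)
    prev <- 0L
    for (w in c(10L, 40L, 120L, 300L)) {
      got <- max_window_count(hits, w, seq_len)
      ref <- brute_window(hits, w, seq_len)
      expect_identical(got$count, ref$count)
      expect_identical(got$window_start, ref$window_start)
      expect_identical(length(got$hit_indices), got$count)
      expect_gte(got$count, prev)
      prev <- got$count
    }
  }
})

test_that("transcriptome screening retains exactly the cluster-bearing sequences", {
  set.seed(11)
  ss <- gen_screen_set(n_background = 30, length = 1500,
                       pattern = "NMDNCRWNCWAYM", k = 6, w = 224)
  sc <- screen_transcripts(ss$seqs, "NMDNCRWNCWAYM", k = 6, w = 224)
  expect_identical(sc$seq_id[sc$retained], "planted")
  expect_gte(sc$best_window_count[sc$seq_id == "planted"], 6L)
  expect_identical(sc$retained, sc$best_window_count >= 6L)
  # k = 1, w = pattern length: retained iff any hit
  sc1 <- screen_transcripts(ss$seqs, "NMDNCRWNCWAYM", k = 1, w = 13)
  expect_identical(sc1$retained, sc1$total_hits >= 1L)
  expect_error(screen_transcripts(ss$seqs, "NMDNCRWNCWAYM", k = 6, w = 5),
               "pattern length")
})

test_that("screen summary and BED outputs round-trip with 1-based/0-based conventions", {
  seqs <- Biostrings::DNAStringSet(c(a = "CAAGACAAGG", b = "GGGGGGGGGG"))
  sc <- screen_transcripts(seqs, "CAAGR", k = 1, w = 5)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_screen_tsv(sc, tsv)
  back <- read_tsv(tsv)
  expect_identical(back$best_window_start, sc$best_window_start + 1L)
  hits <- do.call(rbind, attr(sc, "hits"))
  write_hits_bed(hits, bed)
  bed_tab <- read.delim(bed, header = FALSE)
  expect_identical(bed_tab$V2, hits$start)  # BED stays 0-based
  expect_identical(bed_tab$V3, hits$end)
})
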