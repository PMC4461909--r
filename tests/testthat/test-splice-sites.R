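test_that("pyrimidine counting follows the tract exactly", {
  expect_identical(pyrimidine_count("ctttttcccgtt"), 11L)
  expect_identical(pyrimidine_count("ccaaccaacaaa"), 5L)
  expect_identical(pyrimidine_count("AAAAAAAAAAAA"), 0L)
  expect_identical(pyrimidine_count("CCCCCCCCCCCC"), 12L)
  # ambiguity codes count as neither pyrimidine nor purine
  expect_identical(pyrimidine_count("NNNNNNNNNNNN"), 0L)
  expect_error(pyrimidine_count("ACGT"), "12 nt")
  # purine + pyrimidine = 12 on unambiguous tracts
  set.seed(2)
  for (i in 1:20) {
    tr <- random_dna(12)
    pur <- sum(strsplit(tr, "")[[1]] %in% c("A", "G"))
    expect_identical(pyrimidine_count(tr) + pur, 12L)
  }
})

test_that("acceptor population statistics are plain mean/SD/SE", {
  st <- acceptor_stats(c(11, 12, 8, 10, 10, 10, 5, 9))
  expect_equal(st$mean, 9.375)
  expect_equal(st$sd, sd(c(11, 12, 8, 10, 10, 10, 5, 9)))
  expect_equal(st$se, st$sd / sqrt(8))
  expect_equal(acceptor_stats(c(7, 7, 7))$sd, 0)
  expect_error(acceptor_stats(numeric(0)), "at least 2")
  expect_error(acceptor_stats(5), "at least 2")
})

test_that("weak-acceptor calls are one-sided on the pyrimidine-poor side", {
  ref <- cxq_acceptor_reference()
  low <- flag_weak_acceptor(5, ref)
  expect_equal(low$z, (5 - 8.58) / 1.39, tolerance = 1e-12)
  expect_true(low$weak)
  at_mean <- flag_weak_acceptor(8.58, list(mean = 8.58, sd = 1.39))
  expect_equal(at_mean$z, 0)
  expect_false(at_mean$weak)
  # pyrimidine-rich outlier is strong, not weak
  hi <- flag_weak_acceptor(12, ref)
  expect_gt(hi$z, 2)
  expect_false(hi$weak)
  expect_error(flag_weak_acceptor(5, list(mean = 8, sd = 0)), "sd")
})

test_that("contexts extract exactly from a toy plus-strand gene and its minus-strand encoding", {
  # two-exon gene whose intron ends with the published intron-1 context
  exon1 <- "ATGGCAGCAGCAGCAGCAGCA"
  exon2 <- "ATCCTTGCTTGCAGCAGGGTAA"
  intron <- paste0("GT", strrep("A", 20), "ctttttcccgtttcag")
  contig <- paste0("GGGG", exon1, toupper(intron), exon2, "CCCC")
  s1 <- 4L; e1 <- s1 + nchar(exon1)
  s2 <- e1 + nchar(intron); e2 <- s2 + nchar(exon2)
  gm <- gene_model("c1", "+", c(s1, s2), c(e1, e2), "toy")
  genome <- Biostrings::DNAStringSet(setNames(contig, "c1"))
  ctx <- extract_splice_contexts(genome, gm)
  expect_identical(nrow(ctx), 1L)
  expect_identical(ctx$tract12, "CTTTTTCCCGTT")
  expect_identical(ctx$acceptor4, "TCAG")
  expect_identical(ctx$Y, 11L)
  expect_identical(toupper(substring(ctx$donor16, 1, 2)), "GT")
  # the same locus encoded on the minus strand of the reverse complement
  L <- nchar(contig)
  rc <- cisplice:::reverse_complement(contig)
  gm_m <- gene_model("c1", "-", c(L - e2, L - e1), c(L - s2, L - s1), "toy")
  ctx_m <- extract_splice_contexts(Biostrings::DNAStringSet(setNames(rc, "c1")), gm_m)
  expect_identical(ctx_m$tract12, ctx$tract12)
  expect_identical(ctx_m$acceptor4, ctx$acceptor4)
  expect_identical(ctx_m$donor16, ctx$donor16)
  # single-exon gene: no contexts
  single <- gene_model("c1", "+", s1, e1, "single")
  expect_identical(nrow(extract_splice_contexts(genome, single)), 0L)
  # out-of-bounds exon names the gene
  bad <- gene_model("c1", "+", c(0L, 1000L), c(10L, 2000L), "oob")
  expect_error(extract_splice_contexts(genome, bad), "oob")
})

test_that("synthetic loci round-trip their per-intron pyrimidine targets on both strands", {
  y <- c(11L, 12L, 8L, 10L, 10L, 10L, 5L, 9L)
  for (strand in c("+", "-")) {
    loc <- gen_gene_locus(rep(80L, 9), rep(60L, 8), y, strand = strand, seed = 17)
    ctx <- extract_splice_contexts(loc$genome, loc$model)
    expect_identical(ctx$Y, y)
    expect_true(all(toupper(substring(ctx$donor16, 1, 2)) == "GT"))
    expect_true(all(toupper(substring(ctx$acceptor4, 3, 4)) == "AG"))
  }
  # extreme target: all-pyrimidine tract
  loc12 <- gen_gene_locus(c(50L, 50L), 40L, 12L, seed = 1)
  ctx12 <- extract_splice_contexts(loc12$genome, loc12$model)
  expect_identical(ctx12$Y, 12L)
  expect_false(grepl("[AG]", ctx12$tract12))
})

test_that("canonicality calls catch non-GT-AG junctions", {
  loc <- gen_gene_locus(c(60L, 60L, 60L), c(50L, 50L), c(9L, 9L), seed = 23)
  vc <- validate_canonical(loc$genome, loc$model)
  expect_true(all(vc$canonical))
  # corrupt the first intron donor GT -> GC
  contig <- as.character(loc$genome[[1]])
  d0 <- loc$model$exon_ends[1]
  substring(contig, d0 + 1, d0 + 2) <- "GC"
  vc2 <- validate_canonical(Biostrings::DNAStringSet(setNames(contig, "contig1")),
                            loc$model)
  expect_identical(vc2$canonical, c(FALSE, TRUE))
})

test_that("short introns are skipped with a warning", {
  contig <- paste0(strrep("A", 20), strrep("C", 10), strrep("A", 20))
  gm <- gene_model("c1", "+", c(0L, 30L), c(20L, 50L), "short")
  expect_warning(
    ctx <- extract_splice_contexts(Biostrings::DNAStringSet(setNames(contig, "c1")), gm),
    "< 30"
  )
  expect_identical(nrow(ctx), 0L)
})

test_that("gene models survive a GFF3 round trip", {
  loc <- gen_gene_locus(c(70L, 80L, 90L), c(45L, 60L), c(4L, 10L),
                        strand = "-", seed = 9)
  path <- tempfile(fileext = ".gff3")
  write_gene_models(loc$model, path)
  back <- read_gene_models(path)[[1]]
  expect_identical(back$exon_starts, loc$model$exon_starts)
  expect_identical(back$exon_ends, loc$model$exon_ends)
  expect_identical(back$strand, "-")
  ctx1 <- extract_splice_contexts(loc$genome, loc$model)
  ctx2 <- extract_splice_contexts(loc$genome, back)
  expect_identical(ctx1$Y, ctx2$Y)
})

test_that("whole-pipeline splice_strength flags the planted weak acceptor", {
  y <- c(10L, 9L, 3L, 10L, 9L, 10L, 9L, 10L)
  loc <- gen_gene_locus(rep(70L, 9), rep(50L, 8), y, seed = 31)
  out <- splice_strength(loc$genome, loc$model)
  expect_identical(which(out$weak), 3L)
  st <- attr(out, "stats")
  expect_equal(st$mean, mean(y))
})
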