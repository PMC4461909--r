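## Seeded generators for every input the pipeline consumes, with ground
## truth sufficient to score recall/precision of each stage.  All functions
## draw from R's RNG; passing `seed` fixes the stream for that call.

.maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Generate i.i.d. background sequence
#'
#' @param L Length in nt (`>= 0`).
#' @param background A [background_model] (default uniform).
#' @param seed Optional integer seed.
#' @return A character string of length `L`.
#' @export
gen_background <- function(L, background = background_model(), seed = NULL) {
  background <- background_model(background)
  stopifnot(L >= 0)
  .maybe_seed(seed)
  if (L == 0) return("")
  paste(sample(names(background), L, replace = TRUE, prob = background),
        collapse = "")
}

#' Generate a background transcriptome
#'
#' @param n Number of transcripts.
#' @param lengths Transcript length(s); recycled to `n`.
#' @inheritParams gen_background
#' @return A [Biostrings::DNAStringSet] named `tx0001 ...`.
#' @export
gen_transcriptome <- function(n, lengths = 2000L,
                              background = background_model(), seed = NULL) {
  stopifnot(n >= 1)
  .maybe_seed(seed)
  lengths <- rep_len(as.integer(lengths), n)
  seqs <- vapply(lengths, function(L) gen_background(L, background), character(1))
  Biostrings::DNAStringSet(setNames(seqs, sprintf("tx%04d", seq_len(n))))
}

#' Plant a motif cluster into a sequence
#'
#' Writes `k` concrete expansions of a degenerate pattern (sampled uniformly
#' from the expansion set) into a randomly placed window of `w` nt, at
#' non-overlapping offsets; the rest of the sequence is untouched.
#'
#' @param sequence Host sequence (string).
#' @param pattern A [degenerate_pattern] or IUPAC string.
#' @param k Number of copies to plant (`k = 0` returns the input unchanged).
#' @param w Window length; must fit in the sequence and hold `k`
#'   non-overlapping copies (`w >= k * pattern_length`).
#' @param seed Optional integer seed.
#' @return List with `sequence` (modified) and `truth`: a list holding
#'   `window_start` (0-based), `w`, and a data frame `hits` of planted
#'   `start`/`word`.
#' @export
plant_cluster <- function(sequence, pattern, k, w, seed = NULL) {
  pattern <- degenerate_pattern(pattern)
  L <- nchar(sequence)
  m <- pattern$length
  if (L < w) stop("sequence shorter than the window")
  stopifnot(k >= 0)
  truth <- list(window_start = NA_integer_, w = as.integer(w),
                hits = data.frame(start = integer(), word = character(),
                                  stringsAsFactors = FALSE))
  if (k == 0) return(list(sequence = sequence, truth = truth))
  if (w < k * m) stop("w too small to hold ", k, " non-overlapping copies")
  .maybe_seed(seed)
  window_start <- sample.int(L - w + 1L, 1L) - 1L
  slack <- sort(sample.int(w - k * m + 1L, k, replace = TRUE) - 1L)
  starts <- window_start + slack + (seq_len(k) - 1L) * m
  words <- sample(expand_pattern(pattern), k, replace = TRUE)
  for (i in seq_len(k)) {
    substring(sequence, starts[i] + 1L, starts[i] + m) <- words[i]
  }
  truth$window_start <- window_start
  truth$hits <- data.frame(start = starts, word = words, stringsAsFactors = FALSE)
  list(sequence = sequence, truth = truth)
}

#' Generate a screening set with one planted cluster
#'
#' `n_background` i.i.d. transcripts plus one host carrying a planted
#' k-in-w cluster, shuffled ids fixed: the host is always the last entry
#' named `planted`.
#'
#' @inheritParams gen_transcriptome
#' @inheritParams plant_cluster
#' @param n_background Number of background transcripts.
#' @param length Transcript length (nt).
#' @return List with `seqs` (a `DNAStringSet`), `planted_id`, `truth`.
#' @export
gen_screen_set <- function(n_background = 100L, length = 2000L,
                           pattern = "NMDNCRWNCWAYM", k = 6L, w = 224L,
                           background = background_model(), seed = NULL) {
  .maybe_seed(seed)
  seqs <- gen_transcriptome(n_background + 1L, length, background)
  host <- plant_cluster(as.character(seqs[[n_background + 1L]]), pattern, k, w)
  out <- c(as.character(seqs[seq_len(n_background)]), planted = host$sequence)
  names(out)[n_background + 1L] <- "planted"
  list(seqs = Biostrings::DNAStringSet(out), planted_id = "planted",
       truth = host$truth)
}

.random_tract12 <- function(y) {
  stopifnot(y >= 0, y <= 12)
  tract <- sample(c("A", "G"), 12L, replace = TRUE)
  if (y > 0) {
    pos <- sample.int(12L, y)
    tract[pos] <- sample(c("C", "T"), y, replace = TRUE)
  }
  paste(tract, collapse = "")
}

#' Generate a multi-exon gene locus with controlled acceptor tracts
#'
#' Builds a contig carrying one gene whose introns are canonical (begin
#' `GT`, end `AG`) and whose final 16 intronic nt realise exactly the
#' requested per-intron pyrimidine counts: a 12-nt tract with `y`
#' pyrimidines followed by a random `NNAG` acceptor 4-mer.  With
#' `strand = "-"` the contig is reverse-complemented and the exon
#' coordinates flipped, so extraction must recover identical contexts.
#'
#' @param exon_lengths Integer vector (`>= 1` exon).
#' @param intron_lengths Integer vector, one fewer than exons, all `>= 30`.
#' @param y_targets Per-intron tract pyrimidine counts in `0..12`.
#' @param strand `"+"` or `"-"`.
#' @param flank Flanking background length on each side.
#' @inheritParams gen_background
#' @param seq_id,gene_id Identifiers.
#' @return List with `genome` (1-contig `DNAStringSet`), `model`
#'   (a [gene_model]) and `truth` (list with `y`, `tracts`, `seed` inputs).
#' @export
gen_gene_locus <- function(exon_lengths, intron_lengths, y_targets,
                           strand = "+", flank = 50L,
                           background = background_model(), seed = NULL,
                           seq_id = "contig1", gene_id = "gene1") {
  n_ex <- length(exon_lengths)
  stopifnot(n_ex >= 1L,
            length(intron_lengths) == n_ex - 1L,
            length(y_targets) == n_ex - 1L,
            all(exon_lengths >= 1L))
  if (any(intron_lengths < 30L)) stop("introns must be >= 30 nt")
  if (any(y_targets < 0 | y_targets > 12)) stop("y_targets must be in 0..12")
  .maybe_seed(seed)
  tracts <- character(max(0L, n_ex - 1L))
  pieces <- character(0)
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- flank
  pieces <- c(pieces, gen_background(flank, background))
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    pieces <- c(pieces, gen_background(exon_lengths[i], background))
    pos <- pos + exon_lengths[i]
    ends[i] <- pos
    if (i < n_ex) {
      tracts[i] <- .random_tract12(y_targets[i])
      mid <- gen_background(intron_lengths[i] - 18L, background)
      acc4 <- paste0(gen_background(2L, background), "AG")
      intron <- paste0("GT", mid, tracts[i], acc4)
      pieces <- c(pieces, intron)
      pos <- pos + intron_lengths[i]
    }
  }
  pieces <- c(pieces, gen_background(flank, background))
  contig <- paste(pieces, collapse = "")
  L <- nchar(contig)
  if (strand == "-") {
    contig <- reverse_complement(contig)
    new_starts <- rev(L - ends); new_ends <- rev(L - starts)
    starts <- new_starts; ends <- new_ends
  }
  model <- gene_model(seq_id, strand, starts, ends, gene_id)
  list(
    genome = Biostrings::DNAStringSet(setNames(contig, seq_id)),
    model = model,
    truth = list(y = as.integer(y_targets), tracts = tracts, strand = strand)
  )
}

#' Generate a promoter region with a planted Inr + DPE configuration
#'
#' Background sequence with an initiator and a downstream promoter element
#' planted at the canonical spacing (DPE first base at `dpe_position` with
#' the Inr adenine as +1) and no TATA box: TATA-box matches arising by
#' chance upstream of the TSS are destroyed by resampling.
#'
#' @param L Region length.
#' @param tss Position of the Inr adenine, 0-based (must leave room for the
#'   Inr and the DPE).
#' @param inr_variant,dpe_variant Consensus variants as in [find_promoter()].
#' @param dpe_position Canonical DPE spacing (default +28).
#' @inheritParams gen_background
#' @return List with `sequence` and `truth` (`tss`, `inr_start`,
#'   `dpe_start`, 0-based).
#' @export
gen_promoter_region <- function(L = 300L, tss = 120L,
                                inr_variant = c("YYANWY", "YYANWYY"),
                                dpe_variant = c("RGWYV", "RGWYT"),
                                dpe_position = 28L,
                                background = background_model(), seed = NULL) {
  inr_variant <- match.arg(inr_variant)
  dpe_variant <- match.arg(dpe_variant)
  .maybe_seed(seed)
  tss <- as.integer(tss)
  inr_start <- tss - 2L
  dpe_start <- tss + as.integer(dpe_position) - 1L
  m_dpe <- nchar(dpe_variant)
  stopifnot(inr_start >= 0L, dpe_start + m_dpe <= L)
  seq <- gen_background(L, background)
  inr_word <- sample(expand_pattern(inr_variant), 1L)
  dpe_word <- sample(expand_pattern(dpe_variant), 1L)
  substring(seq, inr_start + 1L, inr_start + nchar(inr_word)) <- inr_word
  substring(seq, dpe_start + 1L, dpe_start + m_dpe) <- dpe_word
  # scrub chance TATA boxes so the planted configuration is TATA-less
  repeat {
    tata <- scan_sequence(seq, "TATAWAW")
    if (!nrow(tata)) break
    for (s in tata$start) {
      substring(seq, s + 1L, s + 7L) <- paste(sample(c("C", "G"), 7L, TRUE),
                                              collapse = "")
    }
  }
  list(sequence = seq,
       truth = list(tss = tss, inr_start = inr_start, dpe_start = dpe_start,
                    inr_variant = inr_variant, dpe_variant = dpe_variant))
}

.random_sense_codon <- function(background) {
  repeat {
    cod <- gen_background(3L, background)
    if (!(cod %in% .STOPS)) return(cod)
  }
}

#' Evolve a codon-sequence pair at a chosen dN/dS
#'
#' Draws an ancestor CDS from the background (stop codons rejected) and
#' derives a descendant by repeated single-nucleotide proposals: proposals
#' creating stop codons are rejected outright; for `omega <= 1` synonymous
#' proposals are accepted with probability 1 and nonsynonymous with
#' probability `omega`; for `omega > 1` the asymmetry is realised by
#' down-weighting synonymous acceptance to `1/omega`.  Substitution stops
#' once `round(subs_per_codon * n_codons)` proposals have been accepted.
#'
#' @param n_codons CDS length in codons.
#' @param omega Target dN/dS (`>= 0`).
#' @param subs_per_codon Expected accepted substitutions per codon
#'   (default 0.3).
#' @inheritParams gen_background
#' @return List with `cds_a` (ancestor), `cds_b` (descendant) and `truth`
#'   (`omega`, `n_subs`, realised `n_syn`/`n_non` accepted counts).
#' @export
evolve_codon_pair <- function(n_codons, omega, subs_per_codon = 0.3,
                              background = background_model(), seed = NULL) {
  stopifnot(n_codons >= 1, omega >= 0, subs_per_codon >= 0)
  .maybe_seed(seed)
  anc <- vapply(seq_len(n_codons), function(i) .random_sense_codon(background),
                character(1))
  target <- round(subs_per_codon * n_codons)
  if (omega <= 1) { p_syn <- 1; p_non <- omega } else { p_syn <- 1 / omega; p_non <- 1 }
  if (omega == 0 && target > 0) {
    # feasible: every sense codon reachable by syn moves? not all codons have
    # synonymous neighbours (ATG, TGG); proposals simply keep drawing.
  }
  des <- anc
  n_syn <- 0L; n_non <- 0L
  accepted <- 0L
  guard <- 0L
  max_guard <- 1000L * max(1L, target) + 10000L
  while (accepted < target) {
    guard <- guard + 1L
    if (guard > max_guard) stop("substitution target unreachable (omega too restrictive?)")
    ci <- sample.int(n_codons, 1L)
    pos <- sample.int(3L, 1L)
    ch <- strsplit(des[ci], "", fixed = TRUE)[[1]]
    ch[pos] <- sample(setdiff(.BASES, ch[pos]), 1L)
    cand <- paste(ch, collapse = "")
    if (cand %in% .STOPS) next
    syn <- .codon_aa(cand) == .codon_aa(des[ci])
    p <- if (syn) p_syn else p_non
    if (p < 1 && runif(1) >= p) next
    # at omega = 0 the pair must differ only synonymously as an endpoint
    # property: pathway-counting methods infer substitutions from the codon
    # pair, so a multi-hit codon whose minimal pathways cross another amino
    # acid (e.g. TTA->CTA->CTC, averaged with the route through Phe) would
    # leak apparent nonsynonymous divergence into a strictly neutral history
    if (omega == 0 && cand != anc[ci] &&
        .ng86_path_counts(anc[ci], cand)["nd"] > 0) next
    des[ci] <- cand
    accepted <- accepted + 1L
    if (syn) n_syn <- n_syn + 1L else n_non <- n_non + 1L
  }
  list(cds_a = paste(anc, collapse = ""), cds_b = paste(des, collapse = ""),
       truth = list(omega = omega, n_subs = accepted,
                    n_syn = n_syn, n_non = n_non))
}
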