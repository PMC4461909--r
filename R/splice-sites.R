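#' Construct a gene model
#'
#' Minimal exon-interval gene model used for splice-context extraction.
#' Coordinates are 0-based half-open on the forward strand of the contig;
#' exons must be non-overlapping and are stored in ascending genomic order.
#'
#' @param seq_id Contig/scaffold identifier.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors (0-based half-open).
#' @param gene_id Gene/transcript identifier.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(seq_id, strand, exon_starts, exon_ends, gene_id = "gene") {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L,
            all(exon_starts < exon_ends))
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o]); exon_ends <- as.integer(exon_ends[o])
  if (any(exon_starts[-1] < exon_ends[-length(exon_ends)])) {
    stop("exons overlap in gene ", gene_id)
  }
  structure(
    list(gene_id = gene_id, seq_id = seq_id, strand = strand,
         exon_starts = exon_starts, exon_ends = exon_ends),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' on %s(%s): %d exon(s)\n",
              x$gene_id, x$seq_id, x$strand, length(x$exon_starts)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file (1-based closed coordinates, converted to the
#' package's internal 0-based half-open convention) and groups `exon`
#' features into [gene_model]s by their `Parent` attribute (falling back to
#' `ID`/`gene_id`).
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  mc <- S4Vectors::mcols(gr)
  grp <- if ("Parent" %in% names(mc) && any(lengths(mc$Parent) > 0)) {
    vapply(mc$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else if ("gene_id" %in% names(mc)) {
    as.character(mc$gene_id)
  } else if ("ID" %in% names(mc)) {
    as.character(mc$ID)
  } else {
    stop("cannot group exons: no Parent/gene_id/ID attribute in ", path)
  }
  if (anyNA(grp)) stop("exon feature(s) without a grouping attribute in ", path)
  models <- lapply(split(seq_along(gr), grp), function(idx) {
    sub <- gr[idx]
    strand <- unique(as.character(BiocGenerics::strand(sub)))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop("exons of one transcript must share a +/- strand")
    }
    gene_model(
      seq_id = as.character(GenomeInfoDb::seqnames(sub))[1],
      strand = strand,
      exon_starts = BiocGenerics::start(sub) - 1L,
      exon_ends = BiocGenerics::end(sub),
      gene_id = grp[idx][1]
    )
  })
  models
}

#' Write gene models as GFF3
#'
#' @param models A [gene_model] or list of them.
#' @param path Output file.
#' @export
write_gene_models <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  grs <- lapply(models, function(m) {
    GenomicRanges::GRanges(
      seqnames = m$seq_id,
      ranges = IRanges::IRanges(start = m$exon_starts + 1L, end = m$exon_ends),
      strand = m$strand,
      type = "exon",
      ID = paste0(m$gene_id, ":exon", seq_along(m$exon_starts)),
      Parent = m$gene_id
    )
  })
  rtracklayer::export(do.call(c, unname(grs)), path, format = "gff3")
  invisible(path)
}

# Return contig sequence and exon intervals in transcription order,
# re-expressed on the coding (working) strand.
.working_strand <- function(seq, model) {
  L <- nchar(seq)
  if (max(model$exon_ends) > L || min(model$exon_starts) < 0L) {
    stop(sprintf("exon out of bounds in gene %s on %s (contig length %d)",
                 model$gene_id, model$seq_id, L))
  }
  if (model$strand == "+") {
    list(seq = seq, starts = model$exon_starts, ends = model$exon_ends)
  } else {
    list(seq = reverse_complement(seq),
         starts = rev(L - model$exon_ends),
         ends = rev(L - model$exon_starts))
  }
}

#' Extract donor and acceptor contexts for every intron
#'
#' For each intron of each gene model, reports the last 6 exonic nt and the
#' first 16 intronic nt at the donor, and at the acceptor the final 16
#' intronic nt split into the 12-nt polypyrimidine tract and the terminal
#' 4-mer, plus the tract's pyrimidine count `Y`.  Minus-strand genes are
#' processed on the reverse complement, so contexts always read in the
#' transcript's 5'→3' direction.  Introns shorter than 30 nt are skipped
#' with a warning (their tract and donor context would overlap).
#'
#' @param genome FASTA path or [Biostrings::DNAStringSet] of contigs.
#' @param models A [gene_model], list of them, or GFF3 path for
#'   [read_gene_models()].
#' @return Data frame with one row per intron: `gene_id`, `seq_id`,
#'   `strand`, `intron_index`, `intron_length`, `exon_end6`, `donor16`,
#'   `tract12`, `acceptor4`, `Y`.
#' @export
extract_splice_contexts <- function(genome, models) {
  if (is.character(genome)) genome <- read_fasta(genome)
  if (is.character(models)) models <- read_gene_models(models)
  if (inherits(models, "gene_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    if (!m$seq_id %in% names(genome)) {
      stop("contig ", m$seq_id, " (gene ", m$gene_id, ") not in genome")
    }
    ws <- .working_strand(as.character(genome[[m$seq_id]]), m)
    n_ex <- length(ws$starts)
    if (n_ex < 2L) return(NULL)
    out <- vector("list", n_ex - 1L)
    for (i in seq_len(n_ex - 1L)) {
      istart <- ws$ends[i]; iend <- ws$starts[i + 1L]
      ilen <- iend - istart
      if (ilen < 30L) {
        warning(sprintf("gene %s intron %d is %d nt (< 30); skipped",
                        m$gene_id, i, ilen))
        next
      }
      ex6 <- substring(ws$seq, max(1L, ws$ends[i] - 5L), ws$ends[i])
      donor16 <- substring(ws$seq, istart + 1L, istart + 16L)
      acc16 <- substring(ws$seq, iend - 15L, iend)
      out[[i]] <- data.frame(
        gene_id = m$gene_id, seq_id = m$seq_id, strand = m$strand,
        intron_index = i, intron_length = ilen,
        exon_end6 = ex6, donor16 = donor16,
        tract12 = substring(acc16, 1L, 12L),
        acceptor4 = substring(acc16, 13L, 16L),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), seq_id = character(),
                      strand = character(), intron_index = integer(),
                      intron_length = integer(), exon_end6 = character(),
                      donor16 = character(), tract12 = character(),
                      acceptor4 = character(), stringsAsFactors = FALSE)
  }
  res$Y <- if (nrow(res)) pyrimidine_count(res$tract12) else integer(0)
  rownames(res) <- NULL
  res
}

#' Pyrimidine count of a 12-nt polypyrimidine tract
#'
#' Number of C/T in the 12 nt immediately upstream of the 4-nt splice
#' acceptor.  Case-insensitive; ambiguity codes count as neither pyrimidine
#' nor purine.
#'
#' @param tract12 Character vector of 12-nt strings.
#' @return Integer vector of counts in `0..12`.
#' @examples
#' pyrimidine_count("ctttttcccgtt")  # 11
#' @export
pyrimidine_count <- function(tract12) {
  if (any(nchar(tract12) != 12L)) stop("tract must be exactly 12 nt")
  vapply(strsplit(toupper(chartr("Uu", "Tt", tract12)), "", fixed = TRUE),
         function(ch) sum(ch %in% c("C", "T")), integer(1))
}

#' Summary statistics for a population of acceptor tracts
#'
#' @param counts Integer vector of per-acceptor pyrimidine counts (`n >= 2`).
#' @return `acceptor_stats`: list with `n`, `mean`, `sd` (sample SD) and
#'   `se = sd/sqrt(n)`.
#' @export
acceptor_stats <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least 2 acceptor counts")
  s <- sd(counts)
  structure(list(n = length(counts), mean = mean(counts), sd = s,
                 se = s / sqrt(length(counts))),
            class = "acceptor_stats")
}

#' @export
print.acceptor_stats <- function(x, ...) {
  cat(sprintf("acceptor_stats: n = %d, mean = %.3f, sd = %.3f, se = %.4f\n",
              x$n, x$mean, x$sd, x$se))
  invisible(x)
}

#' Genome-wide acceptor tract reference for *Culex quinquefasciatus*
#'
#' Published summary of the pyrimidine counts of 52,278 internal-exon
#' acceptor tracts from the CpipJ assembly: mean 8.58, spread 1.39 (treated
#' as a standard deviation; as a standard error at this n it would be
#' impossible).  Used as the reference population when z-scoring individual
#' acceptors.
#'
#' @return An `acceptor_stats`-like list with `n`, `mean`, `sd`, `se`.
#' @export
cxq_acceptor_reference <- function() {
  structure(list(n = 52278L, mean = 8.58, sd = 1.39, se = 1.39 / sqrt(52278)),
            class = "acceptor_stats")
}

#' Published splice-junction contexts of the *Culex quinquefasciatus*
#' doublesex gene
#'
#' The eight donor/acceptor context strings of the Cxqdsx splice junctions
#' (introns 1, 2, 3a, 3b, 4, 4ex, 5 and 6), shipped as a plain-text fixture,
#' with the acceptor split into tract and 4-mer and the pyrimidine count
#' computed.
#'
#' @return Data frame: `intron_id`, `exon_end6`, `donor16`, `tract12`,
#'   `acceptor4`, `next_exon10`, `Y`.
#' @export
cxq_junction_contexts <- function() {
  path <- system.file("extdata", "cxq_dsx_junctions.tsv", package = "cisplice",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$tract12 <- substring(tab$acceptor16, 1L, 12L)
  tab$acceptor4 <- substring(tab$acceptor16, 13L, 16L)
  tab$acceptor16 <- NULL
  tab$Y <- pyrimidine_count(tab$tract12)
  tab
}

#' Flag weak (suboptimal) splice acceptors
#'
#' z-scores each acceptor's pyrimidine count against a reference population
#' and calls it weak when it is pyrimidine-poor beyond the threshold
#' (one-sided: `z <= -z_threshold`).  A pyrimidine-*rich* outlier is a
#' strong acceptor, not a weak one.
#'
#' @param Y Integer vector of pyrimidine counts.
#' @param stats An [acceptor_stats] (or list with `mean` and `sd > 0`).
#' @param z_threshold Positive threshold on the low side (default 2).
#' @return Data frame with `Y`, `z`, `weak`.
#' @examples
#' flag_weak_acceptor(5, cxq_acceptor_reference())  # z ~ -2.58, weak
#' @export
flag_weak_acceptor <- function(Y, stats, z_threshold = 2.0) {
  if (is.null(stats$sd) || !is.finite(stats$sd) || stats$sd <= 0) {
    stop("reference sd must be > 0")
  }
  stopifnot(z_threshold > 0)
  z <- (as.numeric(Y) - stats$mean) / stats$sd
  data.frame(Y = as.integer(Y), z = z, weak = z <= -z_threshold)
}

#' Call splice sites: canonicality and acceptor strength
#'
#' Annotates an intron context table (from [extract_splice_contexts()] or
#' [cxq_junction_contexts()]) with GT–AG canonicality, acceptor z-score and
#' weak flag.
#'
#' @param contexts Data frame with columns `donor16`, `acceptor4`, `Y`.
#' @inheritParams flag_weak_acceptor
#' @return The input with added `canonical`, `z`, `weak` columns.
#' @export
call_splice_sites <- function(contexts, stats, z_threshold = 2.0) {
  fl <- flag_weak_acceptor(contexts$Y, stats, z_threshold)
  contexts$canonical <-
    toupper(substring(contexts$donor16, 1L, 2L)) == "GT" &
    toupper(substring(contexts$acceptor4, 3L, 4L)) == "AG"
  contexts$z <- fl$z
  contexts$weak <- fl$weak
  contexts
}

#' Check GT–AG canonicality of every intron of a gene set
#'
#' @inheritParams extract_splice_contexts
#' @return Data frame: `gene_id`, `intron_index`, `canonical`.
#' @export
validate_canonical <- function(genome, models) {
  ctx <- extract_splice_contexts(genome, models)
  data.frame(
    gene_id = ctx$gene_id, intron_index = ctx$intron_index,
    canonical = toupper(substring(ctx$donor16, 1L, 2L)) == "GT" &
      toupper(substring(ctx$acceptor4, 3L, 4L)) == "AG",
    stringsAsFactors = FALSE
  )
}

#' Per-intron splice-strength report
#'
#' End-to-end convenience: extract contexts, z-score acceptors against a
#' reference (by default the statistics of the extracted population itself)
#' and write a per-intron TSV plus a one-row summary.
#'
#' @inheritParams extract_splice_contexts
#' @param stats Reference [acceptor_stats]; `NULL` (default) uses the
#'   statistics of the extracted acceptor population.
#' @param z_threshold Weak-acceptor threshold.
#' @param path Optional TSV output path.
#' @return The annotated context data frame (invisibly written to `path`
#'   when given); the reference stats are attached as attribute `"stats"`.
#' @export
splice_strength <- function(genome, models, stats = NULL, z_threshold = 2.0,
                            path = NULL) {
  ctx <- extract_splice_contexts(genome, models)
  if (is.null(stats)) stats <- acceptor_stats(ctx$Y)
  out <- call_splice_sites(ctx, stats, z_threshold)
  attr(out, "stats") <- stats
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
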