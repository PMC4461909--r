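## Pairwise Ka/Ks by Nei-Gojobori (1986) counting with Jukes-Cantor
## correction, and the 30-nt/3-nt sliding-window profile.
##
## Conventions fixed here (NG86 variants differ on these): mutations to stop
## codons are excluded from site counting with per-position renormalization;
## substitution pathways passing through a stop codon are dropped and the
## remaining minimal pathways averaged; gap columns and columns with
## ambiguity codes are skipped.

.STOPS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

.codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

.is_valid_codon <- function(codon) {
  !is.na(codon) & nchar(codon) == 3L &
    !grepl("[^ACGT]", codon) & !(codon %in% .STOPS)
}

# memoised per-codon (s, n) site table over the 61 sense codons
.ng86_site_table <- function() {
  if (!is.null(.cache$ng86_sites)) return(.cache$ng86_sites)
  codons <- names(Biostrings::GENETIC_CODE)
  tab <- matrix(NA_real_, nrow = length(codons), ncol = 2,
                dimnames = list(codons, c("s", "n")))
  for (cd in setdiff(codons, .STOPS)) {
    aa <- .codon_aa(cd)
    s <- 0
    for (pos in 1:3) {
      ch <- strsplit(cd, "", fixed = TRUE)[[1]]
      nb <- vapply(setdiff(.BASES, ch[pos]), function(b) {
        ch2 <- ch; ch2[pos] <- b; paste(ch2, collapse = "")
      }, character(1))
      nb <- nb[!(nb %in% .STOPS)]
      if (length(nb)) s <- s + sum(.codon_aa(nb) == aa) / length(nb)
      # a position whose every neighbour is a stop contributes 0 sites of
      # either kind only through the synonymous share; renormalized below
    }
    tab[cd, ] <- c(s, 3 - s)
  }
  .cache$ng86_sites <- tab
  tab
}

#' NG86 fractional synonymous/nonsynonymous site counts of a codon
#'
#' Each codon position contributes one site, split between synonymous and
#' nonsynonymous in proportion to the single-nucleotide neighbours of that
#' position; mutations to stop codons are excluded and the position
#' renormalized over its remaining neighbours.  `s + n = 3` always.
#'
#' @param codon A 3-letter ACGT string; stop codons and ambiguity codes are
#'   an error (such columns are skipped upstream).
#' @return Named numeric `c(s = ..., n = ...)`.
#' @examples
#' ng86_sites("TTT")  # s = 1/3
#' ng86_sites("ATG")  # s = 0
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(chartr("Uu", "Tt", codon))
  if (!.is_valid_codon(codon)) {
    stop("codon must be an unambiguous non-stop ACGT triplet: ", codon)
  }
  tab <- .ng86_site_table()
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

.PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# average (sd, nd) over minimal substitution pathways between two codons;
# pathways through stop codons are excluded (all-blocked falls back to all
# pathways so the column is never silently dropped)
.ng86_path_counts <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  ch1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  ch2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  diffs <- which(ch1 != ch2)
  perms <- lapply(.PERMS[[length(diffs)]], function(p) diffs[p])
  walk <- function(order_pos) {
    cur <- ch1; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in order_pos) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      cod_cur <- paste(cur, collapse = ""); cod_nxt <- paste(nxt, collapse = "")
      if (cod_nxt %in% .STOPS && !identical(nxt, ch2)) blocked <- TRUE
      if (.codon_aa(cod_cur) == .codon_aa(cod_nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  paths <- lapply(perms, walk)
  ok <- !vapply(paths, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  c(sd = mean(vapply(paths[ok], `[[`, numeric(1), "sd")),
    nd = mean(vapply(paths[ok], `[[`, numeric(1), "nd")))
}

.jc_correct <- function(p) {
  if (!is.finite(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

.split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

#' Build a pairwise codon alignment from two CDS
#'
#' Aligns the translated peptides globally (BLOSUM62, affine gaps) and
#' threads the alignment back onto the codons, so gaps occur only in whole
#' codons.  A terminal stop codon is trimmed; internal stops or a length
#' that is not a multiple of 3 are errors.
#'
#' @param cds_a,cds_b Coding sequences (strings or `DNAString`s).
#' @param id_a,id_b Sequence labels.
#' @return A `codon_alignment`: list with `id_a`, `id_b`, `codons_a`,
#'   `codons_b` (equal-length character vectors; gap codon `"---"`).
#' @export
codon_align <- function(cds_a, cds_b, id_a = "seq_a", id_b = "seq_b") {
  prep <- function(x, id) {
    x <- toupper(.normalize_seq(x))
    if (nchar(x) %% 3L != 0L) {
      stop("CDS length of ", id, " is not a multiple of 3")
    }
    cod <- .split_codons(x)
    if (length(cod) && cod[length(cod)] %in% .STOPS) cod <- cod[-length(cod)]
    internal_stop <- which(cod %in% .STOPS)
    if (length(internal_stop)) {
      stop("internal stop codon in ", id, " at codon index ", internal_stop[1])
    }
    if (!length(cod)) stop("CDS ", id, " is empty after stop trimming")
    cod
  }
  cod_a <- prep(cds_a, id_a)
  cod_b <- prep(cds_b, id_b)
  to_aa <- function(cod) {
    aa <- .codon_aa(cod)
    aa[is.na(aa) | grepl("[^ACGT]", cod)] <- "X"
    paste(aa, collapse = "")
  }
  aa_a <- to_aa(cod_a)
  aa_b <- to_aa(cod_b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "", fixed = TRUE)[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "", fixed = TRUE)[[1]]
  ia <- 0L; ib <- 0L
  cols_a <- character(length(al_a)); cols_b <- character(length(al_b))
  for (j in seq_along(al_a)) {
    if (al_a[j] == "-") cols_a[j] <- "---" else { ia <- ia + 1L; cols_a[j] <- cod_a[ia] }
    if (al_b[j] == "-") cols_b[j] <- "---" else { ib <- ib + 1L; cols_b[j] <- cod_b[ib] }
  }
  structure(list(id_a = id_a, id_b = id_b, codons_a = cols_a, codons_b = cols_b),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment %s / %s: %d codon column(s)\n",
              x$id_a, x$id_b, length(x$codons_a)))
  invisible(x)
}

.as_codon_alignment <- function(x) {
  if (inherits(x, "codon_alignment")) return(x)
  stop("expected a codon_alignment (see codon_align())")
}

#' Pairwise Ka/Ks by NG86 counting
#'
#' Counts fractional synonymous/nonsynonymous sites averaged over the two
#' sequences, averages differences over stop-free minimal substitution
#' pathways, and applies the Jukes–Cantor correction
#' `d = -3/4 log(1 - 4p/3)`.  The ratio is `NA` when `Ks` is zero or a
#' proportion exceeds the correction's domain (`p >= 3/4`).  Gap columns
#' and columns containing ambiguity codes or stops are skipped.
#'
#' @param alignment A `codon_alignment` from [codon_align()].
#' @return A `pairwise_rates`: list with `S_sites`, `N_sites`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ka`, `Ks`, `ratio`, `n_codons` (comparable columns).
#' @export
ng86_pair <- function(alignment) {
  alignment <- .as_codon_alignment(alignment)
  ca <- alignment$codons_a; cb <- alignment$codons_b
  keep <- .is_valid_codon(ca) & .is_valid_codon(cb)
  if (!any(keep)) stop("no comparable codon columns")
  ca <- ca[keep]; cb <- cb[keep]
  tab <- .ng86_site_table()
  S <- (sum(tab[ca, "s"]) + sum(tab[cb, "s"])) / 2
  N <- (sum(tab[ca, "n"]) + sum(tab[cb, "n"])) / 2
  diffs <- ca != cb
  sd_tot <- 0; nd_tot <- 0
  for (i in which(diffs)) {
    cnt <- .ng86_path_counts(ca[i], cb[i])
    sd_tot <- sd_tot + cnt["sd"]; nd_tot <- nd_tot + cnt["nd"]
  }
  ps <- if (S > 0) sd_tot / S else NA_real_
  pn <- if (N > 0) nd_tot / N else NA_real_
  Ks <- .jc_correct(ps); Ka <- .jc_correct(pn)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(
    list(S_sites = unname(S), N_sites = unname(N),
         Sd = unname(sd_tot), Nd = unname(nd_tot),
         ps = unname(ps), pn = unname(pn),
         Ka = unname(Ka), Ks = unname(Ks), ratio = unname(ratio),
         n_codons = sum(keep)),
    class = "pairwise_rates"
  )
}

#' @export
print.pairwise_rates <- function(x, ...) {
  cat(sprintf(
    "pairwise_rates over %d codons: Ka = %s, Ks = %s, Ka/Ks = %s\n",
    x$n_codons, format(x$Ka, digits = 4), format(x$Ks, digits = 4),
    if (is.na(x$ratio)) "undefined" else format(x$ratio, digits = 4)
  ))
  invisible(x)
}

#' Sliding-window Ka/Ks profile
#'
#' Recomputes NG86 Ka/Ks in 30-nt (10-codon) windows sliding 3 nt (1 codon)
#' at a time along the codon alignment.  Each window is keyed by the 1-based
#' coordinate of its central nucleotide (position 16 of the window).  For
#' display, ratios are truncated at 6; a window with synonymous rate zero
#' but nonsynonymous divergence reports an undefined ratio shown at the
#' truncation ceiling.  Windows with fewer than `min_codons` comparable
#' codons are reported as undefined.
#'
#' @param alignment A `codon_alignment`.
#' @param window_nt,step_nt Window and step sizes in nt; multiples of 3.
#' @param min_codons Minimum comparable codons per window (default 5).
#' @return Data frame with one row per window: `center_nt`,
#'   `window_start_nt`, `Ka`, `Ks`, `ratio`, `display_ratio`,
#'   `comparable_codons`.
#' @export
sliding_kaks <- function(alignment, window_nt = 30L, step_nt = 3L,
                         min_codons = 5L) {
  alignment <- .as_codon_alignment(alignment)
  if (window_nt %% 3L != 0L || step_nt %% 3L != 0L) {
    stop("window_nt and step_nt must be multiples of 3")
  }
  ncol_aln <- length(alignment$codons_a)
  wc <- window_nt %/% 3L; sc <- step_nt %/% 3L
  if (wc > ncol_aln) stop("window longer than the alignment")
  starts <- seq.int(1L, ncol_aln - wc + 1L, by = sc)
  rows <- lapply(starts, function(s0) {
    idx <- s0:(s0 + wc - 1L)
    sub <- structure(list(id_a = alignment$id_a, id_b = alignment$id_b,
                          codons_a = alignment$codons_a[idx],
                          codons_b = alignment$codons_b[idx]),
                     class = "codon_alignment")
    comparable <- sum(.is_valid_codon(sub$codons_a) & .is_valid_codon(sub$codons_b))
    ka <- ks <- ratio <- disp <- NA_real_
    if (comparable >= min_codons) {
      r <- ng86_pair(sub)
      ka <- r$Ka; ks <- r$Ks; ratio <- r$ratio
      if (!is.na(ratio)) {
        disp <- min(ratio, 6)
      } else if (!is.na(ka) && !is.na(ks) && ks == 0 && ka > 0) {
        disp <- 6
      }
    }
    data.frame(
      center_nt = 3L * (s0 - 1L) + 16L,
      window_start_nt = 3L * (s0 - 1L) + 1L,
      Ka = ka, Ks = ks, ratio = ratio, display_ratio = disp,
      comparable_codons = comparable
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-gene and windowed Ka/Ks from two CDS
#'
#' Convenience wrapper: align, compute whole-gene NG86 rates and the
#' sliding-window profile.
#'
#' @inheritParams codon_align
#' @inheritParams sliding_kaks
#' @return List with `alignment`, `gene` (a `pairwise_rates`) and
#'   `windows` (the [sliding_kaks()] data frame).
#' @export
kaks_profile <- function(cds_a, cds_b, id_a = "seq_a", id_b = "seq_b",
                         window_nt = 30L, step_nt = 3L, min_codons = 5L) {
  aln <- codon_align(cds_a, cds_b, id_a, id_b)
  list(alignment = aln,
       gene = ng86_pair(aln),
       windows = sliding_kaks(aln, window_nt, step_nt, min_codons))
}
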