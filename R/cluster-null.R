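#' Background (Bernoulli / 0-order Markov) nucleotide model
#'
#' @param freq Named numeric of base frequencies for `A`, `C`, `G`, `T`;
#'   must be non-negative and sum to 1 (tolerance 1e-12).  Default uniform.
#' @return Named numeric vector of class `background_model`.
#' @export
background_model <- function(freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (inherits(freq, "background_model")) return(freq)
  stopifnot(is.numeric(freq), length(freq) == 4L)
  if (is.null(names(freq))) names(freq) <- c("A", "C", "G", "T")
  freq <- freq[c("A", "C", "G", "T")]
  if (anyNA(freq) || any(freq < 0)) stop("frequencies must be named A/C/G/T and >= 0")
  if (abs(sum(freq) - 1) > 1e-12) stop("frequencies must sum to 1")
  structure(freq, class = "background_model")
}

#' Empirical background frequencies from sequences
#'
#' @param x FASTA path or [Biostrings::DNAStringSet].
#' @return A [background_model] with the pooled A/C/G/T frequencies
#'   (ambiguity codes ignored).
#' @export
background_from_fasta <- function(x) {
  seqs <- if (is(x, "DNAStringSet")) x else read_fasta(x)
  counts <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  background_model(counts / sum(counts))
}

#' Probability that a fixed position starts a motif match
#'
#' Product over pattern positions of the summed class frequencies; equals
#' the sum of the probabilities of all concrete expansions.
#'
#' @inheritParams occurrence_distribution
#' @return A probability.
#' @examples
#' per_position_match_prob("CAAGR")  # (1/4)^4 * 1/2
#' @export
per_position_match_prob <- function(pattern, background = background_model()) {
  pattern <- degenerate_pattern(pattern)
  background <- background_model(background)
  prod(vapply(pattern$symbols,
              function(s) sum(background[IUPAC_CLASSES[[s]]]),
              numeric(1)))
}

#' Exact null distribution of motif occurrence counts
#'
#' Distribution of the number of (overlapping) match positions of a
#' degenerate motif in a random i.i.d. sequence of length `L` under a
#' 0-order background, computed exactly by dynamic programming over a
#' Shift-And prefix automaton crossed with a capped match count.  Counts
#' `>= cap` are lumped into the final entry.
#'
#' @param pattern A [degenerate_pattern] or IUPAC string (at most 16 nt).
#' @param L Sequence length (nt), `>= 0`.
#' @param background A [background_model] (default uniform).
#' @param cap Count ceiling (`>= 1`); when only the tail at `k` is needed,
#'   `cap = k` suffices.
#' @return An `occurrence_distribution`: list with `p` (probabilities for
#'   counts `0 .. cap-1` plus `P(count >= cap)`), `L`, `cap`, `pattern_id`
#'   and `background`.
#' @examples
#' d <- occurrence_distribution("A", L = 2, cap = 2)
#' d$p  # 0.5625 0.3750 0.0625 -- Binomial(2, 1/4)
#' @export
occurrence_distribution <- function(pattern, L, background = background_model(),
                                    cap = 10L) {
  pattern <- degenerate_pattern(pattern)
  background <- background_model(background)
  if (L < 0) stop("L must be >= 0")
  if (cap < 1) stop("cap must be >= 1")
  L <- as.integer(L); cap <- as.integer(cap)
  p <- if (L < pattern$length) {
    c(1, rep(0, cap))
  } else {
    cpp_occurrence_dp(pattern_bits(pattern), L, as.numeric(background), cap)
  }
  names(p) <- c(as.character(0:(cap - 1L)), paste0(">=", cap))
  structure(
    list(p = p, L = L, cap = cap, pattern_id = pattern$pattern_id,
         background = background),
    class = "occurrence_distribution"
  )
}

#' @export
print.occurrence_distribution <- function(x, ...) {
  cat(sprintf("occurrence_distribution for '%s', L = %d (cap %d)\n",
              x$pattern_id, x$L, x$cap))
  print(x$p)
  invisible(x)
}

#' Upper-tail probability of an occurrence distribution
#'
#' @param dist An [occurrence_distribution].
#' @param k Count threshold, `0 <= k <= cap`.
#' @return `P(count >= k)`.
#' @export
tail_prob <- function(dist, k) {
  stopifnot(inherits(dist, "occurrence_distribution"))
  if (k < 0) stop("k must be >= 0")
  if (k > dist$cap) stop("k exceeds cap; recompute the distribution with cap >= k")
  if (k == 0) return(1)
  sum(dist$p[(k + 1L):(dist$cap + 1L)])
}

#' Monte Carlo estimate of the motif occurrence tail
#'
#' Independent stochastic check on the exact DP: simulates `reps` i.i.d.
#' sequences and reports the fraction holding at least `k` matches, with its
#' binomial standard error.  Driven by R's RNG, so `set.seed()` (or the
#' `seed` argument) makes runs reproducible.
#'
#' @inheritParams occurrence_distribution
#' @param k Count threshold.
#' @param reps Number of simulated sequences (`>= 1`).
#' @param seed Optional integer seed applied before simulation.
#' @return List with `estimate`, `se`, `reps`, `k`, `L`, `seed`.
#' @export
mc_occurrence_prob <- function(pattern, L, k, background = background_model(),
                               reps = 1e5, seed = NULL) {
  pattern <- degenerate_pattern(pattern)
  background <- background_model(background)
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  succ <- cpp_mc_tail(pattern_bits(pattern), as.integer(L), as.integer(k),
                      as.numeric(background), as.integer(reps))
  est <- succ / reps
  list(estimate = est, se = sqrt(est * (1 - est) / reps),
       reps = as.integer(reps), k = as.integer(k), L = as.integer(L),
       seed = seed)
}

#' One-call cluster null probability
#'
#' Convenience wrapper: probability of observing at least `k` motif copies
#' in a random sequence of length `L`, by exact DP or Monte Carlo.
#'
#' @inheritParams mc_occurrence_prob
#' @param method `"dp"` (exact, default) or `"mc"`.
#' @return For `"dp"` a probability; for `"mc"` the list from
#'   [mc_occurrence_prob()].
#' @export
cluster_null_prob <- function(pattern, L, k, background = background_model(),
                              method = c("dp", "mc"), reps = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (method == "dp") {
    tail_prob(occurrence_distribution(pattern, L, background, cap = max(1L, k)), k)
  } else {
    mc_occurrence_prob(pattern, L, k, background, reps, seed)
  }
}
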