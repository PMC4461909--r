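---
title: "Methods: motif clusters, splice-site strength, core promoters and sliding-window Ka/Ks"
author: "cisplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif clusters, splice-site strength, core promoters and sliding-window Ka/Ks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisplice)
```

This vignette is the package's own account of its methods: the models and
rules each module implements, the parameters that matter and their
defaults, the numerical choices made where conventions differ, and what
the synthetic-data generators do and do not emulate.

## The biological setting

In insects, sex-specific splicing of the switch gene *doublesex* is
directed by trans-acting factors binding clusters of short degenerate
cis-elements in the pre-mRNA (TRA/TRA2 sites, RBP1 sites, intronic
silencers), often near splice sites that are intrinsically *weak* — their
polypyrimidine tract is interrupted by purines — and therefore dependent
on enhancer activation.  Transcription initiates at a core promoter that,
in the mosquito genes motivating this package, is TATA-less and built from
an initiator (Inr) plus a downstream promoter element (DPE) at a fixed
spacing.  Finally, the male- and female-specific portions of the
transcript can evolve at very different rates, which a windowed Ka/Ks
profile along a pairwise codon alignment makes visible.  The package
implements each of these analyses as an independent, composable module,
with a simulator that fabricates inputs carrying known ground truth.

## Degenerate motif scanning and cluster screening

A motif is an ordered IUPAC consensus (`degenerate_pattern()`); its
*degeneracy* is the product of per-position class sizes
(`NMDNCRWNCWAYM` → 12,288 concrete words).  Scanning
(`scan_sequence()`) is exact full-length matching of the consensus —
equivalent to enumerating every expansion and reporting every
(possibly overlapping) match position, which is also how the independent
oracle in the test suite works.  Choices fixed here:

- **Subject ambiguity codes never match.**  An `N` in the scanned
  sequence (e.g. masked repeats) matches no pattern position, so masked
  regions cannot seed spurious clusters.
- **Strand.**  Transcript/CDS scans default to the forward (sense)
  strand; `strand_mode = "both"` is available for genomic scans and maps
  reverse-strand hits back onto forward coordinates.  Whether a genomic
  cis-element search should count both strands is left to the caller;
  the default is forward.
- **Windows.**  `max_window_count()` slides a length-`w` window by 1 nt
  over every start position; a hit belongs to a window only if its whole
  span lies inside, overlapping hits each count once, and ties go to the
  smallest window start.  Retention screens (`screen_transcripts()`)
  default to the classical settings `k = 6, w = 224` (TRA/TRA2); the
  RBP1 type-B screen uses `k = 8, w = 546`.
- Coordinates are 0-based half-open internally and in BED output;
  TSV reports are 1-based.

## The occurrence-count null model

The significance of a cluster is judged against the number of motif
matches expected in random sequence.  `occurrence_distribution()` computes
the *exact* distribution of the match count in an i.i.d. (Bernoulli /
0-order Markov) sequence of length $L$: the scanner is compiled into a
Shift-And automaton whose state is the bitmask of motif prefixes matching
at the current position, and a dynamic program propagates probability over
(state × capped count).  Reachable states are enumerated by breadth-first
search; for class-structured motifs the reachable set collapses far below
the $2^{m-1}$ bound, which keeps patterns up to 16 nt tractable.  Counts
at or above `cap` are lumped, since only the tail $P(\text{count} \ge k)$
is usually wanted (`tail_prob()`, `cluster_null_prob()`).

Probabilities at these scales sit far above double-precision underflow, so
the DP uses plain doubles.  The background defaults to uniform
(0.25 each); empirical frequencies can be supplied or computed from a
FASTA (`background_from_fasta()`).  Only 0-order backgrounds are
implemented.  Three independent checks validate the DP: exhaustive
enumeration of all $4^L$ sequences for short patterns, the closed-form
mean $(L-m+1)\,p$ for non-self-overlapping patterns, and a seeded Monte
Carlo sampler (`mc_occurrence_prob()`, written in C++ against R's RNG)
that must agree within 3 standard errors.  For the 13-nt TRA/TRA2
consensus in an 8,045-bp region the uniform-background tail at $k = 6$ is
about $4.2 \times 10^{-3}$ — the right order of magnitude for such a
search, though the exact value depends on the background frequencies
chosen.  Published figures for windowed variants of this quantity are not
mutually consistent under any single stated background, so the package
deliberately offers only the well-defined whole-region tail; a "k copies
inside some w-sub-window" p-value is out of scope.

## Splice-acceptor strength

The acceptor statistic is the **pyrimidine count** $Y \in [0, 12]$ of the
12 nt immediately upstream of the intron's terminal 4-mer
(`pyrimidine_count()`, `extract_splice_contexts()`).  Reference tables of
this statistic are sometimes printed under a "number of purines" heading
even when the values are pyrimidine counts of the printed tracts; the
package follows the data and the definition (pyrimidines), not the
heading.  Genes on the minus strand are processed on the reverse
complement, so contexts always read 5'→3' in transcript orientation;
"internal exons" means every exon but the first, so the last exon's
acceptor is included.  Introns shorter than 30 nt are skipped with a
warning because their donor context and acceptor tract would overlap.

Strength calls (`flag_weak_acceptor()`) z-score $Y$ against a reference
population — either the extracted population itself or an external
reference such as `cxq_acceptor_reference()` (n = 52,278, mean 8.58,
SD 1.39; a value of 1.39 is only credible as an SD, not an SE, at that
sample size).  *Weak* is one-sided, $z \le -2$ by default: a
pyrimidine-rich outlier is a strong acceptor, not a weak one, and the
threshold of 2 makes the classical exon-6 call ($Y = 5$, $z \approx
-2.58$) reproducible while leaving every other published junction
unflagged.  Canonicality is simply intron starts `GT` and ends `AG`,
case-insensitive.

## Core-promoter detection

`find_promoter()` implements the Inr + DPE rule: an initiator match
(`YYANWY`, or `YYANWYY` in the longer variant) whose adenine (motif
position 3) is the TSS, reported as +1; and a DPE match (`RGWYV`, or its
fifth-position-T specialisation `RGWYT`) whose first base sits at
canonical position +28 — i.e. 27 nt downstream of the adenine.  The
spacing is enforced exactly by default (`slack = 0`); a 1-nt shift kills
the call.  A TATA box (`TATAWAW` by default) is searched within
`tata_window = c(-40, -15)` of the TSS; since published assertions of
TATA absence rarely define their search, both the consensus and the
window are configurable, and `tata_found` is reported rather than used as
a filter.  An optional `center`/`radius` pair restricts candidates to a
neighbourhood, e.g. ±250 bp around the point where 5' read coverage
ceases; inferring that point from read pileups is out of scope.

## Pairwise and windowed Ka/Ks

`codon_align()` aligns the translated peptides globally
(BLOSUM62, gap opening 10, extension 0.5, via Biostrings) and threads the
result back to codons, so gaps occur only in whole-codon units; terminal
stop codons are trimmed and internal stops are an error.  `ng86_pair()`
implements Nei–Gojobori (1986) counting with these conventions fixed:

- **Sites.**  Each codon position contributes one site split by the
  synonymous fraction of its single-nucleotide neighbours; mutations to
  stop codons are excluded and the position renormalized over the
  remaining neighbours, so $s + n = 3$ per codon.  Site totals are
  averaged over the two sequences.
- **Differences.**  Codon pairs differing at 2–3 positions are averaged
  over all minimal substitution pathways, excluding pathways that pass
  through a stop codon (if every pathway is blocked, all pathways are
  used rather than silently dropping the column).
- **Correction.**  Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$,
  undefined for $p \ge 3/4$.  The ratio is undefined when $K_s = 0$ or a
  correction is undefined.
- Gap columns and columns with ambiguity codes or stops are skipped.

`sliding_kaks()` recomputes the rates in 30-nt (10-codon) windows sliding
3 nt (1 codon); each window is keyed by the 1-based coordinate of its
central nucleotide, fixed as window position 16 (start + 15) since an
even-length window has no unique centre.  A 300-nt alignment therefore
yields 91 windows.  For plotting, ratios are truncated at 6
(`display_ratio`); a window with $K_s = 0$ but $K_a > 0$ has an undefined
ratio and is displayed at the ceiling, an all-zero window is undefined
without a displayed value, and windows with fewer than 5 comparable
codons are reported as undefined.  Raw values are always retained.
NG86 is a counting estimator: it was chosen over multi-estimator
"model averaging" because it is the transparent, assumption-light
standard, and the package's accuracy claims are therefore phrased as
parameter recovery on simulated data plus qualitative reproduction of the
windowed profile, not numeric equality with other estimators.

## The synthetic-data generators

Every generator draws from R's RNG; passing `seed` fixes the stream, and
each returns a truth record sufficient to score its consumer.

- `gen_background()` / `gen_transcriptome()` — i.i.d. sequence under a
  chosen background; defaults emulate the study conditions used
  throughout the tests: uniform base frequencies, 100 background
  transcripts of 2 kb for screening experiments.
- `plant_cluster()` — writes `k` expansions (sampled uniformly from the
  expansion set, matching the "all possible constituents" reading of a
  consensus) into a random `w`-window at non-overlapping offsets.
  Non-overlap is a deliberate simplification: it guarantees all `k`
  planted copies survive verbatim, while overlapping configurations are
  still exercised by the scanner tests themselves.
- `gen_gene_locus()` — canonical GT..AG introns whose last 16 nt realise
  exact per-intron pyrimidine targets; minus-strand encoding
  reverse-complements the contig and flips coordinates, giving the
  strand-invariance tests their fixture.
- `gen_promoter_region()` — plants Inr + DPE at the canonical spacing and
  resamples any chance TATA-box match upstream, so the planted
  configuration is genuinely TATA-less.
- `evolve_codon_pair()` — ancestor drawn from the background with stops
  rejected; descendant produced by single-nucleotide proposals, rejecting
  stops, accepting synonymous proposals with probability 1 and
  nonsynonymous with probability $\min(\omega, 1)$ (for $\omega > 1$,
  synonymous acceptance is down-weighted to $1/\omega$), until
  `round(subs_per_codon × n_codons)` substitutions have accrued.  The
  default 0.3 substitutions/codon is a divergence at which counting
  methods are comfortably in range — low enough that the Jukes–Cantor
  correction is mild, high enough that windows contain signal — and 200
  codons × 50 replicates gives stable medians in the recovery
  experiments at desk-scale runtime.  At $\omega = 0$ the generator
  additionally rejects proposals whose resulting ancestor/descendant
  codon pair would have any nonsynonymous minimal pathway: pathway
  averaging infers substitutions from endpoints, so without this rule a
  strictly neutral history could still show apparent nonsynonymous
  divergence on multi-hit codons (e.g. TTA→CTA→CTC averages the route
  through Phe), and the generator's contract is that the pair *differs*
  only synonymously.  This is a proposal–acceptance scheme, not a full
  continuous-time substitution model; it reproduces a target dN/dS but
  not codon-frequency or transition/transversion structure.

What the simulators do **not** emulate — repeat content, composition
heterogeneity, real splice-site sequence beyond GT/AG and the tract,
transcript abundance — bounds what green tests mean: they certify the
algorithms and their contracts, not performance on genomic idiosyncrasies.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely offline on
generated data at fixed seeds: enumeration oracles cover all $4^8$
sequences for short patterns; Monte Carlo cross-checks use $10^4$–$10^5$
replicates; screening experiments use 20 seeds × (100 + 1) transcripts of
2 kb; recovery experiments use 50 replicates of 200 codons at
$\omega \in \{0, 0.2, 1, 2\}$.  Exact quantities (expansions, junction
statistics, promoter geometry, window counts) are seed-independent;
stochastic ones are reproducible for a given seed because every random
draw — including the C++ Monte Carlo kernel — goes through R's RNG.

## Known limitations

- No position-weight-matrix or log-odds motif scoring; matching is exact
  degenerate-consensus matching by design.
- The null model is 0-order only, and no p-value is offered for "k copies
  within a w-sub-window of an L-region".
- No MaxEnt/PWM splice-site models, branch-point detection, or donor
  strength statistic (donors are reported as context strings).
- No transcription-start inference from read coverage.
- NG86 is a counting estimator; for heavily saturated or
  composition-biased alignments a likelihood method would be preferable.
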