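#' Find initiator (Inr) elements
#'
#' Scans a sequence for the core-promoter initiator consensus.  The
#' initiator's adenine (motif position 3) marks the transcription start
#' site, reported as +1 in human-facing output.
#'
#' @param seq Sequence (string, `DNAString`, or 1-element `DNAStringSet`).
#' @param variant `"YYANWY"` (default) or `"YYANWYY"`.
#' @param seq_id Identifier for the output table.
#' @return Data frame of candidates: `seq_id`, `inr_start` (0-based),
#'   `tss` (0-based position of the adenine), `inr_variant`.
#' @examples
#' find_inr("CCATAC")  # inr_start 0, tss 2
#' @export
find_inr <- function(seq, variant = c("YYANWY", "YYANWYY"), seq_id = "seq") {
  variant <- match.arg(variant)
  hits <- scan_sequence(seq, degenerate_pattern(variant, pattern_id = variant),
                        seq_id = seq_id)
  data.frame(
    seq_id = rep(seq_id, nrow(hits)),
    inr_start = hits$start, tss = hits$start + 2L,
    inr_variant = rep(variant, nrow(hits)),
    stringsAsFactors = FALSE
  )
}

#' Detect TATA-less Inr + DPE core-promoter configurations
#'
#' Retains initiator candidates whose downstream promoter element (DPE)
#' starts exactly at the canonical spacing: with the Inr adenine as +1, the
#' DPE's first base sits at `dpe_position` (default +28, i.e. 27 nt
#' downstream of the adenine), optionally relaxed by `slack` nt.  Each call
#' also reports whether a TATA box matches within `tata_window` of the TSS
#' (the configuration of interest is TATA-less).
#'
#' @inheritParams find_inr
#' @param inr_variant `"YYANWY"` or `"YYANWYY"`.
#' @param dpe_variant `"RGWYV"` (default) or `"RGWYT"` (the fifth-position-T
#'   specialisation).
#' @param dpe_position 1-based canonical position of the DPE first base
#'   relative to the TSS (+1).
#' @param slack Allowed deviation (nt) from `dpe_position`; 0 enforces the
#'   exact spacing.
#' @param tata_consensus IUPAC consensus searched for a TATA box.
#' @param tata_window Two integers, offsets relative to the TSS within
#'   which a TATA-box match start flags `tata_found` (default `c(-40, -15)`).
#' @param center,radius Optional restriction of the search: only TSS
#'   candidates within `radius` nt of the 0-based position `center` are
#'   considered (e.g. around the point where 5' read coverage ceases).
#' @return Data frame of promoter calls: `seq_id`, `inr_start`, `tss`
#'   (0-based), `inr_variant`, `dpe_start` (0-based), `dpe_variant`,
#'   `dpe_position` (= `dpe_start - tss + 1`), `tata_found`.
#' @export
find_promoter <- function(seq, inr_variant = c("YYANWY", "YYANWYY"),
                          dpe_variant = c("RGWYV", "RGWYT"),
                          dpe_position = 28L, slack = 0L,
                          tata_consensus = "TATAWAW",
                          tata_window = c(-40L, -15L),
                          center = NULL, radius = NULL,
                          seq_id = "seq") {
  inr_variant <- match.arg(inr_variant)
  dpe_variant <- match.arg(dpe_variant)
  if (length(tata_window) != 2L || tata_window[1] > tata_window[2]) {
    stop("tata_window must be c(lo, hi) with lo <= hi")
  }
  stopifnot(dpe_position >= 1L, slack >= 0L)
  inr <- find_inr(seq, inr_variant, seq_id = seq_id)
  if (!is.null(center)) {
    stopifnot(!is.null(radius), radius >= 0)
    inr <- inr[abs(inr$tss - center) <= radius, , drop = FALSE]
  }
  dpe_hits <- scan_sequence(seq, degenerate_pattern(dpe_variant), seq_id = seq_id)
  tata_hits <- scan_sequence(seq, degenerate_pattern(tata_consensus), seq_id = seq_id)
  calls <- lapply(seq_len(nrow(inr)), function(i) {
    tss <- inr$tss[i]
    want <- tss + (dpe_position - 1L) + seq.int(-slack, slack)
    ds <- intersect(want, dpe_hits$start)
    if (!length(ds)) return(NULL)
    ds <- ds[which.min(abs(ds - (tss + dpe_position - 1L)))]  # closest to canonical
    tata <- any(tata_hits$start - tss >= tata_window[1] &
                tata_hits$start - tss <= tata_window[2])
    data.frame(
      seq_id = inr$seq_id[i], inr_start = inr$inr_start[i], tss = tss,
      inr_variant = inr_variant, dpe_start = ds, dpe_variant = dpe_variant,
      dpe_position = ds - tss + 1L, tata_found = tata,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), inr_start = integer(),
                      tss = integer(), inr_variant = character(),
                      dpe_start = integer(), dpe_variant = character(),
                      dpe_position = integer(), tata_found = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write promoter calls as TSV (1-based coordinates)
#'
#' @param calls Result of [find_promoter()].
#' @param path Output file.
#' @export
write_promoters_tsv <- function(calls, path) {
  out <- calls
  out$inr_start <- out$inr_start + 1L
  out$tss <- out$tss + 1L
  out$dpe_start <- out$dpe_start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
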