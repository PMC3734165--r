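# Target-site prediction by antiparallel complementarity with a
# position-weighted penalty score, in the plant-miRNA tradition: every
# length-L window of every transcript is scored against the sRNA (ungapped),
# Watson-Crick match costs 0, a G:U wobble 0.5, a mismatch 1.0, and
# penalties are doubled over the sRNA core (positions 2-13 from the 5'
# end).  Sites at or below the penalty cutoff (default 3.0) are reported.
# All constants are arguments; the coordinates feed the degradome window
# test downstream (sRNA position p pairs with transcript position
# end - p + 1).

#' Predict sRNA binding sites on a transcriptome
#'
#' @param srnas named character vector of sRNA sequences (names are ids), or
#'   a data.frame with columns `srna_id` and `sequence`.  Lengths must be
#'   18-26 nt; T is accepted and treated as U.
#' @param transcripts data.frame from [read_transcriptome()].
#' @param max_penalty report sites with total penalty at or below this
#'   value; default 3.0.
#' @param core_region integer length-2 vector: sRNA positions (5'-based,
#'   inclusive) whose penalties are multiplied by `core_multiplier`;
#'   default c(2, 13).
#' @param wobble_penalty,mismatch_penalty per-position penalties; defaults
#'   0.5 and 1.0 (Watson-Crick matches cost 0).
#' @param core_multiplier multiplier over the core region; default 2.
#' @return data.frame of binding sites sorted by (srna_id, transcript_id,
#'   start): `srna_id`, `srna_seq`, `transcript_id`, `start`, `end`
#'   (1-based inclusive, end - start + 1 = sRNA length), `penalty`, and
#'   `pairing` (one character per sRNA position from the 5' end: M match,
#'   W wobble, X mismatch).
#' @export
scan_targets <- function(srnas, transcripts, max_penalty = 3.0,
                         core_region = c(2L, 13L), wobble_penalty = 0.5,
                         mismatch_penalty = 1.0, core_multiplier = 2.0) {
  if (is.data.frame(srnas)) {
    srna_ids <- srnas$srna_id
    srna_seqs <- srnas$sequence
  } else {
    srna_ids <- names(srnas)
    srna_seqs <- unname(srnas)
  }
  if (is.null(srna_ids) || any(!nzchar(srna_ids))) {
    stop("every sRNA needs an id")
  }
  srna_seqs <- as_rna(srna_seqs)
  assert_rna(srna_seqs, "sRNA")
  lens <- nchar(srna_seqs)
  if (any(lens < 18L | lens > 26L)) {
    stop("sRNA lengths must be between 18 and 26 nt")
  }
  stopifnot(length(core_region) == 2L, max_penalty >= 0)
  empty <- data.frame(srna_id = character(0), srna_seq = character(0),
                      transcript_id = character(0), start = integer(0),
                      end = integer(0), penalty = numeric(0),
                      pairing = character(0), stringsAsFactors = FALSE)
  if (length(srna_seqs) == 0L || nrow(transcripts) == 0L) return(empty)
  tx_seqs <- as_rna(transcripts$sequence)
  hits <- scan_core(srna_seqs, tx_seqs, max_penalty,
                    as.integer(core_region[1]), as.integer(core_region[2]),
                    wobble_penalty, mismatch_penalty, core_multiplier)
  if (length(hits$srna_idx) == 0L) return(empty)
  out <- data.frame(
    srna_id = srna_ids[hits$srna_idx],
    srna_seq = srna_seqs[hits$srna_idx],
    transcript_id = transcripts$transcript_id[hits$tx_idx],
    start = hits$start,
    end = hits$start + nchar(srna_seqs[hits$srna_idx]) - 1L,
    penalty = hits$penalty,
    pairing = hits$pairing,
    stringsAsFactors = FALSE)
  out <- out[order(out$srna_id, out$transcript_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
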