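# Local alignment of reads to a reference with BWA-like scoring and a
# mapping-quality proxy.
#
# The aligner is an affine-gap Smith-Waterman (match +1, mismatch -4, gap
# open 6, gap extend 1 by default; a gap of length L costs open + L*extend).
# mapq is a uniqueness proxy: min(60, best score - best score against a
# column-shuffled decoy of the reference), floored at 0.  Large problems use
# exact-seed banding that falls back to the full DP (see src/align.cpp); the
# banded path is validated against the full DP in the test suite.

#' Alignment scoring parameters
#'
#' @param match match score.
#' @param mismatch mismatch penalty (positive).
#' @param gap_open gap-open penalty (positive); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend gap-extend penalty (positive).
#' @return named list.
#' @export
align_params <- function(match = 1L, mismatch = 4L, gap_open = 6L, gap_extend = 1L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

#' Column-shuffled decoy reference
#'
#' A fixed-seed permutation of the reference used as the second-best
#' alignment target for the mapping-quality proxy; deterministic for a given
#' reference regardless of the caller's RNG state.
#'
#' @param ref reference sequence.
#' @return shuffled sequence of the same composition.
#' @export
make_decoy <- function(ref) {
  with_seed(760201L, {
    paste(sample(strsplit(ref, "")[[1]]), collapse = "")
  })
}

#' Align reads to a reference
#'
#' Best local alignment under affine-gap scoring.  Ties resolve
#' deterministically (leftmost reference end, then diagonal moves before
#' deletions before insertions during traceback).  Duplicate read sequences
#' are aligned once and the results recycled.
#'
#' @param reads character vector of read sequences.
#' @param ref reference sequence.
#' @param params [align_params()].
#' @param decoy optional decoy sequence (see [make_decoy()]); when supplied, a
#'   `mapq` column is computed as `min(60, score - decoy_score)`, floored at 0.
#' @param mode `"auto"` (seed-banded for large problems, full DP otherwise) or
#'   `"full"` (always the full DP).
#' @return data.frame: `seq`, `score`, `ref_start`, `ref_end`, `read_start`,
#'   `read_end` (0-based half-open), `nmatch`, `nmismatch`, `cigar`, and
#'   `mapq` when a decoy is given.  Reads with no positive-scoring alignment
#'   get score 0 and an all-`S` cigar.
#' @export
align_to_reference <- function(reads, ref, params = align_params(), decoy = NULL,
                               mode = c("auto", "full")) {
  mode <- match.arg(mode)
  if (length(reads) == 0)
    return(data.frame(seq = character(0), score = integer(0)))
  if (any(!nzchar(reads)) || anyNA(reads))
    stop("empty read sequence", call. = FALSE)
  check_dna(ref, "reference")
  u <- unique(reads)
  a <- cpp_align_batch(u, ref, params$match, params$mismatch, params$gap_open,
                       params$gap_extend, force_full = (mode == "full"))
  res <- data.frame(seq = u, score = a$score, ref_start = a$ref_start,
                    ref_end = a$ref_end, read_start = a$read_start,
                    read_end = a$read_end, nmatch = a$nmatch,
                    nmismatch = a$nmismatch, cigar = as.character(a$cigar),
                    stringsAsFactors = FALSE)
  if (!is.null(decoy)) {
    ds <- cpp_score_batch(u, decoy, params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
    res$mapq <- pmin(60L, pmax(0L, res$score - ds))
  }
  res[match(reads, u), , drop = FALSE]
}
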