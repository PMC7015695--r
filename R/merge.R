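# Paired-end read merging by maximal-scoring ungapped overlap (the analysis
# unit of the amplicon assay is the assembled read).

#' Merge read pairs by overlap
#'
#' Finds the maximal-scoring ungapped overlap between R1 and the reverse
#' complement of R2 (overlap score = length - 2 * mismatches; candidates must
#' reach `min_overlap` bases with a mismatch fraction at most
#' `max_mismatch_frac`).  The consensus takes the higher-quality base at
#' disagreements.  Pairs without an acceptable overlap are returned with
#' `merged = FALSE` and a reason.
#'
#' @param r1,r2 character vectors of mate sequences (R2 in sequencing
#'   orientation).
#' @param q1,q2 matching Phred+33 quality strings (defaults assume flat
#'   qualities).
#' @param min_overlap minimum acceptable overlap (bp).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap.
#' @return data.frame: `seq`, `qual`, `overlap`, `merged`, `reason`.
#' @export
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 20L,
                        max_mismatch_frac = 0.1) {
  stopifnot(length(r1) == length(r2))
  if (any(!nzchar(r1)) || any(!nzchar(r2)))
    stop("empty mate sequence", call. = FALSE)
  if (is.null(q1)) q1 <- phred_string(0, nchar(r1))
  if (is.null(q2)) q2 <- phred_string(0, nchar(r2))
  m <- cpp_merge_pairs(r1, revcomp(r2), q1, str_rev(q2),
                       as.integer(min_overlap), max_mismatch_frac)
  data.frame(seq = as.character(m$seq), qual = as.character(m$qual),
             overlap = m$overlap, merged = m$ok,
             reason = as.character(m$reason), stringsAsFactors = FALSE)
}

#' @rdname merge_pairs
#' @export
merge_pair <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 20L,
                       max_mismatch_frac = 0.1) {
  merge_pairs(r1, r2, q1, q2, min_overlap, max_mismatch_frac)[1L, ]
}
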