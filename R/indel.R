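# On-target indel-frequency statistic: the fraction of window-mapped reads
# that carry an insertion or deletion inside the target window around the
# predicted cleavage site.

#' Indel frequency in the target window
#'
#' The target window is the closed interval
#' `[cleavage_pos - half_window, cleavage_pos + half_window]` (41 positions at
#' the default +/-20 bp).  The denominator counts alignments with
#' `mapq >= mapq_min` whose reference span overlaps the window; a read counts
#' in the numerator iff it has at least one I or D operation located in the
#' window (for a deletion, any deleted base; for an insertion, its anchor
#' point — an insertion exactly on a window boundary is in-window).
#' Substitutions never count.
#'
#' @param alignments data.frame from [align_to_reference()] (needs `mapq`).
#' @param cleavage_pos 0-based cleavage offset on the reference.
#' @param half_window window half-width in bp.
#' @param mapq_min minimum mapping-quality proxy.
#' @return object of class `indel_result`: `window`, `n_mapped_in_window`,
#'   `n_indel_reads`, `frequency`, plus a per-read logical breakdown in
#'   `reads` (`in_window`, `indel_in_window`, `counted`).
#' @examples
#' ref <- strrep("ACGT", 30)
#' aln <- align_to_reference(substr(ref, 11, 100), ref)
#' aln$mapq <- 60L
#' indel_frequency(aln, cleavage_pos = 60)$frequency # 0: no indels
#' @export
indel_frequency <- function(alignments, cleavage_pos, half_window = 20L,
                            mapq_min = 20) {
  stopifnot(half_window >= 0)
  if (is.null(alignments$mapq))
    stop("alignments need a mapq column (align with a decoy)", call. = FALSE)
  wlo <- as.integer(cleavage_pos - half_window)
  whi <- as.integer(cleavage_pos + half_window)
  in_window <- alignments$mapq >= mapq_min & alignments$score > 0 &
    alignments$ref_start <= whi & alignments$ref_end > wlo
  indel_in <- cpp_indel_in_window(alignments$cigar, alignments$ref_start, wlo, whi)
  counted <- in_window & indel_in
  n_mapped <- sum(in_window)
  if (n_mapped == 0)
    stop(errorCondition("no reads mapped to the target window; frequency undefined",
                        class = c("editquant_undefined_frequency", "error")))
  structure(list(window = c(lo = wlo, hi = whi),
                 n_mapped_in_window = n_mapped,
                 n_indel_reads = sum(counted),
                 frequency = sum(counted) / n_mapped,
                 reads = data.frame(in_window = in_window,
                                    indel_in_window = indel_in,
                                    counted = counted)),
            class = "indel_result")
}

#' @export
print.indel_result <- function(x, ...) {
  cat(sprintf("<indel_result> window [%d, %d]: %d / %d reads with indels (%.4f)\n",
              x$window["lo"], x$window["hi"], x$n_indel_reads,
              x$n_mapped_in_window, x$frequency))
  invisible(x)
}

#' Amplicon indel-quantification pipeline
#'
#' Merges the read pairs, aligns the merged reads to the reference with the
#' mapping-quality decoy, and computes the indel frequency in the target
#' window.  Pairs that fail merging are excluded from both numerator and
#' denominator (the assembled read is the analysis unit).
#'
#' @param r1,r2 data.frames with `id`, `seq`, `qual` (e.g. from
#'   [read_fastq()] or [simulate_indel_reads()]), or paths to FASTQ files.
#' @param ref reference sequence (character) or path to a single-record
#'   FASTA.
#' @param cleavage_pos 0-based predicted cleavage offset on `ref`.
#' @param half_window,mapq_min see [indel_frequency()].
#' @param min_overlap,max_mismatch_frac see [merge_pairs()].
#' @param params [align_params()].
#' @return list: `result` (an `indel_result`), `summary` (one-row
#'   data.frame), `reads` (per-read audit: id, merged, mapq, cigar, counted).
#' @export
quantify_indels <- function(r1, r2, ref, cleavage_pos, half_window = 20L,
                            mapq_min = 20, min_overlap = 20L,
                            max_mismatch_frac = 0.1, params = align_params()) {
  if (is.character(r1) && length(r1) == 1) r1 <- read_fastq(r1)
  if (is.character(r2) && length(r2) == 1) r2 <- read_fastq(r2)
  if (is.character(ref) && file.exists(ref)) ref <- read_fasta(ref)[[1]]
  stopifnot(nrow(r1) == nrow(r2))

  m <- merge_pairs(r1$seq, r2$seq, r1$qual, r2$qual, min_overlap, max_mismatch_frac)
  keep <- m$merged
  audit <- data.frame(id = r1$id, merged = m$merged, reason = m$reason,
                      stringsAsFactors = FALSE)
  if (!any(keep))
    stop(errorCondition("no read pair could be merged",
                        class = c("editquant_undefined_frequency", "error")))
  aln <- align_to_reference(m$seq[keep], ref, params, decoy = make_decoy(ref))
  res <- indel_frequency(aln, cleavage_pos, half_window, mapq_min)
  audit$mapq <- NA_integer_; audit$cigar <- NA_character_
  audit$counted <- FALSE
  audit$mapq[keep] <- aln$mapq
  audit$cigar[keep] <- aln$cigar
  audit$counted[keep] <- res$reads$counted
  list(result = res,
       summary = data.frame(n_pairs = nrow(r1), n_merged = sum(keep),
                            n_mapped = res$n_mapped_in_window,
                            n_indel = res$n_indel_reads,
                            frequency = res$frequency),
       reads = audit)
}
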