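# Simulation parameter records: the outcome mixture of edited alleles and the
# library/sequencing configuration.

#' Edited-allele outcome mixture
#'
#' Fractions of the four repair outcomes a nuclease-plus-donor exposure can
#' leave at the target locus: unedited (parental), NHEJ indel at the cut,
#' HDR knock-in of the donor cassette, and NHEJ capture of a vector fragment
#' at the double-stranded break.
#'
#' @param parental,indel,hdr,vector_fragment non-negative fractions summing
#'   to 1.
#' @param indel_sizes list with `sizes` (integer vector; negative = deletion
#'   length, positive = insertion length) and `probs` (recycled uniform when
#'   `NULL`).
#' @param fragment_sources named non-negative weights over donor/nuclease
#'   feature names from which NHEJ-captured fragments are drawn.
#' @param fragment_length_range length range (bp) of captured fragments.
#' @return object of class `allele_mix`.
#' @export
allele_mix <- function(parental = 1, indel = 0, hdr = 0, vector_fragment = 0,
                       indel_sizes = list(sizes = c(-20:-1, 1:20), probs = NULL),
                       fragment_sources = c(ITR_L = 1, U6_sgRNA = 1, TBG = 1,
                                            hOTCco = 1, polyA = 1, SaCas9 = 1),
                       fragment_length_range = c(10L, 200L)) {
  f <- c(parental = parental, indel = indel, hdr = hdr,
         vector_fragment = vector_fragment)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("outcome fractions must be non-negative and sum to 1", call. = FALSE)
  if (is.null(indel_sizes$probs))
    indel_sizes$probs <- rep(1 / length(indel_sizes$sizes), length(indel_sizes$sizes))
  if (any(indel_sizes$sizes == 0)) stop("indel size 0 is not an indel", call. = FALSE)
  if (any(fragment_sources < 0) || !any(fragment_sources > 0))
    stop("fragment_sources weights must be non-negative with at least one positive",
         call. = FALSE)
  structure(list(fractions = f, indel_sizes = indel_sizes,
                 fragment_sources = fragment_sources,
                 fragment_length_range = as.integer(fragment_length_range)),
            class = "allele_mix")
}

#' Library / sequencing simulation configuration
#'
#' @param n_molecules number of genomic molecules to simulate.
#' @param read_length paired-end read length (bp).
#' @param amplicon_length indel-assay PCR product length (bp), centred on the
#'   cleavage site.
#' @param umi_length UMI length on the LMU-PCR Y-adapter.
#' @param duplication per-molecule PCR read-count distribution for the LMU
#'   library: `list(dist = "geometric", mean = 5)` or
#'   `list(dist = "constant", n = 1)`.
#' @param duplication_indel same, for the indel amplicon library (duplicates
#'   are a no-op for a read-level statistic, so the default is 1).
#' @param sub_error_rate,indel_error_rate per-base sequencing error
#'   probabilities.
#' @param adapter Y-adapter sequence adjacent to the UMI on the adapter-side
#'   mate.
#' @param unique_umis if `TRUE`, molecules receive UMIs at pairwise Hamming
#'   distance >= 2 (collision-free labelling, for PCR-bias studies); default
#'   `FALSE` draws UMIs uniformly at random, collisions permitted by chance.
#' @param seed integer seed for the simulators.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_molecules, read_length = 250L, amplicon_length = 433L,
                       umi_length = 8L,
                       duplication = list(dist = "geometric", mean = 5),
                       duplication_indel = list(dist = "constant", n = 1),
                       sub_error_rate = 0.005, indel_error_rate = 1e-5,
                       adapter = lmu_adapter(), unique_umis = FALSE,
                       seed = 1L) {
  stopifnot(n_molecules >= 1, read_length >= 50,
            sub_error_rate >= 0, sub_error_rate <= 1,
            indel_error_rate >= 0, indel_error_rate <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 read_length = as.integer(read_length),
                 amplicon_length = as.integer(amplicon_length),
                 umi_length = as.integer(umi_length),
                 duplication = duplication,
                 duplication_indel = duplication_indel,
                 sub_error_rate = sub_error_rate,
                 indel_error_rate = indel_error_rate,
                 adapter = adapter,
                 unique_umis = isTRUE(unique_umis),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default LMU-PCR Y-adapter sequence
#'
#' The constant adapter stretch that follows the UMI on the adapter-side
#' mate; used to locate and excise the UMI.
#'
#' @return character(1).
#' @export
lmu_adapter <- function() "ACGCTCTTCCGATCT"

draw_duplication <- function(n, spec) {
  switch(spec$dist,
         constant = rep(as.integer(spec$n), n),
         geometric = {
           m <- spec$mean
           stopifnot(m >= 1)
           if (m == 1) rep(1L, n) else 1L + rgeom(n, prob = 1 / m)
         },
         stop("unknown duplication dist: ", spec$dist, call. = FALSE))
}
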