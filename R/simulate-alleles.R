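# Edited-allele population simulator: draws outcome categories from the
# mixture, builds each molecule's sequence by editing the locus at the
# cleavage site, and records a truth table for parameter-recovery studies.

#' Simulate a population of edited alleles
#'
#' Category counts are multinomial in the mixture fractions.  Indel alleles
#' modify only the cleavage site (deletions centred on the cut, insertions of
#' random bases at the cut); HDR alleles are the seamless knock-in from
#' [build_hdr_allele()]; vector-fragment alleles insert a random sub-interval
#' of a donor/nuclease feature at the cut in either orientation.
#'
#' @param reference an `editquant_reference`.
#' @param mix an [allele_mix()].
#' @param n number of molecules.
#' @param seed integer seed.
#' @return data.frame (class `edited_alleles`) with columns `id`,
#'   `truth_label`, `indel_size`, `frag_source`, `frag_start`, `frag_len`,
#'   `frag_strand`, `sequence`.
#' @export
simulate_alleles <- function(reference, mix, n, seed = 1L) {
  stopifnot(inherits(reference, "editquant_reference"), inherits(mix, "allele_mix"),
            n >= 1)
  locus <- reference$locus
  cut <- locus$cleavage_pos
  loc_seq <- locus$sequence
  hdr_seq <- as.character(reference$hdr_allele)

  feature_seq <- function(source) {
    for (model in list(reference$donor, reference$nuclease)) {
      f <- model$features
      hit <- which(f$name == source)
      if (length(hit))
        return(substr0(model$sequence, f$start[hit[1]], f$end[hit[1]]))
    }
    stop("unknown fragment source feature: ", source, call. = FALSE)
  }
  src_names <- names(mix$fragment_sources)
  src_seqs <- vapply(src_names, feature_seq, character(1))
  src_prob <- mix$fragment_sources / sum(mix$fragment_sources)

  with_seed(seed_stream(seed, 4L), {
    labels <- sample(names(mix$fractions), n, replace = TRUE, prob = mix$fractions)
    id <- sprintf("mol%06d", seq_len(n))
    indel_size <- rep(NA_integer_, n)
    frag_source <- rep(NA_character_, n)
    frag_start <- rep(NA_integer_, n)
    frag_len <- rep(NA_integer_, n)
    frag_strand <- rep(NA_integer_, n)
    sequence <- character(n)

    for (i in seq_len(n)) {
      lab <- labels[i]
      if (lab == "parental") {
        sequence[i] <- loc_seq
      } else if (lab == "hdr") {
        sequence[i] <- hdr_seq
      } else if (lab == "indel") {
        s <- sample(mix$indel_sizes$sizes, 1L, prob = mix$indel_sizes$probs)
        indel_size[i] <- s
        if (s < 0) {
          k <- -s
          sequence[i] <- paste0(substr0(loc_seq, 0L, cut - k %/% 2L),
                                substr0(loc_seq, cut + (k + 1L) %/% 2L, nchar(loc_seq)))
        } else {
          sequence[i] <- paste0(substr0(loc_seq, 0L, cut), random_dna(s),
                                substr0(loc_seq, cut, nchar(loc_seq)))
        }
      } else { # vector_fragment
        ok <- FALSE
        for (try in seq_len(50L)) {
          src <- sample(src_names, 1L, prob = src_prob)
          fl <- nchar(src_seqs[[src]])
          lo <- mix$fragment_length_range[1]
          hi <- min(mix$fragment_length_range[2], fl)
          if (hi < lo) next
          len <- safe_sample(seq.int(lo, hi), 1L)
          st <- safe_sample(seq.int(0L, fl - len), 1L)
          piece <- substr0(src_seqs[[src]], st, st + len)
          strand <- sample(c(1L, -1L), 1L)
          if (strand < 0) piece <- revcomp(piece)
          sequence[i] <- paste0(substr0(loc_seq, 0L, cut), piece,
                                substr0(loc_seq, cut, nchar(loc_seq)))
          frag_source[i] <- src; frag_start[i] <- st
          frag_len[i] <- len; frag_strand[i] <- strand
          ok <- TRUE
          break
        }
        if (!ok)
          stop("no fragment source feature long enough for the requested lengths",
               call. = FALSE)
      }
    }
    out <- data.frame(id = id, truth_label = labels, indel_size = indel_size,
                      frag_source = frag_source, frag_start = frag_start,
                      frag_len = frag_len, frag_strand = frag_strand,
                      sequence = sequence, stringsAsFactors = FALSE)
    class(out) <- c("edited_alleles", "data.frame")
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Write an allele truth table
#'
#' @param alleles a [simulate_alleles()] result.
#' @param path output TSV path.
#' @export
write_truth_table <- function(alleles, path) {
  write_tsv(alleles[setdiff(names(alleles), "sequence")], path)
}
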