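# Read-level simulators for the two assays: amplicon-seq of the cleavage
# window (indel assay) and the restriction-digest / UMI-adapter LMU-PCR
# library.  Sequencing noise is per-base substitutions and 1-bp indels;
# quality strings encode the configured substitution rate (flat Phred model).

# apply per-base substitution and 1-bp indel errors (R RNG, deterministic
# under with_seed)
mutate_seqs <- function(seqs, sub_rate, indel_rate) {
  if (sub_rate > 0) {
    nch <- nchar(seqs)
    nerr <- rbinom(length(seqs), nch, sub_rate)
    # one vectorised substitution pass per error rank; positions are drawn
    # independently per pass, so a read with several errors can (rarely) hit
    # the same base twice
    other <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
    k <- 1L
    repeat {
      sel <- which(nerr >= k)
      if (length(sel) == 0L) break
      p <- ceiling(runif(length(sel)) * nch[sel])
      cur <- substr(seqs[sel], p, p)
      repl <- other[cbind(match(cur, rownames(other)),
                          sample.int(3L, length(sel), replace = TRUE))]
      substr(seqs[sel], p, p) <- repl
      k <- k + 1L
    }
  }
  if (indel_rate > 0) {
    nch <- nchar(seqs)
    nerr <- rbinom(length(seqs), nch, indel_rate)
    for (i in which(nerr > 0L)) {
      s <- seqs[i]
      for (k in seq_len(nerr[i])) {
        p <- sample.int(nchar(s), 1L)
        if (runif(1) < 0.5 && nchar(s) > 1L) {
          s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
        } else {
          s <- paste0(substr(s, 1L, p), safe_sample(DNA_BASES, 1L),
                      substr(s, p + 1L, nchar(s)))
        }
      }
      seqs[i] <- s
    }
  }
  seqs
}

#' Simulate the indel-assay amplicon library
#'
#' For each allele, the PCR product spans `amplicon_length` bases centred on
#' the cleavage site (the product tracks the allele, so insertions lengthen
#' it and deletions shorten it); each molecule yields `duplication_indel`
#' read pairs (R1 from the left primer, R2 reverse-complemented from the
#' right primer).  Truth molecule ids are embedded in read names
#' (`molNNNNNN:R`).
#'
#' @param alleles a [simulate_alleles()] result.
#' @param reference an `editquant_reference`.
#' @param config a [sim_config()].
#' @return list with data.frames `r1`, `r2` (`id`, `seq`, `qual`) and `truth`
#'   (`id`, `truth_label`, `n_reads`, `amplicon_length`).
#' @export
simulate_indel_reads <- function(alleles, reference, config) {
  stopifnot(inherits(alleles, "edited_alleles"), inherits(config, "sim_config"))
  locus <- reference$locus
  cut <- locus$cleavage_pos
  hw_left <- config$amplicon_length %/% 2L
  hw_right <- config$amplicon_length - hw_left
  rl <- config$read_length

  with_seed(seed_stream(config$seed, 5L), {
    delta <- nchar(alleles$sequence) - nchar(locus$sequence)
    a_start <- cut - hw_left
    a_end <- cut + hw_right + delta
    if (a_start < 0 || any(a_end > nchar(alleles$sequence))) {
      warning("amplicon window clipped to allele bounds")
      a_start <- max(0L, a_start)
      a_end <- pmin(a_end, nchar(alleles$sequence))
    }
    amplicon <- substr0(alleles$sequence, a_start, a_end)
    dup <- draw_duplication(nrow(alleles), config$duplication_indel)
    idx <- rep.int(seq_len(nrow(alleles)), dup)
    rid <- paste0(alleles$id[idx], ":", sequence(dup))
    r1 <- substr0(amplicon[idx], 0L, pmin(rl, nchar(amplicon[idx])))
    rc <- revcomp(amplicon)
    r2 <- substr0(rc[idx], 0L, pmin(rl, nchar(rc[idx])))
    r1 <- mutate_seqs(r1, config$sub_error_rate, config$indel_error_rate)
    r2 <- mutate_seqs(r2, config$sub_error_rate, config$indel_error_rate)
    truth <- data.frame(id = alleles$id, truth_label = alleles$truth_label,
                        n_reads = dup, amplicon_length = nchar(amplicon),
                        stringsAsFactors = FALSE)
    list(r1 = data.frame(id = rid, seq = r1,
                         qual = phred_string(config$sub_error_rate, nchar(r1)),
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = rid, seq = r2,
                         qual = phred_string(config$sub_error_rate, nchar(r2)),
                         stringsAsFactors = FALSE),
         truth = truth)
  })
}

# draw UMIs; collision-free mode enforces pairwise Hamming distance >= 2 so
# that UMI identity equals molecule identity
draw_umis <- function(n, umi_length, unique_umis = FALSE) {
  make <- function(k) {
    m <- matrix(sample(DNA_BASES, k * umi_length, replace = TRUE), nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  if (!unique_umis) return(make(n))
  accepted <- character(0)
  acc_mat <- NULL
  while (length(accepted) < n) {
    cand <- make(1L)
    cm <- strsplit(cand, "")[[1]]
    if (!is.null(acc_mat)) {
      d <- colSums(acc_mat != cm)
      if (any(d < 2)) next
    }
    accepted <- c(accepted, cand)
    acc_mat <- cbind(acc_mat, cm)
  }
  accepted
}

#' Simulate the LMU-PCR library
#'
#' Each allele is digested with the assay enzyme; the ligation fragment (GSP3
#' primer site to the first downstream cut) is tagged with a random UMI and
#' amplified to `duplication` read pairs.  R1 begins at the GSP3 primer
#' position (the three nested touchdown-PCR rounds are collapsed into the
#' per-molecule duplication draw); R2 begins at the adapter end and reads
#' UMI, adapter, then fragment sequence.  Molecules whose fragment lost the
#' GSP3 site or has no downstream cut are dropped and logged as unrecoverable
#' in the truth table.
#'
#' @inheritParams simulate_indel_reads
#' @param enzyme assay enzyme ([restriction_enzyme()] or name).
#' @return list with data.frames `r1`, `r2` and `truth` (`id`, `umi`,
#'   `truth_label`, `n_reads`, `fragment_length`, `recovered`).
#' @export
simulate_lmu_library <- function(alleles, reference, enzyme, config) {
  stopifnot(inherits(alleles, "edited_alleles"), inherits(config, "sim_config"))
  enzyme <- as_enzyme(enzyme)
  locus <- reference$locus
  gsp3 <- locus$gsp3_site
  gsp3_seq <- gsp3_sequence(locus)
  rl <- config$read_length
  adapter <- config$adapter
  n <- nrow(alleles)

  with_seed(seed_stream(config$seed, 6L), {
    # digest each distinct allele sequence once
    useq <- unique(alleles$sequence)
    frag_of <- vapply(useq, function(s) {
      if (substr0(s, gsp3[["start"]], gsp3[["end"]]) != gsp3_seq) return(NA_character_)
      tryCatch(ligation_fragment(s, enzyme, gsp3)$sequence,
               editquant_no_fragment = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
    frag <- frag_of[match(alleles$sequence, useq)]
    recovered <- !is.na(frag)

    umi <- draw_umis(n, config$umi_length, config$unique_umis)
    dup <- draw_duplication(n, config$duplication)
    dup[!recovered] <- 0L

    idx <- rep.int(seq_len(n), dup)
    rid <- paste0(alleles$id[idx], ":", sequence(dup))
    fr <- frag[idx]
    r1 <- substr0(fr, 0L, pmin(rl, nchar(fr)))
    rc <- revcomp(fr)
    ins_len <- pmin(rl - config$umi_length - nchar(adapter), nchar(rc))
    r2 <- paste0(umi[idx], adapter, substr0(rc, 0L, ins_len))
    r1 <- mutate_seqs(r1, config$sub_error_rate, config$indel_error_rate)
    r2 <- mutate_seqs(r2, config$sub_error_rate, config$indel_error_rate)

    truth <- data.frame(id = alleles$id, umi = umi,
                        truth_label = alleles$truth_label, n_reads = dup,
                        fragment_length = ifelse(recovered, nchar(frag), NA_integer_),
                        recovered = recovered, stringsAsFactors = FALSE)
    list(r1 = data.frame(id = rid, seq = r1,
                         qual = phred_string(config$sub_error_rate, nchar(r1)),
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = rid, seq = r2,
                         qual = phred_string(config$sub_error_rate, nchar(r2)),
                         stringsAsFactors = FALSE),
         truth = truth)
  })
}
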