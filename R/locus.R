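# Synthetic target-locus construction.
#
# The locus emulates an intronic SaCas9 target flanked by homology arms:
# uniform random sequence, a 21-nt protospacer + 6-nt NNGRRT-style PAM
# spanning the cut (blunt cut `cut_offset` bp 5' of the PAM), one planted
# restriction site per enzyme per arm at a configured distance from the cut,
# and a nested-primer (GSP3) landing site in the left arm.  All coordinates
# are 0-based; intervals are half-open; cut positions are between-base
# offsets.

#' Build a synthetic target locus
#'
#' Constructs a random locus of `flank_length + 2*arm_length + flank_length`
#' bases whose cleavage site sits exactly between the two homology arms.  For
#' each enzyme in `enzyme_layout` one recognition site is planted in each arm
#' with its cut point `distance` bp from the cleavage site; every other
#' occurrence of any listed recognition sequence within the arms is removed by
#' rejection masking, so in-silico digestion of the arms is fully determined
#' by the layout.  The result is deterministic for a fixed seed.
#'
#' @param arm_length homology-arm length in bp (default 900, i.e. 0.9-kb arms).
#' @param seed integer seed; the builder is a pure function of its arguments.
#' @param enzyme_layout named numeric vector or list, enzyme name ->
#'   cut-distance from the cleavage site in bp (must be < `arm_length`).
#' @param flank_length extra sequence beyond each arm.
#' @param cut_offset blunt-cut distance 5' of the PAM in bp (default 3).
#' @param gsp3_offset distance from the cleavage site to the 5' end of the
#'   GSP3 primer site in the left arm.
#' @param gsp3_length GSP3 primer length.
#' @param mutation_offset annotational offset of the disease-mutation
#'   surrogate upstream of the cut (default 47 bp).
#' @return an object of class `locus_model` with fields `sequence`,
#'   `cleavage_pos`, `protospacer`, `pam`, `left_arm`, `right_arm`,
#'   `gsp3_site` (+ strand), `enzyme_layout`, `enzymes`.
#' @examples
#' loc <- build_synthetic_locus(arm_length = 200, seed = 1,
#'                              enzyme_layout = c(HaeIII = 150))
#' substr(loc$sequence, loc$gsp3_site["start"] + 1, loc$gsp3_site["end"])
#' @export
build_synthetic_locus <- function(arm_length = 900L, seed = 1L,
                                  enzyme_layout = c(HaeIII = 880, TaqI = 860),
                                  flank_length = 30L, cut_offset = 3L,
                                  gsp3_offset = 120L, gsp3_length = 20L,
                                  mutation_offset = 47L) {
  arm_length <- as.integer(arm_length)
  if (arm_length < 100L) stop("arm_length must be >= 100", call. = FALSE)
  enzymes <- lapply(names(enzyme_layout), as_enzyme)
  names(enzymes) <- names(enzyme_layout)
  dist <- as.integer(unlist(enzyme_layout))
  names(dist) <- names(enzyme_layout)
  for (nm in names(dist)) {
    e <- enzymes[[nm]]
    if (dist[nm] >= arm_length)
      stop("enzyme_layout distance for ", nm, " must be < arm_length", call. = FALSE)
    if (dist[nm] - e$cut_offset < 0 ||
        dist[nm] + (nchar(e$recognition) - e$cut_offset) > arm_length)
      stop("planted ", nm, " site would not fit inside the arm", call. = FALSE)
  }
  if (gsp3_offset <= gsp3_length || gsp3_offset > arm_length)
    stop("gsp3_offset must place the primer site inside the left arm", call. = FALSE)

  total <- flank_length + 2L * arm_length + flank_length
  cut <- flank_length + arm_length

  with_seed(seed_stream(seed, 1L), {
    seq <- strsplit(random_dna(total), "")[[1]]

    protected <- integer(0) # 0-based positions that masking must not touch
    plant <- function(seq, site, at0) {
      chars <- strsplit(site, "")[[1]]
      idx <- at0 + seq_along(chars) # 1-based
      seq[idx] <- chars
      protected <<- c(protected, at0 + seq_along(chars) - 1L)
      seq
    }
    # PAM: keep an NNGRRT-compatible motif just 3' of the cut
    pam_start <- cut + cut_offset
    seq <- plant(seq, "GAAT", pam_start + 2L)

    for (nm in names(dist)) {
      e <- enzymes[[nm]]
      seq <- plant(seq, e$recognition, cut + dist[nm] - e$cut_offset)   # right arm
      seq <- plant(seq, e$recognition, cut - dist[nm] - e$cut_offset)   # left arm
    }

    # rejection masking: no stray recognition sites inside the arms
    arms <- c((flank_length + 1L):(flank_length + arm_length),
              (cut + 1L):(cut + arm_length)) # 1-based positions
    arm_set <- logical(total); arm_set[arms] <- TRUE
    planted_cuts <- sort(unlist(lapply(names(dist), function(nm)
      c(cut + dist[nm], cut - dist[nm]))))
    for (round in seq_len(200L)) {
      s <- paste(seq, collapse = "")
      bad <- integer(0)
      for (nm in names(dist)) {
        e <- enzymes[[nm]]
        cuts <- find_restriction_sites(s, e)
        stray <- setdiff(cuts, c(cut + dist[nm], cut - dist[nm]))
        for (cp in stray) {
          occ0 <- cp - e$cut_offset # 0-based start of the stray occurrence
          pos <- occ0:(occ0 + nchar(e$recognition) - 1L)
          pos <- pos[arm_set[pos + 1L] & !(pos %in% protected)]
          if (length(pos) == 0L) next # outside arms or fully protected: leave it
          bad <- c(bad, pos[1L])
        }
      }
      if (length(bad) == 0L) break
      if (round == 200L)
        stop("constraint-infeasible: could not mask stray restriction sites",
             call. = FALSE)
      for (p0 in unique(bad))
        seq[p0 + 1L] <- sample(setdiff(DNA_BASES, seq[p0 + 1L]), 1L)
    }

    sequence <- paste(seq, collapse = "")
    structure(list(
      name = "synthetic_locus",
      sequence = sequence,
      cleavage_pos = cut,
      protospacer = interval(cut - (21L - cut_offset), cut + cut_offset),
      pam = interval(cut + cut_offset, cut + cut_offset + 6L),
      left_arm = interval(flank_length, cut),
      right_arm = interval(cut, cut + arm_length),
      gsp3_site = c(interval(cut - gsp3_offset, cut - gsp3_offset + gsp3_length),
                    strand = 1L), # +1 = forward
      mutation_pos = cut - as.integer(mutation_offset),
      arm_length = arm_length,
      flank_length = as.integer(flank_length),
      cut_offset = as.integer(cut_offset),
      enzyme_layout = dist,
      enzymes = enzymes,
      seed = as.integer(seed)
    ), class = "locus_model")
  })
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %d bp, cleavage at %d, arms %d bp, enzymes: %s\n",
              nchar(x$sequence), x$cleavage_pos, x$arm_length,
              paste(sprintf("%s@%d", names(x$enzyme_layout), x$enzyme_layout),
                    collapse = ", ")))
  invisible(x)
}

# GSP3 primer sequence (and optionally the following arm bases) of a locus
gsp3_sequence <- function(locus, arm_prefix = 0L) {
  substr0(locus$sequence, locus$gsp3_site[["start"]],
          locus$gsp3_site[["end"]] + arm_prefix)
}
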