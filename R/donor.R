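# Donor / nuclease vector models, the HDR allele, ligation fragments, and the
# classification reference panel.
#
# The donor emulates an AAV genome: ITR - U6.sgRNA - HA_L - TBG - hOTCco -
# polyA - HA_R - ITR, with the homology arms copied verbatim from the locus
# and one restriction site per enzyme planted inside the cassette so that
# parental and HDR ligation fragments come out at comparable sizes.  The
# nuclease vector carries the SaCas9 ORF between the same ITRs.  Sequences
# are random (masked where digestion must be determined); no real genome or
# vector sequence is embedded.

#' Build a synthetic donor vector
#'
#' @param locus a [build_synthetic_locus()] result; its arms are copied
#'   verbatim as HA_L/HA_R.
#' @param seed integer seed.
#' @param sizes named integer vector of element lengths
#'   (ITR, U6_sgRNA, TBG, hOTCco, polyA).
#' @param cassette_layout enzyme name -> cut-distance (bp) from the cassette
#'   start; one site per enzyme is planted inside the cassette and all other
#'   cassette occurrences are masked away.
#' @param targeted if `TRUE` the donor carries the locus protospacer (the
#'   guide spacer of its U6-sgRNA cassette) and is itself cleavable; the
#'   untargeted control donor lacks the protospacer.
#' @return object of class `donor_model`: `sequence`, `features`
#'   (data.frame: name, label, start, end, strand), `targeted`,
#'   `cassette` interval.
#' @export
build_synthetic_donor <- function(locus, seed = 2L,
                                  sizes = c(ITR = 145, U6_sgRNA = 250, TBG = 250,
                                            hOTCco = 400, polyA = 150),
                                  cassette_layout = c(HaeIII = 780, TaqI = 760),
                                  targeted = TRUE) {
  stopifnot(inherits(locus, "locus_model"))
  sizes <- setNames(as.integer(sizes), names(sizes))
  arm_l <- substr0(locus$sequence, locus$left_arm[["start"]], locus$left_arm[["end"]])
  arm_r <- substr0(locus$sequence, locus$right_arm[["start"]], locus$right_arm[["end"]])
  cas_len <- sizes[["TBG"]] + sizes[["hOTCco"]] + sizes[["polyA"]]
  enzymes <- lapply(names(cassette_layout), as_enzyme)
  names(enzymes) <- names(cassette_layout)
  cdist <- setNames(as.integer(unlist(cassette_layout)), names(cassette_layout))
  for (nm in names(cdist)) {
    e <- enzymes[[nm]]
    if (cdist[nm] - e$cut_offset < 0 ||
        cdist[nm] + (nchar(e$recognition) - e$cut_offset) > cas_len)
      stop("cassette_layout site for ", nm, " does not fit in the cassette",
           call. = FALSE)
  }

  with_seed(seed_stream(seed, 2L), {
    itr_l <- random_dna(sizes[["ITR"]])
    u6 <- random_dna(sizes[["U6_sgRNA"]])
    if (targeted) {
      proto <- substr0(locus$sequence, locus$protospacer[["start"]],
                       locus$protospacer[["end"]])
      at <- min(150L, sizes[["U6_sgRNA"]] - nchar(proto))
      substr(u6, at + 1L, at + nchar(proto)) <- proto
    }
    cassette <- strsplit(random_dna(cas_len), "")[[1]]
    protected <- integer(0)
    for (nm in names(cdist)) {
      e <- enzymes[[nm]]
      at0 <- cdist[nm] - e$cut_offset
      chars <- strsplit(e$recognition, "")[[1]]
      cassette[at0 + seq_along(chars)] <- chars
      protected <- c(protected, at0 + seq_along(chars) - 1L)
    }
    for (round in seq_len(200L)) {
      s <- paste(cassette, collapse = "")
      bad <- integer(0)
      for (nm in names(cdist)) {
        e <- enzymes[[nm]]
        stray <- setdiff(find_restriction_sites(s, e), cdist[nm])
        for (cp in stray) {
          pos <- (cp - e$cut_offset):(cp - e$cut_offset + nchar(e$recognition) - 1L)
          pos <- pos[!(pos %in% protected)]
          if (length(pos)) bad <- c(bad, pos[1L])
        }
      }
      if (length(bad) == 0L) break
      if (round == 200L)
        stop("constraint-infeasible: could not mask cassette restriction sites",
             call. = FALSE)
      for (p0 in unique(bad))
        cassette[p0 + 1L] <- sample(setdiff(DNA_BASES, cassette[p0 + 1L]), 1L)
    }
    cassette <- paste(cassette, collapse = "")
    itr_r <- revcomp(itr_l)

    parts <- c(ITR_L = itr_l, U6_sgRNA = u6, HA_L = arm_l,
               TBG = substr(cassette, 1L, sizes[["TBG"]]),
               hOTCco = substr(cassette, sizes[["TBG"]] + 1L,
                               sizes[["TBG"]] + sizes[["hOTCco"]]),
               polyA = substr(cassette, sizes[["TBG"]] + sizes[["hOTCco"]] + 1L,
                              cas_len),
               HA_R = arm_r, ITR_R = itr_r)
    lens <- nchar(parts)
    ends <- cumsum(lens)
    starts <- ends - lens
    features <- data.frame(
      name = names(parts),
      label = c("ITR", "U6_sgRNA", "HA_L", "TBG", "hOTCco", "polyA", "HA_R", "ITR"),
      start = as.integer(starts), end = as.integer(ends),
      strand = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, -1L),
      stringsAsFactors = FALSE
    )
    cas_start <- features$start[features$name == "TBG"]
    structure(list(
      name = if (targeted) "synthetic_donor_targeted" else "synthetic_donor_untargeted",
      sequence = paste(parts, collapse = ""),
      features = features,
      targeted = isTRUE(targeted),
      cassette = interval(cas_start, cas_start + cas_len),
      cassette_layout = cdist,
      seed = as.integer(seed)
    ), class = "donor_model")
  })
}

#' @export
print.donor_model <- function(x, ...) {
  cat(sprintf("<donor_model> %s, %d bp, cassette %d bp, %s\n", x$name,
              nchar(x$sequence), diff(x$cassette),
              if (x$targeted) "targeted" else "untargeted"))
  invisible(x)
}

#' Build a synthetic nuclease (SaCas9) vector
#'
#' @param donor a [build_synthetic_donor()] result (the ITRs are shared
#'   between the two AAV genomes, as they would be in a real vector pair).
#' @param seed integer seed for the SaCas9 ORF surrogate.
#' @param sacas9_length ORF surrogate length in bp.
#' @return object of class `donor_model` with features ITR_L, SaCas9, ITR_R.
#' @export
build_nuclease_vector <- function(donor, seed = 3L, sacas9_length = 600L) {
  stopifnot(inherits(donor, "donor_model"))
  f <- donor$features
  itr_l <- substr0(donor$sequence, f$start[f$name == "ITR_L"], f$end[f$name == "ITR_L"])
  itr_r <- substr0(donor$sequence, f$start[f$name == "ITR_R"], f$end[f$name == "ITR_R"])
  orf <- with_seed(seed_stream(seed, 3L), random_dna(sacas9_length))
  parts <- c(ITR_L = itr_l, SaCas9 = orf, ITR_R = itr_r)
  lens <- nchar(parts); ends <- cumsum(lens); starts <- ends - lens
  features <- data.frame(name = names(parts), label = c("ITR", "SaCas9", "ITR"),
                         start = as.integer(starts), end = as.integer(ends),
                         strand = c(1L, 1L, -1L), stringsAsFactors = FALSE)
  structure(list(name = "synthetic_nuclease_vector",
                 sequence = paste(parts, collapse = ""),
                 features = features, targeted = FALSE,
                 cassette = NULL, seed = as.integer(seed)),
            class = "donor_model")
}

#' Construct the HDR (knock-in) allele
#'
#' Inserts the donor cassette (TBG + hOTCco + polyA; the U6-sgRNA cassette and
#' ITRs are not part of the homology-directed insertion) seamlessly at the
#' cleavage site of the locus.
#'
#' @param locus a `locus_model`.
#' @param donor a `donor_model` with a contiguous cassette.
#' @return the HDR allele sequence (character) with attributes
#'   `left_junction`, `right_junction`, `cassette_length`.
#' @export
build_hdr_allele <- function(locus, donor) {
  stopifnot(inherits(locus, "locus_model"), inherits(donor, "donor_model"))
  if (is.null(donor$cassette))
    stop("donor lacks a contiguous TBG+hOTCco+polyA cassette", call. = FALSE)
  f <- donor$features
  idx <- match(c("TBG", "hOTCco", "polyA"), f$name)
  if (anyNA(idx) || f$start[idx[2]] != f$end[idx[1]] ||
      f$start[idx[3]] != f$end[idx[2]])
    stop("donor lacks a contiguous TBG+hOTCco+polyA cassette", call. = FALSE)
  cassette <- substr0(donor$sequence, donor$cassette[["start"]], donor$cassette[["end"]])
  cut <- locus$cleavage_pos
  allele <- paste0(substr0(locus$sequence, 0L, cut), cassette,
                   substr0(locus$sequence, cut, nchar(locus$sequence)))
  structure(allele, left_junction = cut, right_junction = cut + nchar(cassette),
            cassette_length = nchar(cassette))
}

#' Ligation fragment of an allele
#'
#' The molecule that LMU-PCR would amplify: from the 5' end of the nested
#' (GSP3) primer site to the first restriction cut downstream in the primer's
#' orientation.  On the minus strand the fragment is returned
#' reverse-complemented (primer orientation 5'->3').
#'
#' @param allele DNA string.
#' @param enzyme a [restriction_enzyme()] or its name.
#' @param gsp3_site numeric vector `c(start, end, strand)` (0-based half-open;
#'   strand +1/-1) locating the primer site on `allele`.
#' @return list: `sequence`, `start`, `end` (0-based half-open on the allele),
#'   `strand`.
#' @export
ligation_fragment <- function(allele, enzyme, gsp3_site) {
  enzyme <- as_enzyme(enzyme)
  cuts <- find_restriction_sites(allele, enzyme)
  s <- as.integer(gsp3_site[["start"]]); e <- as.integer(gsp3_site[["end"]])
  strand <- as.integer(gsp3_site[["strand"]])
  if (s < 0 || e > nchar(allele))
    stop("gsp3_site out of allele bounds", call. = FALSE)
  if (strand >= 0) {
    down <- cuts[cuts >= e]
    if (length(down) == 0L)
      stop(errorCondition("no restriction cut downstream of the primer site",
                          class = c("editquant_no_fragment", "error")))
    cut <- down[1L]
    list(sequence = substr0(allele, s, cut), start = s, end = cut, strand = 1L)
  } else {
    down <- cuts[cuts <= s]
    if (length(down) == 0L)
      stop(errorCondition("no restriction cut downstream of the primer site",
                          class = c("editquant_no_fragment", "error")))
    cut <- down[length(down)]
    list(sequence = revcomp(substr0(allele, cut, e)), start = cut, end = e,
         strand = -1L)
  }
}

#' Classification reference panel
#'
#' Named references against which unaligned (soft-clipped) molecule portions
#' are classified.  The HDR references are the two expected homology-arm /
#' cassette junction sequences (`junction_halfwidth` bp on each side of each
#' junction of the HDR allele); the element references are taken from the
#' donor and nuclease vectors.  Names are ordered by classification
#' precedence (HDR > hOTCco > TBG > polyA > ITR > SaCas9 > other_vector).
#'
#' @param locus,donor,nuclease the synthetic reference models.
#' @param junction_halfwidth bp of context on each side of an HDR junction.
#' @return named character vector of reference sequences.
#' @export
element_panel <- function(locus, donor, nuclease, junction_halfwidth = 150L) {
  hdr <- build_hdr_allele(locus, donor)
  lj <- attr(hdr, "left_junction"); rj <- attr(hdr, "right_junction")
  h <- as.integer(junction_halfwidth)
  f <- donor$features
  take <- function(model, name) {
    ff <- model$features
    substr0(model$sequence, ff$start[ff$name == name], ff$end[ff$name == name])
  }
  c(HDR_left  = substr0(hdr, lj - h, lj + h),
    HDR_right = substr0(hdr, rj - h, rj + h),
    hOTCco = take(donor, "hOTCco"),
    TBG = take(donor, "TBG"),
    polyA = take(donor, "polyA"),
    ITR = take(donor, "ITR_L"),
    SaCas9 = take(nuclease, "SaCas9"),
    other_vector = take(donor, "U6_sgRNA"))
}

panel_category <- function(panel_name) {
  ifelse(panel_name %in% c("HDR_left", "HDR_right"), "HDR", panel_name)
}

#' Build the full synthetic reference set
#'
#' Convenience orchestrator: locus, targeted donor, nuclease vector, HDR
#' allele, and classification panel, all derived deterministically from one
#' seed.
#'
#' @inheritParams build_synthetic_locus
#' @param donor_sizes,cassette_layout passed to [build_synthetic_donor()].
#' @param targeted whether the donor carries the protospacer.
#' @return object of class `editquant_reference`.
#' @export
synthetic_reference <- function(seed = 1L, arm_length = 900L,
                                enzyme_layout = c(HaeIII = 880, TaqI = 860),
                                donor_sizes = c(ITR = 145, U6_sgRNA = 250,
                                                TBG = 250, hOTCco = 400, polyA = 150),
                                cassette_layout = c(HaeIII = 780, TaqI = 760),
                                targeted = TRUE, ...) {
  locus <- build_synthetic_locus(arm_length = arm_length, seed = seed,
                                 enzyme_layout = enzyme_layout, ...)
  donor <- build_synthetic_donor(locus, seed = seed + 1L, sizes = donor_sizes,
                                 cassette_layout = cassette_layout,
                                 targeted = targeted)
  nuclease <- build_nuclease_vector(donor, seed = seed + 2L)
  structure(list(locus = locus, donor = donor, nuclease = nuclease,
                 hdr_allele = build_hdr_allele(locus, donor),
                 panel = element_panel(locus, donor, nuclease),
                 seed = as.integer(seed)),
            class = "editquant_reference")
}

#' @export
print.editquant_reference <- function(x, ...) {
  cat(sprintf("<editquant_reference> locus %d bp, donor %d bp, nuclease %d bp, panel: %s\n",
              nchar(x$locus$sequence), nchar(x$donor$sequence),
              nchar(x$nuclease$sequence), paste(names(x$panel), collapse = ", ")))
  invisible(x)
}
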