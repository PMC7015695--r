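# LMU-PCR quantification: filtering rules, soft-clip classification against
# the vector-element panel, and the HDR-percentage statistic.

MOLECULE_CATEGORIES <- c("mOTC_locus", "HDR", "hOTCco", "TBG", "polyA", "ITR",
                         "SaCas9", "other_vector", "unclassified")

# assay-specific minimum aligned-portion length (bp)
min_aligned_for <- function(assay) {
  switch(assay, HaeIII = 60L, TaqI = 55L,
         stop("assay must be HaeIII or TaqI", call. = FALSE))
}

#' Filter unique molecules
#'
#' Keeps molecules that (i) have mapping-quality proxy `>= mapq_min`,
#' (ii) have an aligned portion of at least 60 bp (HaeIII assay) or 55 bp
#' (TaqI assay), and (iii) start with the GSP3 primer sequence plus a portion
#' of the homology arm (exact match over the primer, at most
#' `arm_prefix_max_mismatch` mismatches over the arm prefix).  Failing
#' molecules carry the first failing reason in the order mapq, length,
#' primer_prefix.
#'
#' @param molecules data.frame with `consensus`, `mapq`, `aligned` columns
#'   (see [quantify_hdr()] for how these are derived).
#' @param assay `"HaeIII"` or `"TaqI"`.
#' @param primer GSP3 primer sequence.
#' @param arm_prefix homology-arm bases that follow the primer.
#' @param mapq_min minimum mapping-quality proxy.
#' @param min_aligned override of the assay-specific aligned-length threshold.
#' @param arm_prefix_max_mismatch mismatch tolerance over the arm prefix.
#' @return the input with logical `kept` and character `filter_reason` columns.
#' @export
filter_molecules <- function(molecules, assay, primer, arm_prefix = "",
                             mapq_min = 20, min_aligned = NULL,
                             arm_prefix_max_mismatch = 1L) {
  if (is.null(min_aligned)) min_aligned <- min_aligned_for(assay)
  lp <- nchar(primer); la <- nchar(arm_prefix)
  prim_ok <- substr(molecules$consensus, 1L, lp) == primer
  if (la > 0) {
    arm_obs <- substr(molecules$consensus, lp + 1L, lp + la)
    full <- nchar(arm_obs) == la
    mm <- rep(NA_integer_, length(arm_obs))
    mm[full] <- la - vapply(which(full), function(i) {
      sum(strsplit(arm_obs[i], "")[[1]] == strsplit(arm_prefix, "")[[1]])
    }, integer(1))
    prim_ok <- prim_ok & full & mm <= arm_prefix_max_mismatch
  }
  reason <- rep(NA_character_, nrow(molecules))
  reason[!prim_ok] <- "primer_prefix"
  reason[molecules$aligned < min_aligned] <- "length"
  reason[molecules$mapq < mapq_min] <- "mapq"
  molecules$kept <- is.na(reason)
  molecules$filter_reason <- reason
  molecules
}

#' Classify unique molecules
#'
#' A molecule whose unaligned portion is shorter than `min_unaligned` bp is
#' the parental target locus (`mOTC_locus`).  Otherwise the unaligned portion
#' (the longest of: 3' soft clip, 5' soft clip, largest internal insertion)
#' is aligned in both orientations to every panel reference; the
#' best-scoring reference whose alignment covers at least `min_coverage` of
#' the portion at `min_identity` identity assigns the category, score ties
#' resolving by panel precedence (HDR > hOTCco > TBG > polyA > ITR > SaCas9 >
#' other_vector).  No qualifying hit yields `unclassified`.
#'
#' @param molecules data.frame with `consensus`, `read_start`, `read_end`,
#'   `clip_left`, `clip_right`, `max_ins`, `max_ins_pos` columns.
#' @param panel named references from [element_panel()].
#' @param min_unaligned minimum unaligned-portion length routed to
#'   classification.
#' @param min_coverage minimum fraction of the portion covered by the panel
#'   alignment.
#' @param min_identity minimum alignment identity
#'   (matches / alignment columns).
#' @param params [align_params()].
#' @return the input with `category`, `clip_seq`, `best_panel`, `best_score`
#'   columns.
#' @export
classify_molecules <- function(molecules, panel, min_unaligned = 10L,
                               min_coverage = 0.8, min_identity = 0.9,
                               params = align_params()) {
  n <- nrow(molecules)
  if (any(!nzchar(molecules$consensus)))
    stop("empty consensus sequence", call. = FALSE)
  lens <- cbind(right = molecules$clip_right, left = molecules$clip_left,
                ins = molecules$max_ins)
  pick <- apply(lens, 1L, which.max) # ties -> right > left > ins
  best_len <- lens[cbind(seq_len(n), pick)]
  clip <- rep(NA_character_, n)
  route <- best_len >= min_unaligned
  for (i in which(route)) {
    cs <- molecules$consensus[i]
    clip[i] <- switch(colnames(lens)[pick[i]],
      right = substr(cs, molecules$read_end[i] + 1L, nchar(cs)),
      left = substr(cs, 1L, molecules$read_start[i]),
      ins = substr(cs, molecules$max_ins_pos[i] + 1L,
                   molecules$max_ins_pos[i] + molecules$max_ins[i]))
  }
  category <- rep("mOTC_locus", n)
  best_panel <- rep(NA_character_, n)
  best_score <- rep(NA_integer_, n)

  uclip <- unique(clip[route])
  if (length(uclip)) {
    cls <- vapply(uclip, function(cs) {
      hit_label <- NA_character_; hit_score <- -1L
      cl <- nchar(cs)
      for (orient in c(cs, revcomp(cs))) {
        a <- cpp_align_batch(panel, orient, params$match, params$mismatch,
                             params$gap_open, params$gap_extend,
                             force_full = TRUE)
        # panel refs are the "reads" here so one call scores all references;
        # coverage/identity are computed on the clip (the subject)
        st <- cpp_cigar_stats(a$cigar)
        cov <- (a$ref_end - a$ref_start) / cl
        cols <- a$nmatch + a$nmismatch + st$ins_total + st$del_total
        ident <- ifelse(cols > 0, a$nmatch / cols, 0)
        ok <- cov >= min_coverage & ident >= min_identity
        if (any(ok)) {
          sc <- ifelse(ok, a$score, -1L)
          bi <- which.max(sc) # first max = panel precedence order
          if (sc[bi] > hit_score) { hit_score <- sc[bi]; hit_label <- names(panel)[bi] }
        }
      }
      c(label = hit_label, score = as.character(hit_score))
    }, character(2))
    idx <- match(clip[route], uclip)
    lab <- cls["label", idx]
    sc <- as.integer(cls["score", idx])
    category[route] <- ifelse(is.na(lab), "unclassified", panel_category(lab))
    best_panel[route] <- lab
    best_score[route] <- ifelse(sc < 0, NA_integer_, sc)
  }
  molecules$clip_seq <- clip
  molecules$category <- category
  molecules$best_panel <- best_panel
  molecules$best_score <- best_score
  molecules
}

#' HDR integration percentage
#'
#' `100 * n(HDR) / n(unique molecules after filtering)`, with the full
#' category breakdown (the vector-element composition table).
#'
#' @param molecules data.frame with `kept`, `filter_reason`, `category`
#'   columns (category may be NA for filtered molecules).
#' @param assay `"HaeIII"` or `"TaqI"`.
#' @return object of class `hdr_result`: `assay`, `counts` (named, all
#'   categories plus `filtered_out`), `total_after_filtering`, `hdr_percent`.
#' @export
hdr_percentage <- function(molecules, assay = c("HaeIII", "TaqI")) {
  assay <- match.arg(assay)
  kept <- molecules$kept
  total <- sum(kept)
  if (total == 0)
    stop(errorCondition("no unique molecules left after filtering; HDR percentage undefined",
                        class = c("editquant_undefined_percentage", "error")))
  counts <- setNames(integer(length(MOLECULE_CATEGORIES)), MOLECULE_CATEGORIES)
  tab <- table(molecules$category[kept])
  counts[names(tab)] <- as.integer(tab)
  counts <- c(counts, filtered_out = sum(!kept))
  structure(list(assay = assay, counts = counts,
                 total_after_filtering = total,
                 hdr_percent = 100 * counts[["HDR"]] / total),
            class = "hdr_result")
}

#' @export
print.hdr_result <- function(x, ...) {
  cat(sprintf("<hdr_result> %s assay: %d unique molecules after filtering, HDR %.3f%%\n",
              x$assay, x$total_after_filtering, x$hdr_percent))
  nz <- x$counts[x$counts > 0]
  cat(paste(sprintf("  %s: %d", names(nz), nz), collapse = "\n"), "\n")
  invisible(x)
}

#' LMU-PCR HDR-quantification pipeline
#'
#' UMI extraction, position anchoring, directional unique-molecule
#' identification, alignment of molecule consensuses to the target locus,
#' the three filtering rules, soft-clip classification against the element
#' panel, and the HDR percentage.  The primer-side read is the analysis unit
#' (LMU fragments are longer than the read-pair span); set `merge = TRUE` to
#' attempt overlap assembly first and analyse merged reads where assembly
#' succeeds.
#'
#' @param r1,r2 data.frames with `id`, `seq`, `qual` (R2 = adapter/UMI side),
#'   or FASTQ paths.
#' @param reference an `editquant_reference`, or a target-locus sequence (then
#'   `panel` and `primer`/`arm_prefix` must be given).
#' @param assay `"HaeIII"` or `"TaqI"`.
#' @param panel named panel references (defaults to `reference$panel`).
#' @param umi_length,adapter see [extract_umi_and_trim()].
#' @param mapq_min,min_aligned,arm_prefix_length filtering rules (see
#'   [filter_molecules()]).
#' @param min_unaligned,min_coverage,min_identity classification rules (see
#'   [classify_molecules()]).
#' @param merge attempt read-pair merging before grouping.
#' @param params [align_params()].
#' @return list: `result` (an `hdr_result`), `summary` (one-row data.frame),
#'   `molecules` (per-molecule audit).
#' @export
quantify_hdr <- function(r1, r2, reference, assay = c("HaeIII", "TaqI"),
                         panel = NULL, umi_length = 8L, adapter = lmu_adapter(),
                         mapq_min = 20, min_aligned = NULL,
                         arm_prefix_length = 10L, min_unaligned = 10L,
                         min_coverage = 0.8, min_identity = 0.9,
                         merge = FALSE, params = align_params()) {
  assay <- match.arg(assay)
  if (is.character(r1) && length(r1) == 1) r1 <- read_fastq(r1)
  if (is.character(r2) && length(r2) == 1) r2 <- read_fastq(r2)
  if (inherits(reference, "editquant_reference")) {
    locus_seq <- reference$locus$sequence
    if (is.null(panel)) panel <- reference$panel
    primer <- gsp3_sequence(reference$locus)
    arm_prefix <- substr0(locus_seq, reference$locus$gsp3_site[["end"]],
                          reference$locus$gsp3_site[["end"]] + arm_prefix_length)
  } else {
    locus_seq <- reference
    if (is.null(panel)) stop("panel required when reference is a bare sequence",
                             call. = FALSE)
    primer <- attr(reference, "primer")
    arm_prefix <- attr(reference, "arm_prefix")
    if (is.null(primer)) stop("primer attribute required", call. = FALSE)
    if (is.null(arm_prefix)) arm_prefix <- ""
  }

  ex <- extract_umi_and_trim(r1$seq, r2$seq, adapter, umi_length)
  n_pairs <- nrow(r1)
  keep <- ex$ok
  aseq <- ex$r1[keep]
  if (merge) {
    trim <- nchar(r2$seq[keep]) - nchar(ex$insert[keep]) # UMI + adapter bases
    m <- merge_pairs(ex$r1[keep], ex$insert[keep], r1$qual[keep],
                     substr(r2$qual[keep], trim + 1L, nchar(r2$qual[keep])))
    aseq <- ifelse(m$merged, m$seq, aseq)
  }
  umi <- ex$umi[keep]

  pos <- anchor_positions(aseq, locus_seq)
  anchored <- !is.na(pos)
  mols <- group_unique_molecules(umi[anchored], aseq[anchored], pos[anchored])

  aln <- align_to_reference(mols$consensus, locus_seq, params,
                            decoy = make_decoy(locus_seq))
  st <- cpp_cigar_stats(aln$cigar)
  mols$mapq <- aln$mapq
  mols$score <- aln$score
  mols$ref_start <- aln$ref_start; mols$ref_end <- aln$ref_end
  mols$read_start <- aln$read_start; mols$read_end <- aln$read_end
  mols$cigar <- aln$cigar
  mols$aligned <- st$aligned
  mols$clip_left <- st$clip_left; mols$clip_right <- st$clip_right
  mols$max_ins <- st$max_ins; mols$max_ins_pos <- st$max_ins_pos

  mols <- filter_molecules(mols, assay, primer, arm_prefix, mapq_min, min_aligned)
  mols$category <- NA_character_
  if (any(mols$kept)) {
    cl <- classify_molecules(mols[mols$kept, , drop = FALSE], panel,
                             min_unaligned, min_coverage, min_identity, params)
    mols$category[mols$kept] <- cl$category
    mols$clip_seq <- NA_character_; mols$best_panel <- NA_character_
    mols$clip_seq[mols$kept] <- cl$clip_seq
    mols$best_panel[mols$kept] <- cl$best_panel
  }
  res <- hdr_percentage(mols, assay)
  list(result = res,
       summary = data.frame(assay = assay, n_pairs = n_pairs,
                            n_umi_ok = sum(keep), n_anchored = sum(anchored),
                            n_molecules = nrow(mols),
                            total_after_filtering = res$total_after_filtering,
                            n_hdr = res$counts[["HDR"]],
                            hdr_percent = res$hdr_percent),
       molecules = mols)
}
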