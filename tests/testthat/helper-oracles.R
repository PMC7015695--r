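# Independent oracles used across the test suite.
#
# Each oracle re-derives a quantity by a different route from the production
# code: restriction sites via Biostrings::matchPattern, alignment scores via
# a vectorised-row dynamic program, UMI networks via Hamming-ball hashing,
# consensus via R column tallies, and molecule classification via an
# independent R implementation of the documented alignment/classification
# algorithm (local alignments are only defined up to ties, so the
# deterministic tie-break rules are part of the algorithm both routes
# implement).

ORACLE_BASES <- c("A", "C", "G", "T")

# all (possibly overlapping) recognition occurrences via matchPattern
oracle_sites <- function(sequence, recognition, cut_offset) {
  m <- Biostrings::matchPattern(recognition, Biostrings::DNAString(sequence))
  sort(BiocGenerics::start(m) - 1L + cut_offset)
}

# affine-gap local alignment score by a vectorised-row DP:
# I (gap in reference) from the previous row, D (gap in read) via the
# running-maximum identity D(i,j) = max_k<j H0(i,k) + e*k - o - e*j
oracle_sw_score <- function(read, ref, match = 1, mismatch = 4, gap_open = 6,
                            gap_extend = 1) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(s)
  oe <- gap_open + gap_extend
  NEG <- -1e9
  Hprev <- numeric(m + 1)
  Iprev <- rep(NEG, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    sub <- ifelse(r[i] == s, match, -mismatch)
    Irow <- pmax(Hprev - oe, Iprev - gap_extend)
    H0 <- pmax(0, c(0, Hprev[1:m] + sub), Irow)
    run <- cummax(H0 + gap_extend * (0:m))
    D <- c(NEG, run[1:m] - gap_open - gap_extend * (1:m))
    H <- pmax(H0, D)
    best <- max(best, H)
    Hprev <- H; Iprev <- Irow
  }
  best
}

# directional UMI clustering via Hamming-ball hashing (same documented
# algorithm as the production C++ route, independent machinery)
oracle_group_umis <- function(umis, counts) {
  k <- length(umis)
  ord <- order(-counts, umis)
  rnk <- integer(k); rnk[ord] <- seq_len(k)
  idx <- seq_len(k); names(idx) <- umis
  L <- nchar(umis[1])
  neigh <- vector("list", k)
  for (i in seq_len(k)) {
    u <- umis[i]
    cand <- character(0)
    for (p in seq_len(L)) {
      for (b in ORACLE_BASES) {
        if (substr(u, p, p) != b) { v <- u; substr(v, p, p) <- b; cand <- c(cand, v) }
      }
    }
    hit <- unname(idx[cand])
    hit <- hit[!is.na(hit)]
    neigh[[i]] <- hit[order(rnk[hit])]
  }
  cluster <- rep(NA_integer_, k)
  cid <- 0L
  for (s in ord) {
    if (!is.na(cluster[s])) next
    cid <- cid + 1L
    queue <- s; cluster[s] <- cid; qi <- 1L
    while (qi <= length(queue)) {
      a <- queue[qi]; qi <- qi + 1L
      for (b in neigh[[a]]) {
        if (is.na(cluster[b]) && counts[a] >= 2L * counts[b] - 1L) {
          cluster[b] <- cid; queue <- c(queue, b)
        }
      }
    }
  }
  cluster
}

# per-column majority consensus over reads of the modal length
# (ties: shorter length; base ties in A<C<G<T order)
oracle_consensus <- function(reads) {
  lens <- nchar(reads)
  tl <- sort(table(lens), decreasing = TRUE)
  cand <- as.integer(names(tl)[tl == tl[1]])
  L <- min(cand)
  reads <- reads[lens == L]
  if (length(unique(reads)) == 1) return(reads[1])
  codes <- matrix(match(unlist(strsplit(reads, "")), ORACLE_BASES),
                  nrow = length(reads), byrow = TRUE)
  paste(ORACLE_BASES[vapply(seq_len(L), function(j)
    which.max(tabulate(codes[, j], 4L)), integer(1))], collapse = "")
}

# Full affine-gap local alignment with traceback: an R implementation of the
# same documented algorithm as the production C++ aligner (vectorised-row
# forward pass, explicit tie-breaks: best cell = smallest reference end then
# smallest read end; step priority diagonal > deletion > insertion; gap
# opening preferred over extension on ties).  Local alignment is only
# well-defined up to ties, so the tie-break rules are part of the algorithm
# and both implementations must share them.
oracle_sw_align <- function(read, ref, match = 1, mismatch = 4, gap_open = 6,
                            gap_extend = 1) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(s)
  oe <- gap_open + gap_extend
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1) # gap in read (D op, ref consumed)
  F <- matrix(NEG, n + 1, m + 1) # gap in ref (I op, read consumed)
  for (i in seq_len(n)) {
    sub <- ifelse(r[i] == s, match, -mismatch)
    Frow <- pmax(H[i, ] - oe, F[i, ] - gap_extend)
    H0 <- pmax(0, c(0, H[i, 1:m] + sub), Frow)
    run <- cummax(H0 + gap_extend * (0:m))
    Erow <- c(NEG, run[1:m] - gap_open - gap_extend * (1:m))
    H[i + 1, ] <- pmax(H0, Erow)
    E[i + 1, ] <- Erow
    F[i + 1, ] <- Frow
  }
  best <- max(H)
  out <- list(score = best, read_start = 0L, read_end = 0L, ref_start = 0L,
              ref_end = 0L, nmatch = 0L, nmismatch = 0L, aligned = 0L,
              clip_left = 0L, clip_right = n, max_ins = 0L,
              max_ins_pos = NA_integer_, ins_total = 0L, del_total = 0L)
  if (best <= 0) return(out)
  cand <- which(H == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  i <- unname(cand[1, 1]) - 1L; j <- unname(cand[1, 2]) - 1L # 1..n / 1..m cells
  out$read_end <- i; out$ref_end <- j
  state <- "H"
  ins_len <- 0L
  # consecutive I steps form one run even across gap reopenings (as in the
  # production CIGAR); a run closes at the next diagonal or deletion step
  close_run <- function(at) {
    if (ins_len > 0L &&
        (ins_len > out$max_ins || ins_len == out$max_ins)) {
      out$max_ins <<- ins_len
      out$max_ins_pos <<- at
    }
    ins_len <<- 0L
  }
  while (i > 0 && j > 0) {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (h <= 0) break
      diag <- H[i, j] + (if (r[i] == s[j]) match else -mismatch)
      if (h == diag) {
        close_run(i)
        if (r[i] == s[j]) out$nmatch <- out$nmatch + 1L
        else out$nmismatch <- out$nmismatch + 1L
        out$aligned <- out$aligned + 1L
        i <- i - 1L; j <- j - 1L
      } else if (h == E[i + 1, j + 1]) {
        close_run(i)
        state <- "E"
      } else state <- "F"
    } else if (state == "E") {
      out$del_total <- out$del_total + 1L
      open <- H[i + 1, j] - oe
      state <- if (E[i + 1, j + 1] == open) "H" else "E"
      j <- j - 1L
    } else { # F
      out$ins_total <- out$ins_total + 1L
      ins_len <- ins_len + 1L
      open <- H[i, j + 1] - oe
      state <- if (F[i + 1, j + 1] == open) "H" else "F"
      i <- i - 1L
    }
  }
  close_run(i)
  out$read_start <- i; out$ref_start <- j
  out$clip_left <- i
  out$clip_right <- n - out$read_end
  out
}

# per-consensus record: locus-alignment statistics, primer check, and the
# (assay-independent) classification decision, mirroring the documented
# rules with the independent R aligner; memoised across assays via `cache`
oracle_consensus_record <- function(consensus, locus, decoy, panel, primer,
                                    arm_prefix, min_unaligned = 10,
                                    min_coverage = 0.8, min_identity = 0.9,
                                    cache = new.env(parent = emptyenv())) {
  apc <- strsplit(arm_prefix, "")[[1]]
  one <- function(cs) {
    key <- cs
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    st <- oracle_sw_align(cs, locus)
    dsc <- oracle_sw_score(cs, decoy)
    mapq <- min(60, max(0, st$score - dsc))
    prim_ok <- substr(cs, 1, nchar(primer)) == primer
    if (prim_ok && length(apc) > 0) {
      obs <- strsplit(substr(cs, nchar(primer) + 1,
                             nchar(primer) + length(apc)), "")[[1]]
      prim_ok <- length(obs) == length(apc) && sum(obs != apc) <= 1
    }
    lens <- c(right = st$clip_right, left = st$clip_left, ins = st$max_ins)
    pick <- which.max(lens)
    if (lens[pick] < min_unaligned) {
      category <- "mOTC_locus"
    } else {
      clip <- switch(names(lens)[pick],
                     right = substr(cs, nchar(cs) - st$clip_right + 1, nchar(cs)),
                     left = substr(cs, 1, st$clip_left),
                     ins = substr(cs, st$max_ins_pos + 1,
                                  st$max_ins_pos + st$max_ins))
      cl <- nchar(clip)
      hit_label <- NA_character_; hit_score <- -1
      for (orient in c(clip, editquant::revcomp(clip))) {
        sc <- rep(-1, length(panel)); ok <- logical(length(panel))
        for (t in seq_along(panel)) {
          a <- oracle_sw_align(panel[[t]], orient) # panel plays the read role
          cov <- (a$ref_end - a$ref_start) / cl
          cols <- a$nmatch + a$nmismatch + a$ins_total + a$del_total
          ident <- if (cols > 0) a$nmatch / cols else 0
          ok[t] <- cov >= min_coverage && ident >= min_identity
          sc[t] <- if (ok[t]) a$score else -1
        }
        if (any(ok)) {
          bi <- which.max(sc)
          if (sc[bi] > hit_score) { hit_score <- sc[bi]; hit_label <- names(panel)[bi] }
        }
      }
      category <- if (is.na(hit_label)) "unclassified"
      else if (hit_label %in% c("HDR_left", "HDR_right")) "HDR"
      else hit_label
    }
    rec <- list(mapq = mapq, aligned = st$aligned, prim_ok = prim_ok,
                category = category)
    cache[[key]] <- rec
    rec
  }
  recs <- lapply(consensus, one)
  data.frame(mapq = vapply(recs, `[[`, numeric(1), "mapq"),
             aligned = vapply(recs, `[[`, integer(1), "aligned"),
             prim_ok = vapply(recs, `[[`, logical(1), "prim_ok"),
             category = vapply(recs, `[[`, character(1), "category"),
             stringsAsFactors = FALSE)
}

# full filter + classification decisions for a vector of consensuses
oracle_classify <- function(consensus, locus, decoy, panel, primer, arm_prefix,
                            assay, mapq_min = 20, min_unaligned = 10,
                            min_coverage = 0.8, min_identity = 0.9,
                            cache = new.env(parent = emptyenv())) {
  st <- oracle_consensus_record(consensus, locus, decoy, panel, primer,
                                arm_prefix, min_unaligned, min_coverage,
                                min_identity, cache)
  min_aligned <- c(HaeIII = 60L, TaqI = 55L)[[assay]]
  out <- st$category
  out[!st$prim_ok] <- "filtered:primer_prefix"
  out[st$aligned < min_aligned] <- "filtered:length"
  out[st$mapq < mapq_min] <- "filtered:mapq"
  out
}

# Expected unique-molecule categories of an LMU library, recomputed from the
# truth table and the raw reads by the oracle chain (grouping -> consensus ->
# filters -> classification).  Returns the per-cluster category vector keyed
# by representative UMI.
oracle_lmu_expectation <- function(lmu, reference, assay,
                                   arm_prefix_length = 10L,
                                   cache = new.env(parent = emptyenv())) {
  locus <- reference$locus$sequence
  decoy <- editquant::make_decoy(locus)
  primer <- substr(locus, reference$locus$gsp3_site[["start"]] + 1,
                   reference$locus$gsp3_site[["end"]])
  arm_prefix <- substr(locus, reference$locus$gsp3_site[["end"]] + 1,
                       reference$locus$gsp3_site[["end"]] + arm_prefix_length)
  umi_len <- nchar(lmu$truth$umi[1])
  read_umi <- substr(lmu$r2$seq, 1, umi_len)
  cnt <- table(read_umi)
  umis <- names(cnt); counts <- as.integer(cnt)
  cl <- oracle_group_umis(umis, counts)
  read_cl <- cl[match(read_umi, umis)]
  cons <- vapply(split(lmu$r1$seq, read_cl), oracle_consensus, character(1))
  ucons <- unique(cons)
  ucat <- oracle_classify(ucons, locus = locus, decoy = decoy,
                          panel = reference$panel, primer = primer,
                          arm_prefix = arm_prefix, assay = assay,
                          cache = cache)
  cats <- ucat[match(cons, ucons)]
  rep_umi <- character(max(cl))
  for (i in order(-counts, umis)) {
    if (rep_umi[cl[i]] == "") rep_umi[cl[i]] <- umis[i]
  }
  names(cats) <- rep_umi[as.integer(names(cons))]
  cats
}

# expected HDR percentage from oracle categories
oracle_hdr_percent <- function(cats) {
  kept <- !startsWith(cats, "filtered:")
  100 * sum(cats[kept] == "HDR") / sum(kept)
}
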