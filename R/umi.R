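# UMI handling: extraction from the adapter-side mate, position anchoring of
# the primer-side read, and directional unique-molecule identification.

#' Extract UMIs and trim the adapter
#'
#' The adapter-side mate is laid out `[UMI][adapter][insert]`.  The adapter is
#' located allowing one mismatch per 10 adapter bases (expected position
#' first, then a scan); the UMI is the `umi_length` bases before it and the
#' insert is everything after it.  Pairs whose adapter cannot be found, or
#' whose UMI is truncated, are flagged for exclusion.
#'
#' @param r1,r2 mate sequences; `r2` is the adapter-side mate.
#' @param adapter adapter sequence (default [lmu_adapter()]).
#' @param umi_length UMI length.
#' @return data.frame: `umi`, `r1`, `insert` (adapter-side insert), `ok`,
#'   `reason`.
#' @export
extract_umi_and_trim <- function(r1, r2, adapter = lmu_adapter(), umi_length = 8L) {
  stopifnot(length(r1) == length(r2))
  max_mm <- nchar(adapter) %/% 10L
  pos <- cpp_find_adapter(r2, adapter, max_mm, as.integer(umi_length))
  ok <- pos == umi_length # full-length UMI directly before the adapter
  umi <- ifelse(ok, substr(r2, pos - umi_length + 1L, pos), NA_character_)
  insert <- ifelse(ok, substr(r2, pos + nchar(adapter) + 1L, nchar(r2)), NA_character_)
  reason <- ifelse(pos < 0, "adapter-missing",
                   ifelse(ok, NA_character_, "umi-truncated"))
  data.frame(umi = umi, r1 = r1, insert = insert, ok = ok, reason = reason,
             stringsAsFactors = FALSE)
}

# anchor each read's reference start position via the first exact k-mer at a
# few read offsets; NA when no offset anchors (such reads are dropped by the
# pipeline and logged)
anchor_positions <- function(reads, ref, k = 15L, offsets = c(0L, 20L, 40L)) {
  n <- nchar(ref)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(ref, starts, starts + k - 1L)
  first <- !duplicated(kmers)
  tab <- setNames(starts[first] - 1L, kmers[first])
  pos <- rep(NA_integer_, length(reads))
  for (off in offsets) {
    miss <- is.na(pos) & nchar(reads) >= off + k
    if (!any(miss)) break
    key <- substr(reads[miss], off + 1L, off + k)
    hit <- tab[key]
    pos[miss] <- ifelse(is.na(hit), NA_integer_, hit - off)
  }
  pos
}

#' Identify unique molecules from UMI-tagged reads
#'
#' Groups reads by (alignment start position, UMI network).  The UMI network
#' uses directional adjacency: UMIs at Hamming distance 1 are merged when
#' `count(a) >= 2 * count(b) - 1`, seeds taken in (count desc, UMI asc)
#' order, clusters grown by breadth-first search.  The molecule consensus is
#' the per-column majority over the group's reads (reads of the modal length
#' vote; base ties resolve in A<C<G<T order).
#'
#' @param umi UMI per read.
#' @param seq analysis-read sequence per read (the primer-side read, or the
#'   merged read when the fragment is short enough to assemble).
#' @param position alignment start position per read (single-position data
#'   may pass 0).
#' @return data.frame (class `umi_molecules`): `position`, `umi`
#'   (representative = highest-count network member), `n_umis`, `read_count`,
#'   `consensus`.
#' @export
group_unique_molecules <- function(umi, seq, position = 0L) {
  stopifnot(length(umi) == length(seq))
  position <- rep_len(as.integer(position), length(umi))
  out <- list()
  for (p in sort(unique(position))) {
    sel <- which(position == p)
    cnt <- table(umi[sel])
    umis <- names(cnt)
    counts <- as.integer(cnt)
    cl <- cpp_umi_cluster(umis, counts)
    # representative: first by (count desc, umi asc) within each cluster
    ord <- order(-counts, umis)
    rep_umi <- character(max(cl))
    for (i in ord) if (rep_umi[cl[i]] == "" || is.na(rep_umi[cl[i]])) rep_umi[cl[i]] <- umis[i]
    read_cl <- cl[match(umi[sel], umis)]
    by_cl <- split(seq[sel], read_cl)
    cons <- vapply(by_cl, function(rs)
      as.character(cpp_consensus(rs, rep(1L, length(rs)))), character(1))
    cons <- unname(cons[as.character(seq_len(max(cl)))])
    out[[length(out) + 1L]] <- data.frame(
      position = p,
      umi = rep_umi,
      n_umis = as.integer(tabulate(cl)),
      read_count = as.integer(tabulate(read_cl)),
      consensus = cons,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("umi_molecules", "data.frame")
  res
}
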