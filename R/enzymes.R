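#' Restriction enzyme model
#'
#' A minimal enzyme description for in-silico digestion: recognition sequence
#' and the cut offset within it.  Cut positions are 0-based between-base
#' offsets, so an enzyme with recognition `GGCC` and `cut_offset = 2` cuts
#' between the two Gs and the two Cs (blunt, as HaeIII does).
#'
#' @param name enzyme name.
#' @param recognition uppercase recognition sequence (A/C/G/T).
#' @param cut_offset integer offset of the cut within the recognition site,
#'   `0 <= cut_offset <= nchar(recognition)`.
#' @return an object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("HaeIII", "GGCC", 2)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  check_dna(recognition, "recognition")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  structure(list(name = name, recognition = recognition, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s (cut at +%d)\n",
              x$name, x$recognition, x$cut_offset))
  invisible(x)
}

#' Default LMU-PCR enzymes
#'
#' HaeIII (GGCC, blunt) and TaqI (TCGA, cutting after the T); both
#' recognition sites are palindromic, so forward-strand scanning finds every
#' site.
#'
#' @return named list of [restriction_enzyme()] objects.
#' @export
lmu_enzymes <- function() {
  list(HaeIII = restriction_enzyme("HaeIII", "GGCC", 2L),
       TaqI   = restriction_enzyme("TaqI",   "TCGA", 1L))
}

as_enzyme <- function(enzyme) {
  if (inherits(enzyme, "restriction_enzyme")) return(enzyme)
  if (is.character(enzyme) && length(enzyme) == 1) {
    enz <- lmu_enzymes()
    hit <- match(tolower(enzyme), tolower(names(enz)))
    if (!is.na(hit)) return(enz[[hit]])
  }
  stop("unknown enzyme: supply a restriction_enzyme or one of ",
       paste(names(lmu_enzymes()), collapse = ", "), call. = FALSE)
}

#' Find restriction cut positions
#'
#' Scans the forward strand for every (possibly overlapping) occurrence of the
#' enzyme's recognition sequence and returns the corresponding cut positions
#' as 0-based between-base offsets, strictly increasing.  The default enzymes
#' are palindromic, so reverse-strand scanning would be redundant;
#' non-palindromic enzymes would need both strands and are not part of the
#' default set.
#'
#' @param sequence uppercase DNA string.
#' @param enzyme a [restriction_enzyme()] or its name.
#' @return integer vector of cut positions.
#' @examples
#' find_restriction_sites("AAGGCCAA", "HaeIII") # 4
#' @export
find_restriction_sites <- function(sequence, enzyme) {
  check_dna(sequence)
  enzyme <- as_enzyme(enzyme)
  len <- nchar(enzyme$recognition)
  n <- nchar(sequence)
  if (n < len) return(integer(0))
  starts <- seq_len(n - len + 1L)
  hits <- which(substring(sequence, starts, starts + len - 1L) == enzyme$recognition)
  as.integer(hits - 1L + enzyme$cut_offset)
}

#' Digest a sequence in silico
#'
#' Splits the sequence at every cut position of the enzyme.  The concatenation
#' of the fragments always reproduces the input; a site-free sequence returns
#' a single fragment.
#'
#' @inheritParams find_restriction_sites
#' @return character vector of fragments, 5' to 3'.
#' @examples
#' digest_sequence("AAGGCCAA", "HaeIII") # "AAGG" "CCAA"
#' @export
digest_sequence <- function(sequence, enzyme) {
  cuts <- find_restriction_sites(sequence, enzyme)
  bounds <- c(0L, cuts, nchar(sequence))
  substring(sequence, head(bounds, -1L) + 1L, bounds[-1L])
}
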