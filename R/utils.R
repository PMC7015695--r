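# shared helpers: seeded RNG scoping, random sequence, reverse complement,
# Phred encoding

# Derive a function-specific RNG seed from the user seed: each stochastic
# builder/simulator mixes in its own stream id so that passing the same user
# seed to two different functions never replays one function's draws inside
# another (random reference sequence leaking into "random" inserts, say).
seed_stream <- function(seed, id) {
  as.integer((as.double(seed) %% 2147483647) * 48271 %% 2147483647 +
               id * 100003) %% 2147483647L
}

# evaluate `code` under set.seed(seed) without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse each string (for qualities accompanying a reverse-complemented read)
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# constant Phred+33 quality strings encoding a per-base error rate
phred_string <- function(error_rate, n) {
  q <- if (error_rate <= 0) 41L else max(2L, min(41L, as.integer(round(-10 * log10(error_rate)))))
  vapply(n, function(len) strrep(rawToChar(as.raw(33L + q)), len), character(1))
}

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) == 0)
    stop(what, " must be a single non-empty character string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " must be uppercase DNA (A/C/G/T only)", call. = FALSE)
  invisible(x)
}

# 0-based half-open interval helper
interval <- function(start, end) {
  stopifnot(start < end)
  c(start = as.integer(start), end = as.integer(end))
}

substr0 <- function(x, start, end) {
  # 0-based half-open extraction
  substr(x, start + 1L, end)
}

# sample() without the scalar-x surprise
safe_sample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
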