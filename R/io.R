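# File interfaces: FASTA (references), FASTQ (reads, Phred+33), TSV truth
# tables, JSON run configuration.  Sequence IO goes through Biostrings.

#' Write the reference set as FASTA
#'
#' Writes `locus.fasta`, `donor.fasta`, `nuclease.fasta` (one record each) and
#' `panel.fasta` (one record per classification reference, labels in headers)
#' into `dir`.
#'
#' @param reference an `editquant_reference`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_reference_fasta <- function(reference, dir) {
  stopifnot(inherits(reference, "editquant_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(seqs, file) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                filepath = file.path(dir, file))
    file.path(dir, file)
  }
  paths <- c(
    w(setNames(reference$locus$sequence, reference$locus$name), "locus.fasta"),
    w(setNames(reference$donor$sequence, reference$donor$name), "donor.fasta"),
    w(setNames(reference$nuclease$sequence, reference$nuclease$name), "nuclease.fasta"),
    w(reference$panel, "panel.fasta"))
  invisible(paths)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param id,seq,qual parallel character vectors.
#' @param path output file.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read and validate a run configuration
#'
#' Flat JSON key-value configuration.  Unknown keys are rejected so typos do
#' not silently fall back to defaults.
#'
#' @param path JSON file.
#' @param allowed character vector of permitted keys (`NULL` accepts all).
#' @return named list.
#' @export
read_run_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("config must be a JSON object", call. = FALSE)
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# JSON-lines audit trail
write_jsonl <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}
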