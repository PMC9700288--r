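#' Read a FASTA file into a tibble
#'
#' Multi-line FASTA is accepted; sequences are uppercased, `U` becomes `T`,
#' and any other non-`ACGTN` character becomes `N` (with a warning counting
#' the replacements).
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Tibble with columns `seq_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  tibble(
    seq_id = ids,
    sequence = unname(normalize_sequence(as.character(ss), context = path))
  )
}

#' Write sequences to FASTA
#'
#' @param records Tibble with an id column (`seq_id`, `fragment_id` or
#'   `read_id`) and a `sequence` column, or a named character vector.
#' @param path Output path.
#' @param line_width Sequence line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  records <- as_seq_tbl(records)
  if (nrow(records) > 0 && any(records$seq_id == "")) abort("empty sequence id")
  ss <- Biostrings::DNAStringSet(setNames(records$sequence, records$seq_id))
  Biostrings::writeXStringSet(ss, path, width = line_width)
  invisible(path)
}
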