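#' Read a FASTQ file into a tibble
#'
#' Strict 4-line-per-record FASTQ with Phred+33 qualities.  Malformed records
#' raise a parse error naming the offending line.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `read_id` (character), `sequence`
#'   (character, normalised to `ACGTN`) and `qualities` (list of integer
#'   Phred scores, one per base).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sequence = character(),
                  qualities = list()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf("truncated FASTQ record starting at line %d of %s",
                  4L * (length(lines) %/% 4L) + 1L, path))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0) {
    abort(sprintf("FASTQ parse error: line %d does not start with '@'",
                  idx[bad_hdr[1]]))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0) {
    abort(sprintf("FASTQ parse error: line %d does not start with '+'",
                  idx[bad_plus[1]] + 2L))
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len) > 0) {
    abort(sprintf(
      "FASTQ parse error: sequence/quality length mismatch at line %d",
      idx[bad_len[1]] + 3L))
  }
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("FASTQ parse error: empty sequence at line %d",
                  idx[which(nchar(seqs) == 0)[1]] + 1L))
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  if (any(ids == "")) abort("FASTQ parse error: empty read id")
  tibble(
    read_id = ids,
    sequence = normalize_sequence(seqs, context = path),
    qualities = lapply(qual, decode_phred)
  )
}

#' Decode / encode Phred+33 quality strings
#'
#' @param q A single quality string (`decode_phred`) or an integer vector of
#'   Phred scores (`encode_phred`).
#' @return Integer vector of scores, or a quality string.
#' @export
decode_phred <- function(q) {
  utf8ToInt(q) - 33L
}

#' @rdname decode_phred
#' @export
encode_phred <- function(q) {
  intToUtf8(pmin(pmax(as.integer(q), 0L), 93L) + 33L)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Tibble with `read_id`, `sequence` and `qualities` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_tibble(reads)
  if (nrow(reads) > 0 && any(reads$read_id == "")) abort("empty read id")
  lines <- character(4L * nrow(reads))
  if (nrow(reads) > 0) {
    lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
    lines[seq(2, length(lines), 4)] <- reads$sequence
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <-
      vapply(reads$qualities, encode_phred, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}
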