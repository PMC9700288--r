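#' Reverse complement
#'
#' @param x Character vector of DNA sequences over `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAN"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

# Uppercase, U -> T, anything outside ACGTN -> N (with a warning that counts
# the replacements).  The single normalisation point for all sequence input.
normalize_sequence <- function(x, context = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- stringr::str_count(x, "[^ACGTN]")
  n_bad <- sum(bad)
  if (n_bad > 0) {
    x <- stringr::str_replace_all(x, "[^ACGTN]", "N")
    warn(sprintf("%s: replaced %d non-ACGTN character(s) with N", context, n_bad))
  }
  x
}

# Standardise a table of sequences: first of seq_id / read_id / fragment_id
# becomes `seq_id`; a `sequence` column is required.
as_seq_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(tibble(seq_id = ids, sequence = unname(x)))
  }
  x <- as_tibble(x)
  idcol <- intersect(c("seq_id", "fragment_id", "read_id"), names(x))[1]
  if (is.na(idcol)) abort("no id column (seq_id / fragment_id / read_id) found")
  if (!"sequence" %in% names(x)) abort("no `sequence` column found")
  tibble(seq_id = as.character(x[[idcol]]), sequence = x$sequence)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Derive a reproducible child seed from a base seed and a stream label,
# keeping the result inside 32-bit integer range.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}
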