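#' Parse Kraken2-style per-sequence classification output
#'
#' Standard 5-column format: `C`/`U`, sequence id, call taxid, sequence
#' length, and a space-separated LCA mapping string of `taxid:count` tokens.
#' Ambiguous-base tokens (`A:count`) are retained with their marker.
#'
#' @param line Character vector of classification lines.
#' @return Tibble with columns `seq_id`, `classified` (logical), `taxid`
#'   (integer) and `lca` (list of tibbles with character `taxid` -- `"A"`
#'   marks ambiguous entries -- and integer `count`).
#' @export
#' @examples
#' parse_kraken2_line("C\tf1\t562\t600\t562:10 0:5")
parse_kraken2_line <- function(line) {
  if (length(line) == 0) return(empty_kraken())
  fields <- strsplit(line, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 5L)
  if (length(short) > 0) {
    abort(sprintf("classification parse error: line %d has %d fields (5 required)",
                  short[1], lengths(fields)[short[1]]))
  }
  m <- t(vapply(fields, function(f) f[1:5], character(5)))
  bad <- which(!m[, 1] %in% c("C", "U"))
  if (length(bad) > 0) {
    abort(sprintf("classification parse error: line %d: unknown status '%s'",
                  bad[1], m[bad[1], 1]))
  }
  lca <- lapply(seq_len(nrow(m)), function(i) parse_lca(m[i, 5], i))
  out <- tibble(
    seq_id = m[, 2],
    classified = m[, 1] == "C",
    taxid = as.integer(m[, 3]),
    lca = lca
  )
  if (any(!out$classified & out$taxid != 0L)) {
    abort("classification parse error: unclassified record with nonzero taxid")
  }
  out
}

parse_lca <- function(s, line_no) {
  toks <- strsplit(trimws(s), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) {
    return(tibble(taxid = character(), count = integer()))
  }
  parts <- strsplit(toks, ":", fixed = TRUE)
  ok <- lengths(parts) == 2L &
    vapply(parts, function(p) p[1] == "A" || grepl("^[0-9]+$", p[1]), logical(1)) &
    vapply(parts, function(p) grepl("^[0-9]+$", p[2]), logical(1))
  if (any(!ok)) {
    abort(sprintf("classification parse error: line %d: malformed token '%s'",
                  line_no, toks[which(!ok)[1]]))
  }
  counts <- as.integer(vapply(parts, `[`, character(1), 2))
  if (any(counts < 1L)) {
    abort(sprintf("classification parse error: line %d: k-mer count < 1", line_no))
  }
  tibble(taxid = vapply(parts, `[`, character(1), 1), count = counts)
}

empty_kraken <- function() {
  tibble(seq_id = character(), classified = logical(), taxid = integer(),
         lca = list())
}

#' @rdname parse_kraken2_line
#' @param path Path to a classification file.
#' @export
read_kraken2 <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  parse_kraken2_line(lines[nzchar(lines)])
}

#' Write classification calls in Kraken2-style 5-column format
#'
#' @param calls Tibble as returned by [parse_kraken2_line()]; an optional
#'   `seq_len` column is used for column 4 (else 0).
#' @param path Output path.
#' @export
write_kraken2 <- function(calls, path) {
  len <- if ("seq_len" %in% names(calls)) calls$seq_len else rep(0L, nrow(calls))
  lca <- vapply(calls$lca, function(l) {
    if (nrow(l) == 0) "" else paste(sprintf("%s:%d", l$taxid, l$count), collapse = " ")
  }, character(1))
  lines <- sprintf("%s\t%s\t%d\t%d\t%s",
                   ifelse(calls$classified, "C", "U"), calls$seq_id,
                   calls$taxid, as.integer(len), lca)
  writeLines(lines, path)
  invisible(path)
}
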