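paf_cols <- c("query_id", "query_len", "q_start", "q_end", "strand",
              "target_id", "target_len", "t_start", "t_end",
              "n_matches", "block_len", "mapq")

validate_paf <- function(df, context = "PAF") {
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0) abort(sprintf("%s validation error (record %d): %s",
                                     context, i[1], msg))
  }
  bad(df$q_start < 0 | df$q_start >= df$q_end | df$q_end > df$query_len,
      "query interval must satisfy 0 <= q_start < q_end <= query_len")
  bad(df$t_start < 0 | df$t_start >= df$t_end | df$t_end > df$target_len,
      "target interval must satisfy 0 <= t_start < t_end <= target_len")
  bad(df$n_matches <= 0 | df$n_matches > df$block_len,
      "matches must satisfy 0 < n_matches <= block_len")
  bad(!df$strand %in% c("+", "-"), "strand must be '+' or '-'")
  df
}

paf_from_fields <- function(fields, context = "PAF") {
  short <- which(lengths(fields) < 12L)
  if (length(short) > 0) {
    abort(sprintf("%s parse error: line %d has %d fields (12 required)",
                  context, short[1], lengths(fields)[short[1]]))
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  df <- tibble(
    query_id = m[, 1],
    query_len = as.integer(m[, 2]),
    q_start = as.integer(m[, 3]),
    q_end = as.integer(m[, 4]),
    strand = m[, 5],
    target_id = m[, 6],
    target_len = as.integer(m[, 7]),
    t_start = as.integer(m[, 8]),
    t_end = as.integer(m[, 9]),
    n_matches = as.integer(m[, 10]),
    block_len = as.integer(m[, 11]),
    mapq = as.integer(m[, 12])
  )
  df <- validate_paf(df, context)
  df$identity <- df$n_matches / df$block_len
  df
}

#' Parse PAF alignment lines
#'
#' PAF columns 1--12 (minimap2 dialect) are parsed; optional tags beyond
#' column 12 are ignored.  Coordinates are 0-based half-open; query
#' coordinates are always on the forward query strand.
#'
#' @param line Character vector of tab-separated PAF lines.
#' @return A tibble of alignment records with an added `identity` column
#'   (`n_matches / block_len`).
#' @export
#' @examples
#' parse_paf("r1\t1000\t0\t400\t+\tchr1\t5000\t100\t500\t380\t400\t60")
parse_paf <- function(line) {
  if (length(line) == 0) return(empty_paf())
  paf_from_fields(strsplit(line, "\t", fixed = TRUE))
}

#' @rdname parse_paf
#' @param path Path to a PAF file.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  paf_from_fields(strsplit(lines, "\t", fixed = TRUE), context = path)
}

empty_paf <- function() {
  tibble(query_id = character(), query_len = integer(), q_start = integer(),
         q_end = integer(), strand = character(), target_id = character(),
         target_len = integer(), t_start = integer(), t_end = integer(),
         n_matches = integer(), block_len = integer(), mapq = integer(),
         identity = double())
}

#' Format / write alignment records as PAF
#'
#' Columns 1--12 plus an `id:f:` identity tag.
#'
#' @param aln Tibble of alignment records (as from [parse_paf()] or
#'   [minialign()]).
#' @return `format_paf` returns a character vector of PAF lines.
#' @export
format_paf <- function(aln) {
  if (nrow(aln) == 0) return(character())
  if (!"mapq" %in% names(aln)) aln$mapq <- 255L
  sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\tid:f:%.4f",
          aln$query_id, aln$query_len, aln$q_start, aln$q_end, aln$strand,
          aln$target_id, aln$target_len, aln$t_start, aln$t_end,
          aln$n_matches, aln$block_len, aln$mapq,
          aln$n_matches / aln$block_len)
}

#' @rdname format_paf
#' @param path Output path.
#' @export
write_paf <- function(aln, path) {
  writeLines(format_paf(aln), path)
  invisible(path)
}
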