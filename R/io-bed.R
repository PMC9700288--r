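#' Write intervals as BED5
#'
#' Coordinates are written as-is (the package is 0-based half-open
#' throughout, which is BED's native convention).
#'
#' @param x Tibble with columns `target_id`, `start`, `end`, `name` and
#'   `score` (e.g. cluster support).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_tibble(x)
  need <- c("target_id", "start", "end", "name", "score")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("BED output requires columns: %s", paste(missing, collapse = ", ")))
  }
  if (nrow(x) > 0 && any(x$start < 0 | x$end < x$start)) {
    abort("invalid BED interval (start < 0 or end < start)")
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", x$target_id, as.integer(x$start),
                   as.integer(x$end), x$name, format(x$score, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED5 file
#'
#' @param path Path to a BED file with at least 5 columns.
#' @return Tibble with columns `target_id`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(target_id = character(), start = integer(), end = integer(),
                  name = character(), score = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5)) {
    abort(sprintf("BED parse error: line %d has fewer than 5 columns",
                  which(lengths(fields) < 5)[1]))
  }
  m <- t(vapply(fields, function(f) f[1:5], character(5)))
  tibble(target_id = m[, 1], start = as.integer(m[, 2]),
         end = as.integer(m[, 3]), name = m[, 4], score = m[, 5])
}
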