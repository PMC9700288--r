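# Interval arithmetic on 0-based half-open tibbles, backed by IRanges.

as_interval_tbl <- function(start, end) {
  tibble(start = as.integer(start), end = as.integer(end))
}

empty_intervals <- function() as_interval_tbl(integer(), integer())

check_intervals <- function(x) {
  if (nrow(x) > 0 && any(x$start < 0 | x$end <= x$start)) {
    abort("invalid interval: need 0 <= start < end")
  }
  x
}

#' Merge overlapping or adjacent intervals
#'
#' @param x Tibble with integer `start`, `end` (0-based half-open).
#' @return Tibble of sorted, disjoint merged intervals.
#' @export
interval_merge <- function(x) {
  x <- check_intervals(as_tibble(x))
  if (nrow(x) == 0) return(empty_intervals())
  r <- IRanges::reduce(IRanges::IRanges(start = x$start + 1L, end = x$end))
  as_interval_tbl(IRanges::start(r) - 1L, IRanges::end(r))
}

#' Complement of intervals within `[0, len)`
#'
#' @param x Tibble of intervals (need not be disjoint).
#' @param len Total length of the enclosing sequence.
#' @return Tibble of the uncovered intervals, sorted and disjoint.
#' @export
interval_complement <- function(x, len) {
  x <- check_intervals(as_tibble(x))
  len <- as.integer(len)
  if (nrow(x) > 0 && any(x$end > len)) abort("interval exceeds sequence length")
  if (nrow(x) == 0) {
    if (len == 0) return(empty_intervals())
    return(as_interval_tbl(0L, len))
  }
  r <- IRanges::IRanges(start = x$start + 1L, end = x$end)
  g <- IRanges::gaps(r, start = 1L, end = len)
  as_interval_tbl(IRanges::start(g) - 1L, IRanges::end(g))
}

# Total covered length of a set of (possibly overlapping) intervals.
interval_covered <- function(x) {
  m <- interval_merge(x)
  sum(m$end - m$start)
}
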