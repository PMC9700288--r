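# Triplet code sequence: integer in 0..63 per overlapping 3-mer, NA where
# the 3-mer touches a non-ACGT base.
triplet_codes <- function(sequence) {
  n <- nchar(sequence)
  if (n < 3) return(integer(0))
  b <- utf8ToInt(sequence)
  code <- rep(NA_integer_, n)
  code[b == utf8ToInt("A")] <- 0L
  code[b == utf8ToInt("C")] <- 1L
  code[b == utf8ToInt("G")] <- 2L
  code[b == utf8ToInt("T")] <- 3L
  code[1:(n - 2)] * 16L + code[2:(n - 1)] * 4L + code[3:n]
}

#' Low-complexity masking by triplet entropy (DUST-style)
#'
#' Slides a window over the sequence; the window score is
#' `10 * sum(c_t * (c_t - 1) / 2) / (L - 3)` over the counts `c_t` of its
#' overlapping triplets.  Every window whose score strictly exceeds
#' `score_threshold` is masked, and masked windows are merged into maximal
#' intervals.  `N` is never masked by itself but breaks windows.
#'
#' @param sequence A single DNA string over `ACGTN`.
#' @param window Window length (default 64).
#' @param score_threshold Score cutoff (default 20; a homopolymer scores in
#'   the hundreds, random sequence around 5).
#' @return Tibble of masked `start`/`end` intervals (0-based half-open).
#' @export
dust_mask <- function(sequence, window = 64, score_threshold = 20) {
  n <- nchar(sequence)
  if (n < 3) return(empty_intervals())
  tc <- triplet_codes(sequence)
  # split into runs of valid triplets (N breaks windows)
  valid <- !is.na(tc)
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  masked <- list()
  for (ri in which(runs$values)) {
    t0 <- starts[ri]; t1 <- ends[ri]       # triplet index range (1-based)
    nt <- t1 - t0 + 1L                     # triplets in this run
    seg_len <- nt + 2L                     # bases spanned by the run
    w <- min(window, seg_len)
    if (w < 4) next
    wt <- w - 2L                           # triplets per window
    counts <- integer(64)
    num <- 0
    # initialise first window
    for (j in t0:(t0 + wt - 1L)) {
      c0 <- counts[tc[j] + 1L]
      num <- num + c0
      counts[tc[j] + 1L] <- c0 + 1L
    }
    hits <- logical(nt - wt + 1L)
    hits[1] <- 10 * num / (w - 3) > score_threshold
    if (nt > wt) {
      for (s in 2:(nt - wt + 1L)) {
        drop <- tc[t0 + s - 2L]
        add <- tc[t0 + s + wt - 2L]
        counts[drop + 1L] <- counts[drop + 1L] - 1L
        num <- num - counts[drop + 1L]
        num <- num + counts[add + 1L]
        counts[add + 1L] <- counts[add + 1L] + 1L
        hits[s] <- 10 * num / (w - 3) > score_threshold
      }
    }
    if (any(hits)) {
      hs <- which(hits)
      # window starting at triplet (t0 + s - 1) covers bases
      # [t0 + s - 2, t0 + s - 2 + w) in 0-based coordinates
      masked[[length(masked) + 1L]] <-
        tibble(start = t0 + hs - 2L, end = pmin(t0 + hs - 2L + w, n))
    }
  }
  if (length(masked) == 0) return(empty_intervals())
  interval_merge(dplyr::bind_rows(masked))
}

#' Simple tandem repeat masking
#'
#' For each unit length `u` up to `max_unit`, bases are compared to the base
#' `u` positions earlier and runs are extended greedily while the cumulative
#' mismatch fraction stays at or below `max_mismatch_frac`; runs spanning at
#' least `min_span` bases (unit included) are reported and merged across
#' unit lengths.
#'
#' @param sequence A single DNA string.
#' @param max_unit Maximum repeat unit length (default 6).
#' @param min_span Minimum reported run span in bases (default 20).
#' @param max_mismatch_frac Allowed mismatch fraction within a run
#'   (default 0.1).
#' @return Tibble of masked `start`/`end` intervals (0-based half-open).
#' @export
tandem_mask <- function(sequence, max_unit = 6, min_span = 20,
                        max_mismatch_frac = 0.1) {
  n <- nchar(sequence)
  if (n < min_span) return(empty_intervals())
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- list()
  for (u in seq_len(max_unit)) {
    if (n <= u) break
    m <- b[(u + 1):n] == b[1:(n - u)] & b[(u + 1):n] != "N"
    # m[i] compares 0-based position (i + u - 1) with (i - 1)
    i <- 1L
    nm <- length(m)
    while (i <= nm) {
      if (!m[i]) { i <- i + 1L; next }
      # greedy extension from comparison i
      mm <- 0L
      j <- i
      last_match <- i
      while (j <= nm) {
        if (!m[j]) {
          if ((mm + 1L) / (j - i + 1L) > max_mismatch_frac) break
          mm <- mm + 1L
        } else {
          last_match <- j
        }
        j <- j + 1L
      }
      # run covers bases [i - 1, last_match + u) in 0-based coordinates
      span <- last_match + u - (i - 1L)
      if (span >= min_span) {
        out[[length(out) + 1L]] <- tibble(start = i - 1L,
                                          end = last_match + u)
      }
      i <- max(j, last_match + 1L)
    }
  }
  if (length(out) == 0) return(empty_intervals())
  interval_merge(dplyr::bind_rows(out))
}

#' Annotate low-complexity and simple-repeat content
#'
#' Runs [dust_mask()] and [tandem_mask()] over each fragment and reports the
#' per-class segments and the fraction of each sequence covered by their
#' union.
#'
#' @param fragments Tibble with an id column and `sequence`.
#' @param window,score_threshold Passed to [dust_mask()].
#' @param max_unit,min_span,max_mismatch_frac Passed to [tandem_mask()].
#' @return Tibble: `seq_id`, `length`, `segments` (list of tibbles with
#'   `start`, `end`, `class`), `masked_fraction`.
#' @export
annotate_repeats <- function(fragments, window = 64, score_threshold = 20,
                             max_unit = 6, min_span = 20,
                             max_mismatch_frac = 0.1) {
  frag <- as_seq_tbl(fragments)
  if (nrow(frag) == 0) {
    return(tibble(seq_id = character(), length = integer(),
                  segments = list(), masked_fraction = double()))
  }
  rows <- lapply(seq_len(nrow(frag)), function(i) {
    s <- frag$sequence[i]
    lc <- dust_mask(s, window, score_threshold)
    tr <- tandem_mask(s, max_unit, min_span, max_mismatch_frac)
    seg <- dplyr::bind_rows(
      if (nrow(lc) > 0) dplyr::mutate(lc, class = "low_complexity"),
      if (nrow(tr) > 0) dplyr::mutate(tr, class = "simple_repeat")
    )
    if (is.null(seg) || ncol(seg) == 0) {
      seg <- tibble(start = integer(), end = integer(), class = character())
    }
    covered <- interval_covered(seg[, c("start", "end")])
    tibble(seq_id = frag$seq_id[i], length = nchar(s),
           segments = list(seg), masked_fraction = covered / nchar(s))
  })
  dplyr::bind_rows(rows)
}

#' Drop fragments dominated by repeats
#'
#' Removes fragments whose masked fraction (union of low-complexity and
#' simple-repeat segments) is at least `max_masked_frac`.
#'
#' @param fragments Tibble with an id column and `sequence`.
#' @param annotation Optional result of [annotate_repeats()]; computed if
#'   missing.
#' @param max_masked_frac Inclusive removal threshold (default 0.8).
#' @param ... Passed to [annotate_repeats()] when `annotation` is NULL.
#' @return List with `kept` (input rows retained), `dropped` (input rows
#'   removed) and `annotation`.
#' @export
repeat_filter <- function(fragments, annotation = NULL, max_masked_frac = 0.8,
                          ...) {
  frag_ids <- as_seq_tbl(fragments)$seq_id
  if (is.null(annotation)) annotation <- annotate_repeats(fragments, ...)
  drop <- annotation$seq_id[annotation$masked_fraction >= max_masked_frac]
  fragments <- as_tibble(fragments)
  idcol <- intersect(c("seq_id", "fragment_id", "read_id"), names(fragments))[1]
  list(
    kept = fragments[!fragments[[idcol]] %in% drop, , drop = FALSE],
    dropped = fragments[fragments[[idcol]] %in% drop, , drop = FALSE],
    annotation = annotation
  )
}
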