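#' Merged aligned query intervals of one read
#'
#' @param alignments Alignment tibble whose records all share one
#'   `query_id`.  Query coordinates are forward-strand in PAF, so the union
#'   is strand-independent.
#' @return Tibble of merged, sorted `start`/`end` intervals on the read.
#' @export
aligned_query_intervals <- function(alignments) {
  alignments <- as_tibble(alignments)
  if (nrow(alignments) == 0) return(empty_intervals())
  if (length(unique(alignments$query_id)) > 1) {
    abort("aligned_query_intervals: records with mixed query_ids")
  }
  interval_merge(tibble(start = alignments$q_start, end = alignments$q_end))
}

#' Seed candidate fragments from whole reads
#'
#' One full-length fragment per read, round 0; the align-and-subtract rounds
#' then carve these down.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @return A fragment tibble: `fragment_id`, `source_read_id`, `start`,
#'   `end` (interval on the original read), `sequence`, `round_created`.
#' @export
fragments_from_reads <- function(reads) {
  reads <- as_tibble(reads)
  len <- nchar(reads$sequence)
  tibble(
    fragment_id = paste0(reads$read_id, ":0-", len),
    source_read_id = reads$read_id,
    start = 0L,
    end = as.integer(len),
    sequence = reads$sequence,
    round_created = 0L
  )
}

#' Unmapped fragments of a read
#'
#' Complement intervals of the merged aligned set that are strictly longer
#' than `min_len`.  An entirely unmapped read yields one full-length
#' fragment.
#'
#' @param read One-row tibble (or list) with `read_id` and `sequence`.
#' @param merged_aligned Tibble of sorted, disjoint aligned intervals on the
#'   read (as from [aligned_query_intervals()]).
#' @param min_len Fragments must be strictly longer than this (default 300).
#' @return Fragment tibble (see [fragments_from_reads()]).
#' @export
unmapped_fragments <- function(read, merged_aligned, min_len = 300) {
  read <- as_tibble(read)
  stopifnot(nrow(read) == 1)
  len <- nchar(read$sequence)
  gaps <- interval_complement(merged_aligned, len)
  gaps <- gaps[gaps$end - gaps$start > min_len, , drop = FALSE]
  tibble(
    fragment_id = sprintf("%s:%d-%d", read$read_id, gaps$start, gaps$end),
    source_read_id = rep(read$read_id, nrow(gaps)),
    start = gaps$start,
    end = gaps$end,
    sequence = if (nrow(gaps) == 0) character() else
      substring(read$sequence, gaps$start + 1L, gaps$end),
    round_created = rep(0L, nrow(gaps))
  )
}

#' Subtract aligned portions from candidate fragments
#'
#' Every aligned query interval is removed regardless of its own length;
#' surviving complement pieces strictly longer than `min_len` become child
#' fragments with coordinates re-mapped onto the original read and
#' `round_created` incremented.  Fragments with no alignments pass through
#' as a single identical child.
#'
#' @param fragments Fragment tibble.
#' @param alignments Alignment tibble whose `query_id`s are fragment ids
#'   (the fragments' own sequences were the queries).
#' @param min_len Strict minimum child length (default 300).
#' @return Fragment tibble of surviving children.
#' @export
subtract_mapped <- function(fragments, alignments, min_len = 300) {
  fragments <- as_tibble(fragments)
  alignments <- as_tibble(alignments)
  if (nrow(alignments) > 0) {
    unknown <- setdiff(unique(alignments$query_id), fragments$fragment_id)
    if (length(unknown) > 0) {
      abort(sprintf("alignment for unknown fragment: %s", unknown[1]))
    }
  }
  by_frag <- split(alignments, alignments$query_id)
  pieces <- lapply(seq_len(nrow(fragments)), function(i) {
    f <- fragments[i, ]
    flen <- f$end - f$start
    aln <- by_frag[[f$fragment_id]]
    if (is.null(aln) || nrow(aln) == 0) {
      covered <- empty_intervals()
    } else {
      if (any(aln$q_end > flen)) abort("alignment exceeds fragment length")
      covered <- interval_merge(tibble(start = aln$q_start, end = aln$q_end))
    }
    gaps <- interval_complement(covered, flen)
    gaps <- gaps[gaps$end - gaps$start > min_len, , drop = FALSE]
    if (nrow(gaps) == 0) return(NULL)
    tibble(
      fragment_id = sprintf("%s:%d-%d", f$source_read_id,
                            f$start + gaps$start, f$start + gaps$end),
      source_read_id = f$source_read_id,
      start = f$start + gaps$start,
      end = f$start + gaps$end,
      sequence = substring(f$sequence, gaps$start + 1L, gaps$end),
      round_created = f$round_created + 1L
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    out <- fragments[0, , drop = FALSE]
    out$round_created <- integer()
    return(out)
  }
  dplyr::bind_rows(pieces)
}

#' Run the align-and-subtract filtering rounds
#'
#' Each round aligns the current fragments to the reference with its preset
#' and removes every aligned query interval; pieces not strictly longer than
#' `min_len` are dropped.  The default is three rounds with presets
#' `map-long`, `sensitive`, `map-long`.  An external PAF may replace the
#' built-in aligner for any round.
#'
#' @param fragments Fragment tibble (e.g. from [fragments_from_reads()]).
#' @param ref_index A [seq_index()] of the reference.
#' @param rounds Character vector of preset names, one per round.
#' @param min_len Strict minimum fragment length (default 300).
#' @param paf List of pre-computed alignment tibbles, one per round
#'   (element `NULL` to use the built-in aligner for that round).
#' @return List with `fragments` (the survivors) and `rounds` (a tibble of
#'   per-round fragment and base counts).
#' @export
run_rounds <- function(fragments, ref_index,
                       rounds = c("map-long", "sensitive", "map-long"),
                       min_len = 300, paf = NULL) {
  fragments <- as_tibble(fragments)
  log <- vector("list", length(rounds))
  for (r in seq_along(rounds)) {
    n_in <- nrow(fragments)
    bp_in <- sum(nchar(fragments$sequence))
    if (n_in > 0) {
      aln <- if (!is.null(paf) && length(paf) >= r && !is.null(paf[[r]])) {
        paf[[r]]
      } else {
        minialign(fragments, ref_index, preset = rounds[r])
      }
      fragments <- subtract_mapped(fragments, aln, min_len = min_len)
    }
    log[[r]] <- tibble(
      round = r, preset = rounds[r], n_in = n_in, bp_in = bp_in,
      n_out = nrow(fragments), bp_out = sum(nchar(fragments$sequence))
    )
  }
  list(fragments = fragments, rounds = dplyr::bind_rows(log))
}
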