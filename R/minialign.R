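#' Alignment presets for the built-in mini-aligner
#'
#' `map-long` (rounds against a reference), `sensitive` (short minimum chain
#' span of 31, mirroring a sensitive exact-match aligner configuration) and
#' `ava` (all-vs-all fragment overlapping).
#'
#' @param name One of `"map-long"`, `"sensitive"`, `"ava"`, or a list of
#'   parameters to use as-is.
#' @return A list of aligner parameters.
#' @export
align_preset <- function(name = c("map-long", "sensitive", "ava")) {
  if (is.list(name)) return(name)
  name <- match.arg(name)
  base <- list(k = 15L, band_width = 64L, max_occ = 64L, max_chains = 64L,
               max_ext = 2000L)
  switch(name,
    "map-long" = c(base, list(min_chain_span = 100L, max_seed_gap = 500L,
                              min_seeds = 3L)),
    "sensitive" = c(base, list(min_chain_span = 31L, max_seed_gap = 200L,
                               min_seeds = 2L, max_occ = 128L)),
    "ava" = c(base, list(min_chain_span = 100L, max_seed_gap = 500L,
                         min_seeds = 3L))
  )
}

#' Index target sequences for the mini-aligner
#'
#' All k-mers (canonical, strand-min; k-mers containing `N` skipped) are
#' stored exactly -- no minimizer subsampling -- which keeps desk-scale
#' alignment fully deterministic.
#'
#' @param seqs Tibble with an id column and `sequence`, or a named character
#'   vector.
#' @param k Odd k-mer size between 11 and 21 (default 15).
#' @return A `seq_index` object.
#' @export
seq_index <- function(seqs, k = 15L) {
  seqs <- as_seq_tbl(seqs)
  if (nrow(seqs) == 0) abort("seq_index: no sequences to index")
  if (anyDuplicated(seqs$seq_id)) abort("seq_index: duplicated sequence ids")
  xp <- cpp_build_index(seqs$sequence, seqs$seq_id, as.integer(k))
  structure(list(ptr = xp, k = as.integer(k), target_id = seqs$seq_id,
                 target_len = nchar(seqs$sequence)),
            class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  st <- cpp_index_stats(x$ptr)
  cat(sprintf("<seq_index> k=%d, %d target(s), %.0f distinct k-mers\n",
              st$k, st$n_targets, st$n_kmers))
  invisible(x)
}

#' Summary statistics of a sequence index
#'
#' @param index A `seq_index`.
#' @return List with `k`, `n_targets`, `n_kmers` (distinct canonical
#'   k-mers), `target_id` and `target_len`.
#' @export
index_stats <- function(index) {
  stopifnot(inherits(index, "seq_index"))
  cpp_index_stats(index$ptr)
}

#' Align queries against an indexed target set
#'
#' Seed-and-extend: exact canonical k-mer seeds, collinear chaining per
#' (target, strand) with bounded seed gaps, banded dynamic programming
#' between consecutive seed runs and banded semi-global extension at the
#' chain ends.  Match counts come from the actual alignment, so
#' `identity = n_matches / block_len` reflects the aligned bases.  Chains
#' spanning less than the preset's `min_chain_span` on the query are
#' discarded.  Queries with no seed hits yield no records.
#'
#' @param query Tibble with an id column and `sequence`, or a named
#'   character vector.
#' @param index A [seq_index()].
#' @param preset Preset name or parameter list (see [align_preset()]).
#' @return PAF-style tibble (one row per chain) sorted by query id and
#'   query start, with an `identity` column.
#' @export
minialign <- function(query, index, preset = "map-long") {
  stopifnot(inherits(index, "seq_index"))
  p <- align_preset(preset)
  query <- as_seq_tbl(query)
  res <- lapply(seq_len(nrow(query)), function(i) {
    if (nchar(query$sequence[i]) < index$k) return(NULL)
    df <- cpp_align(query$sequence[i], index$ptr, p$max_occ, p$min_chain_span,
                    p$max_seed_gap, p$band_width, p$min_seeds, p$max_chains,
                    p$max_ext)
    if (nrow(df) == 0) return(NULL)
    df$query_id <- query$seq_id[i]
    df
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(empty_paf())
  out <- as_tibble(dplyr::bind_rows(res))
  out$mapq <- 255L
  out$identity <- out$n_matches / out$block_len
  out <- out[, names(empty_paf())]
  out <- validate_paf(out, context = "minialign")
  dplyr::arrange(out, .data$query_id, .data$q_start, .data$target_id)
}

#' All-vs-all overlap alignment of a fragment set
#'
#' Every sequence is aligned against an index of the full set; self-hits are
#' excluded and each unordered pair is reported once (records are kept from
#' the lexicographically smaller query id), making the output symmetric
#' under input order.
#'
#' @param seqs Tibble with an id column and `sequence`, or a named character
#'   vector (at least 2 sequences).
#' @param preset Preset name or parameter list (default `"ava"`).
#' @return PAF-style tibble of pairwise overlaps.
#' @export
minialign_ava <- function(seqs, preset = "ava") {
  seqs <- as_seq_tbl(seqs)
  if (nrow(seqs) < 2) abort("minialign_ava: need at least 2 sequences")
  idx <- seq_index(seqs, k = align_preset(preset)$k)
  aln <- minialign(seqs, idx, preset = preset)
  dplyr::filter(aln, .data$query_id < .data$target_id)
}
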