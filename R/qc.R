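#' Mean read quality in probability space
#'
#' The per-read quality is the Phred-scaled mean of the per-base error
#' probabilities: `-10 * log10(mean(10^(-Q/10)))`.  This is the convention of
#' common nanopore QC tools; the arithmetic mean of Phred scores would
#' overestimate quality.
#'
#' @param qualities Integer vector of per-base Phred scores, or a list of
#'   such vectors (one value returned per element).
#' @return Numeric mean quality (Phred units).
#' @export
#' @examples
#' mean_quality(c(10, 10, 20))
mean_quality <- function(qualities) {
  if (is.list(qualities)) {
    return(vapply(qualities, mean_quality, double(1)))
  }
  if (length(qualities) == 0) abort("mean_quality: empty quality vector")
  if (any(qualities < 0)) abort("mean_quality: negative Phred score")
  -10 * log10(mean(10^(-qualities / 10)))
}

#' Filter reads by mean quality
#'
#' Keeps reads whose probability-space mean quality is at least `min_q`;
#' reads strictly below the cutoff are dropped.
#'
#' @param reads Tibble with `read_id`, `sequence`, `qualities`.
#' @param min_q Minimum mean Phred quality (default 10).
#' @return A list with `reads` (the kept tibble, plus a `mean_q` column) and
#'   `report` (a tibble of `read_id`, `mean_q`, `passed`).
#' @export
filter_by_quality <- function(reads, min_q = 10) {
  reads <- as_tibble(reads)
  no_q <- vapply(reads$qualities, is.null, logical(1)) |
    lengths(reads$qualities) == 0
  if (any(no_q)) {
    abort(sprintf("read without qualities: %s", reads$read_id[which(no_q)[1]]))
  }
  mq <- mean_quality(reads$qualities)
  report <- tibble(read_id = reads$read_id, mean_q = mq, passed = mq >= min_q)
  kept <- reads[report$passed, , drop = FALSE]
  kept$mean_q <- mq[report$passed]
  list(reads = kept, report = report)
}

# Best local hit of one adapter against one window; Biostrings does the
# semi-global search work.  Returns NULL or list(start, end, identity,
# adapter_bases) with 0-based half-open window coordinates.
best_adapter_hit <- function(window_seq, adapter, min_identity, min_match) {
  if (nchar(window_seq) < min_match) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    pattern = adapter, subject = window_seq, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 3, gapExtension = 2
  )
  nm <- Biostrings::nmatch(aln)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (cols == 0) return(NULL)
  identity <- nm / cols
  pw <- Biostrings::width(Biostrings::pattern(aln))
  if (identity < min_identity || pw < min_match) return(NULL)
  sb <- Biostrings::subject(aln)
  list(start = Biostrings::start(sb) - 1L, end = Biostrings::end(sb),
       identity = identity, adapter_bases = pw)
}

#' Trim adapters from read ends
#'
#' Each adapter (and its reverse complement) is searched within the first
#' and last `end_window` bases; a hit with identity at least `min_identity`
#' over at least `min_match` aligned adapter bases truncates the read at the
#' adapter's inner boundary.  Qualities are trimmed in lockstep and the
#' search repeats until no hit remains.  Reads trimmed to nothing are
#' dropped (and counted), not an error.  Middle-of-read adapters are out of
#' scope.
#'
#' @param reads Tibble with `read_id`, `sequence`, `qualities`.
#' @param adapters Tibble of adapter sequences (as from [read_fasta()]) or a
#'   character vector.
#' @param end_window Bases searched at each read end (default 150).
#' @param min_identity Minimum alignment identity (default 0.75).
#' @param min_match Minimum aligned adapter bases (default 10).
#' @return List with `reads` (trimmed tibble), `n_trimmed` (reads that lost
#'   bases) and `n_dropped` (reads removed entirely).
#' @export
trim_adapters <- function(reads, adapters, end_window = 150,
                          min_identity = 0.75, min_match = 10) {
  reads <- as_tibble(reads)
  adapters <- as_seq_tbl(adapters)
  adapter_seqs <- unique(c(adapters$sequence, revcomp(adapters$sequence)))
  n_trimmed <- 0L
  keep <- logical(nrow(reads))
  out_seq <- character(nrow(reads))
  out_qual <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    q <- reads$qualities[[i]]
    trimmed <- FALSE
    for (iter in seq_len(20L)) {
      n <- nchar(s)
      if (n == 0) break
      hit <- NULL
      # leading window: cut at the hit's inner (right) boundary
      w <- substr(s, 1, min(end_window, n))
      for (ad in adapter_seqs) {
        h <- best_adapter_hit(w, ad, min_identity, min_match)
        if (!is.null(h) && (is.null(hit) || h$identity > hit$identity)) {
          hit <- h
          hit$side <- "start"
        }
      }
      # trailing window: cut at the hit's inner (left) boundary
      off <- max(0L, n - end_window)
      w <- substr(s, off + 1L, n)
      for (ad in adapter_seqs) {
        h <- best_adapter_hit(w, ad, min_identity, min_match)
        if (!is.null(h) && (is.null(hit) || h$identity > hit$identity)) {
          hit <- h
          hit$side <- "end"
          hit$start <- hit$start + off
          hit$end <- hit$end + off
        }
      }
      if (is.null(hit)) break
      trimmed <- TRUE
      if (hit$side == "start") {
        s <- substr(s, hit$end + 1L, n)
        if (!is.null(q)) q <- q[seq_len(n) > hit$end]
      } else {
        s <- substr(s, 1L, hit$start)
        if (!is.null(q)) q <- q[seq_len(n) <= hit$start]
      }
    }
    if (trimmed) n_trimmed <- n_trimmed + 1L
    if (nchar(s) > 0) {
      keep[i] <- TRUE
      out_seq[i] <- s
      out_qual[[i]] <- q
    }
  }
  out <- reads[keep, , drop = FALSE]
  out$sequence <- out_seq[keep]
  out$qualities <- out_qual[keep]
  list(reads = out, n_trimmed = n_trimmed, n_dropped = sum(!keep))
}
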