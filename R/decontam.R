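#' Kraken2-style classification confidence
#'
#' Recomputed from the per-sequence LCA mapping string rather than trusted
#' from upstream: `C / Q`, where `C` sums the k-mer counts whose taxid lies
#' within the clade rooted at the call's taxid and `Q` sums all counted
#' k-mers -- ambiguous (`A`) entries are excluded everywhere, and taxid 0
#' (unclassified k-mers) counts in the denominator only.
#'
#' @param calls Tibble of taxonomic calls (see [parse_kraken2_line()]).
#' @param tax A [taxonomy()] object.
#' @return Numeric vector of confidences in `[0, 1]` (`NA` for unclassified
#'   calls).
#' @export
kraken_confidence <- function(calls, tax) {
  stopifnot(inherits(tax, "novel_taxonomy"))
  calls <- as_tibble(calls)
  vapply(seq_len(nrow(calls)), function(i) {
    if (!calls$classified[i]) return(NA_real_)
    lca <- calls$lca[[i]]
    counted <- lca[lca$taxid != "A", , drop = FALSE]
    q <- sum(counted$count)
    if (q == 0) return(0)
    tids <- as.integer(counted$taxid)
    in_clade <- vapply(tids, function(t) tax_in_clade(tax, t, calls$taxid[i]),
                       logical(1))
    sum(counted$count[in_clade]) / q
  }, double(1))
}

#' Is a classified sequence a contaminant?
#'
#' TRUE iff the call is classified, its taxid falls inside one of the
#' taxonomy's contaminant clades (or its sequence id carries a plasmid /
#' UniVec library label), and the recomputed confidence strictly exceeds
#' `conf_threshold`.
#'
#' @inheritParams kraken_confidence
#' @param conf_threshold Strict confidence cutoff (default 0.05).
#' @return Logical vector, one element per call.
#' @export
is_contaminant <- function(calls, tax, conf_threshold = 0.05) {
  stopifnot(inherits(tax, "novel_taxonomy"))
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) return(logical())
  conf <- kraken_confidence(calls, tax)
  in_clades <- vapply(seq_len(nrow(calls)), function(i) {
    if (!calls$classified[i]) return(FALSE)
    any(vapply(tax$roots, function(r) tax_in_clade(tax, calls$taxid[i], r),
               logical(1)))
  }, logical(1))
  labelled <- rep(FALSE, nrow(calls))
  if (!is.null(tax$labels)) {
    lib <- tax$labels$library[match(calls$seq_id, tax$labels$seq_id)]
    labelled <- !is.na(lib) & lib %in% c("plasmid", "UniVec")
  }
  calls$classified & (in_clades | labelled) &
    !is.na(conf) & conf > conf_threshold
}

#' Remove contaminant fragments
#'
#' Partitions fragments into kept and removed using Kraken2-style calls.
#' Fragments without a call are kept (an unclassified fragment cannot exceed
#' any confidence threshold).
#'
#' @param fragments Fragment tibble.
#' @param calls Taxonomic call tibble; `seq_id` must match `fragment_id`
#'   and each fragment may have at most one call.
#' @param tax A [taxonomy()] object.
#' @param conf_threshold Strict confidence cutoff (default 0.05).
#' @return List with `kept` (fragment tibble) and `removed` (report tibble:
#'   `fragment_id`, `taxid`, `confidence`).
#' @export
filter_contaminants <- function(fragments, calls, tax, conf_threshold = 0.05) {
  fragments <- as_tibble(fragments)
  calls <- as_tibble(calls)
  if (anyDuplicated(calls$seq_id)) {
    abort(sprintf("duplicate seq_id in calls: %s",
                  calls$seq_id[anyDuplicated(calls$seq_id)]))
  }
  calls <- calls[calls$seq_id %in% fragments$fragment_id, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(list(kept = fragments,
                removed = tibble(fragment_id = character(), taxid = integer(),
                                 confidence = double())))
  }
  contam <- is_contaminant(calls, tax, conf_threshold)
  conf <- kraken_confidence(calls, tax)
  removed_ids <- calls$seq_id[contam]
  list(
    kept = fragments[!fragments$fragment_id %in% removed_ids, , drop = FALSE],
    removed = tibble(fragment_id = calls$seq_id[contam],
                     taxid = calls$taxid[contam],
                     confidence = conf[contam])
  )
}
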