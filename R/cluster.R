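#' Mutual alignment coverage of a sequence pair
#'
#' Coverage is measured on the shorter of the two sequences: alignment
#' blocks are merged, and the covered length on the shorter sequence is
#' divided by its length.  (Coverage of the shorter sequence -- rather than
#' reciprocal coverage -- is what lets clusters contain members of unequal
#' length, which the longest-representative rule presumes.)
#'
#' @param alignments Alignment tibble whose records are all between the two
#'   ids of the pair, in either orientation.
#' @param len_a,len_b Lengths of the two sequences.
#' @param id_a,id_b Ids of the pair (defaults taken from `alignments`).
#' @param reciprocal If TRUE, return the minimum of the two coverages
#'   instead (configurable interpretation of mutual coverage).
#' @return Coverage in `[0, 1]`; 0 when there are no alignments.
#' @export
pair_coverage <- function(alignments, len_a, len_b, id_a = NULL, id_b = NULL,
                          reciprocal = FALSE) {
  alignments <- as_tibble(alignments)
  if (nrow(alignments) == 0) return(0)
  ids <- unique(c(alignments$query_id, alignments$target_id))
  if (is.null(id_a)) id_a <- alignments$query_id[1]
  if (is.null(id_b)) id_b <- alignments$target_id[1]
  if (!all(ids %in% c(id_a, id_b))) {
    abort("pair_coverage: alignments are not all between the given pair")
  }
  cov_of <- function(id, len) {
    qi <- alignments[alignments$query_id == id, c("q_start", "q_end")]
    ti <- alignments[alignments$target_id == id, c("t_start", "t_end")]
    names(qi) <- names(ti) <- c("start", "end")
    interval_covered(dplyr::bind_rows(qi, ti)) / len
  }
  if (reciprocal) {
    return(min(cov_of(id_a, len_a), cov_of(id_b, len_b)))
  }
  if (len_a <= len_b) cov_of(id_a, len_a) else cov_of(id_b, len_b)
}

#' Cluster redundant fragments by alignment coverage
#'
#' Two fragments are connected when their mutual coverage strictly exceeds
#' `cov_threshold`; clusters are the connected components of that graph
#' (single linkage -- transitive), singletons included.  Cluster ids are
#' deterministic: ordered by representative length descending, then by
#' representative id, so the output is independent of input order.
#'
#' @param fragments Fragment tibble (ids + sequences; lengths taken from
#'   the sequences).
#' @param alignments All-vs-all alignment tibble (e.g. [minialign_ava()]).
#' @param cov_threshold Strict coverage threshold (default 0.8).
#' @param reciprocal Use reciprocal instead of shorter-sequence coverage.
#' @return Cluster tibble: `cluster_id`, `representative_id`,
#'   `representative_len`, `n_members`, `member_ids` (list column).
#' @export
build_clusters <- function(fragments, alignments, cov_threshold = 0.8,
                           reciprocal = FALSE) {
  stopifnot(cov_threshold > 0, cov_threshold <= 1)
  frag <- as_seq_tbl(fragments)
  if (nrow(frag) == 0) {
    return(tibble(cluster_id = character(), representative_id = character(),
                  representative_len = integer(), n_members = integer(),
                  member_ids = list()))
  }
  lens <- setNames(nchar(frag$sequence), frag$seq_id)
  alignments <- as_tibble(alignments)
  if (nrow(alignments) > 0) {
    unknown <- setdiff(unique(c(alignments$query_id, alignments$target_id)),
                       frag$seq_id)
    if (length(unknown) > 0) {
      abort(sprintf("alignment names unknown fragment: %s", unknown[1]))
    }
    alignments <- alignments[alignments$query_id != alignments$target_id, ]
  }
  edges <- character(0)
  if (nrow(alignments) > 0) {
    a <- pmin(alignments$query_id, alignments$target_id)
    b <- pmax(alignments$query_id, alignments$target_id)
    pair_key <- paste(a, b, sep = "\r")
    keep <- vapply(split(seq_len(nrow(alignments)), pair_key), function(i) {
      ia <- a[i[1]]; ib <- b[i[1]]
      pair_coverage(alignments[i, ], lens[[ia]], lens[[ib]], ia, ib,
                    reciprocal = reciprocal) > cov_threshold
    }, logical(1))
    ek <- names(keep)[keep]
    edges <- unlist(strsplit(ek, "\r", fixed = TRUE), use.names = FALSE)
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(frag$seq_id)
  if (length(edges) > 0) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  clusters <- lapply(members, function(ids) {
    l <- lens[ids]
    rep_id <- sort(ids[l == max(l)])[1]  # tie: lexicographically smallest id
    tibble(representative_id = rep_id,
           representative_len = unname(max(l)),
           n_members = length(ids),
           member_ids = list(sort(ids)))
  })
  out <- dplyr::bind_rows(clusters)
  out <- dplyr::arrange(out, desc(.data$representative_len),
                        .data$representative_id)
  out$cluster_id <- sprintf("cluster%04d", seq_len(nrow(out)))
  out[, c("cluster_id", "representative_id", "representative_len",
          "n_members", "member_ids")]
}

#' Representative sequences of fragment clusters
#'
#' The longest member of each cluster (ties broken by smallest fragment id,
#' as recorded by [build_clusters()]).
#'
#' @param clusters Cluster tibble from [build_clusters()].
#' @param fragments Fragment tibble the clusters were built from.
#' @return Tibble with `seq_id` (= representative fragment id), `sequence`,
#'   `cluster_id` and `n_members`.
#' @export
cluster_representatives <- function(clusters, fragments) {
  frag <- as_seq_tbl(fragments)
  if (any(clusters$n_members == 0)) abort("empty cluster")
  i <- match(clusters$representative_id, frag$seq_id)
  if (anyNA(i)) abort("cluster representative missing from fragments")
  tibble(seq_id = clusters$representative_id,
         sequence = frag$sequence[i],
         cluster_id = clusters$cluster_id,
         n_members = clusters$n_members)
}
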