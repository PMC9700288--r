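#' Select a consistent anchor set for one read
#'
#' Alignments are filtered to identity >= `min_identity` (inclusive).  The
#' read is accepted iff exactly one alignment remains, or exactly two that
#' are consistent: same target and strand, non-overlapping on both read and
#' reference (up to a `max_overlap` micro-homology slack), and with
#' reference order matching read order on `+` (reversed on `-`).  Rejection
#' is a value, not an error.
#'
#' @param alignments Alignment tibble sharing one `query_id`.
#' @param min_identity Inclusive identity floor (default 0.8).
#' @param max_overlap Tolerated anchor overlap in bp on read or reference
#'   (default 100): insertion junctions commonly carry micro-homology, and
#'   aligner end extension can step a few bases across a junction, so the
#'   two flanking anchors of a genuine insertion may overlap slightly.
#' @return The accepted anchor tibble (1 or 2 rows, ordered by read
#'   position), or `NULL` when the read is rejected.
#' @export
consistent_anchor_set <- function(alignments, min_identity = 0.8,
                                  max_overlap = 100) {
  alignments <- as_tibble(alignments)
  if (nrow(alignments) == 0) return(NULL)
  if (length(unique(alignments$query_id)) > 1) {
    abort("consistent_anchor_set: records with mixed query_ids")
  }
  if (!"identity" %in% names(alignments)) {
    alignments$identity <- alignments$n_matches / alignments$block_len
  }
  a <- alignments[alignments$identity >= min_identity, , drop = FALSE]
  if (nrow(a) == 1) return(a)
  if (nrow(a) != 2) return(NULL)
  a <- dplyr::arrange(a, .data$q_start)
  same <- a$target_id[1] == a$target_id[2] && a$strand[1] == a$strand[2]
  if (!same) return(NULL)
  if (a$q_end[1] - a$q_start[2] > max_overlap) return(NULL)  # overlap on read
  t_overlap <- min(a$t_end) - max(a$t_start)
  if (t_overlap > max_overlap) return(NULL)              # overlap on reference
  collinear <- if (a$strand[1] == "+") {
    a$t_start[1] < a$t_start[2]
  } else {
    a$t_start[1] > a$t_start[2]
  }
  if (!collinear) return(NULL)
  a
}

#' Call SEP/BEP insertion placements from one read's anchors
#'
#' Unmapped read intervals strictly longer than `min_fragment_len` become
#' placement calls.  A gap between two anchors becomes a BEP (both ends
#' placed) with breakpoint spanning the facing anchor boundaries on the
#' reference (zero-width when the anchors abut; reduced to the midpoint
#' when they overlap through micro-homology).  A gap outside a single
#' anchor at a read end becomes a SEP (single end placed) with a zero-width
#' breakpoint at the anchor's facing boundary, strand-aware.
#'
#' @param read One-row tibble with `read_id` and `sequence`.
#' @param anchors Anchor tibble accepted by [consistent_anchor_set()].
#' @param min_fragment_len Strict minimum fragment length (default 1000).
#' @param sample_id Sample label carried into the calls.
#' @return Tibble of placement calls: `kind` (`"SEP"`/`"BEP"`), `sample_id`,
#'   `read_id`, `fragment_id`, `sequence`, `fragment_len`, `target_id`,
#'   `bp_start`, `bp_end`, `strand`.
#' @export
call_placements <- function(read, anchors, min_fragment_len = 1000,
                            sample_id = "sample") {
  read <- as_tibble(read)
  stopifnot(nrow(read) == 1)
  if (is.null(anchors) || nrow(anchors) == 0) return(empty_calls())
  anchors <- dplyr::arrange(as_tibble(anchors), .data$q_start)
  len <- nchar(read$sequence)
  gaps <- interval_complement(
    tibble(start = anchors$q_start, end = anchors$q_end), len)
  gaps <- gaps[gaps$end - gaps$start > min_fragment_len, , drop = FALSE]
  if (nrow(gaps) == 0) return(empty_calls())
  calls <- lapply(seq_len(nrow(gaps)), function(i) {
    g <- gaps[i, ]
    left <- anchors[anchors$q_end <= g$start, , drop = FALSE]
    right <- anchors[anchors$q_start >= g$end, , drop = FALSE]
    left <- if (nrow(left) > 0) left[nrow(left), , drop = FALSE] else NULL
    right <- if (nrow(right) > 0) right[1, , drop = FALSE] else NULL
    seq <- substring(read$sequence, g$start + 1L, g$end)
    base <- tibble(
      sample_id = sample_id, read_id = read$read_id,
      fragment_id = sprintf("%s:%d-%d", read$read_id, g$start, g$end),
      sequence = seq, fragment_len = g$end - g$start,
      strand = anchors$strand[1]
    )
    if (!is.null(left) && !is.null(right)) {
      # facing reference boundaries depend on strand
      if (base$strand == "+") {
        lo <- left$t_end; hi <- right$t_start
      } else {
        lo <- right$t_end; hi <- left$t_start
      }
      if (lo > hi) {  # micro-homology overlap: zero-width midpoint
        mid <- as.integer(floor((lo + hi) / 2))
        lo <- mid; hi <- mid
      }
      dplyr::mutate(base, kind = "BEP", target_id = left$target_id,
                    bp_start = as.integer(lo), bp_end = as.integer(hi))
    } else if (!is.null(left) || !is.null(right)) {
      anc <- if (is.null(left)) right else left
      at_read_start <- is.null(left)
      # the boundary facing the unmapped read end
      bp <- if (at_read_start == (anc$strand == "+")) anc$t_start else anc$t_end
      dplyr::mutate(base, kind = "SEP", target_id = anc$target_id,
                    bp_start = as.integer(bp), bp_end = as.integer(bp))
    } else {
      NULL
    }
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0) return(empty_calls())
  out <- dplyr::bind_rows(calls)
  out[, names(empty_calls())]
}

empty_calls <- function() {
  tibble(kind = character(), sample_id = character(), read_id = character(),
         fragment_id = character(), sequence = character(),
         fragment_len = integer(), target_id = character(),
         bp_start = integer(), bp_end = integer(), strand = character())
}

# Distance between two breakpoint intervals on the same target (0 when they
# touch or overlap).
bp_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

calls_to_clusters <- function(calls, membership, kind) {
  groups <- split(seq_len(nrow(calls)), membership)
  rows <- lapply(groups, function(i) {
    m <- calls[i, , drop = FALSE]
    best <- order(-m$fragment_len, m$read_id)[1]
    tibble(
      kind = kind,
      target_id = m$target_id[1],
      bp_start = min(m$bp_start),
      bp_end = max(m$bp_end),
      support = nrow(m),
      representative_id = m$fragment_id[best],
      representative_len = m$fragment_len[best],
      sequence = m$sequence[best],
      samples = list(sort(unique(m$sample_id))),
      member_ids = list(m$fragment_id)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$target_id, .data$bp_start,
                        desc(.data$support), .data$representative_id)
  out$cluster_id <- sprintf("%s%04d", tolower(kind), seq_len(nrow(out)))
  out[, c("cluster_id", "kind", "target_id", "bp_start", "bp_end", "support",
          "representative_id", "representative_len", "sequence", "samples",
          "member_ids")]
}

#' Merge BEP placement calls into clusters
#'
#' Two BEP calls merge iff they are on the same target with breakpoints
#' within `max_dist` of each other, and their fragment sequences overlap
#' near-full-length: the merged aligned length on the shorter fragment must
#' differ from the shorter fragment's length by strictly less than
#' `max_dist`.  Clusters are connected components; the merged breakpoint is
#' the span of the members' breakpoints.
#'
#' @param calls Tibble of BEP calls ([call_placements()]).
#' @param max_dist Breakpoint proximity / overlap slack in bp (default 100).
#' @param proximity_only Skip the fragment-overlap requirement.
#' @return Cluster tibble: `cluster_id`, `kind`, `target_id`, `bp_start`,
#'   `bp_end`, `support`, representative fields, `samples`, `member_ids`.
#' @export
merge_bep <- function(calls, max_dist = 100, proximity_only = FALSE) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) return(empty_cluster_tbl())
  if (any(calls$kind != "BEP")) abort("merge_bep: non-BEP call in input")
  n <- nrow(calls)
  ava <- NULL
  if (!proximity_only && n > 1) {
    seqs <- dplyr::distinct(
      tibble(seq_id = calls$fragment_id, sequence = calls$sequence),
      .data$seq_id, .keep_all = TRUE)
    if (nrow(seqs) >= 2) ava <- minialign_ava(seqs)
  }
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (calls$target_id[i] != calls$target_id[j]) next
        d <- bp_distance(calls$bp_start[i], calls$bp_end[i],
                         calls$bp_start[j], calls$bp_end[j])
        if (d > max_dist) next
        if (!proximity_only) {
          ok <- fragment_overlap_ok(calls$fragment_id[i], calls$fragment_id[j],
                                    calls$fragment_len[i], calls$fragment_len[j],
                                    ava, max_dist)
          if (!ok) next
        }
        edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(seq_len(n))
  if (length(edges) > 0) g <- g + igraph::edges(edges)
  calls_to_clusters(calls, igraph::components(g)$membership, "BEP")
}

fragment_overlap_ok <- function(id_a, id_b, len_a, len_b, ava, max_dist) {
  if (id_a == id_b) return(TRUE)  # the same fragment called twice
  if (is.null(ava)) return(FALSE)
  pair <- ava[(ava$query_id == id_a & ava$target_id == id_b) |
              (ava$query_id == id_b & ava$target_id == id_a), , drop = FALSE]
  if (nrow(pair) == 0) return(FALSE)
  cov <- pair_coverage(pair, len_a, len_b, id_a, id_b)
  overlap <- cov * min(len_a, len_b)
  abs(overlap - min(len_a, len_b)) < max_dist
}

empty_cluster_tbl <- function() {
  tibble(cluster_id = character(), kind = character(), target_id = character(),
         bp_start = integer(), bp_end = integer(), support = integer(),
         representative_id = character(), representative_len = integer(),
         sequence = character(), samples = list(), member_ids = list())
}

#' Merge SEP placement calls into clusters
#'
#' Single-linkage merging of breakpoints on the same target with gaps of at
#' most `max_dist` (inclusive).
#'
#' @param calls Tibble of SEP calls.
#' @param max_dist Maximum gap in bp (default 100).
#' @return Cluster tibble (see [merge_bep()]).
#' @export
merge_sep <- function(calls, max_dist = 100) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) return(empty_cluster_tbl())
  if (any(calls$kind != "SEP")) abort("merge_sep: non-SEP call in input")
  ord <- order(calls$target_id, calls$bp_start, calls$bp_end)
  membership <- integer(nrow(calls))
  comp <- 0L
  prev_target <- NULL
  prev_end <- NULL
  for (i in ord) {
    if (is.null(prev_target) || calls$target_id[i] != prev_target ||
        calls$bp_start[i] - prev_end > max_dist) {
      comp <- comp + 1L
      prev_end <- calls$bp_end[i]
    } else {
      prev_end <- max(prev_end, calls$bp_end[i])
    }
    prev_target <- calls$target_id[i]
    membership[i] <- comp
  }
  calls_to_clusters(calls, membership, "SEP")
}

#' Filter placement clusters by read support
#'
#' @param clusters Cluster tibble from [merge_bep()] / [merge_sep()].
#' @param min_support Minimum member count (default 3; clusters with fewer
#'   members are excluded).
#' @return The supported clusters.
#' @export
filter_clusters <- function(clusters, min_support = 3) {
  clusters <- as_tibble(clusters)
  clusters[clusters$support >= min_support, , drop = FALSE]
}

#' Call and cluster novel placements for one sample
#'
#' Aligns reads to the reference, keeps reads with one or two consistent
#' high-identity anchors, extracts unmapped fragments longer than
#' `min_fragment_len` as SEP/BEP calls, merges them, and drops clusters
#' below `min_support`.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param ref_index A [seq_index()] of the reference (or a reference tibble,
#'   which will be indexed).
#' @param sample_id Sample label.
#' @param min_identity Inclusive anchor identity floor (default 0.8).
#' @param min_fragment_len Strict minimum fragment length (default 1000).
#' @param max_dist Merge distance in bp (default 100).
#' @param min_support Minimum cluster support (default 3).
#' @param alignments Optional pre-computed alignment tibble (external PAF).
#' @return A `novel_placements` object: list with `clusters` (surviving),
#'   `all_clusters`, `calls` and counters.
#' @export
call_novel_placements <- function(reads, ref_index, sample_id = "sample",
                                  min_identity = 0.8, min_fragment_len = 1000,
                                  max_dist = 100, min_support = 3,
                                  alignments = NULL) {
  reads <- as_tibble(reads)
  if (is.null(alignments)) {
    if (!inherits(ref_index, "seq_index")) ref_index <- seq_index(ref_index)
    alignments <- minialign(reads, ref_index, preset = "map-long")
  }
  by_read <- split(alignments, alignments$query_id)
  calls <- lapply(seq_len(nrow(reads)), function(i) {
    aln <- by_read[[reads$read_id[i]]]
    if (is.null(aln)) return(NULL)
    anchors <- consistent_anchor_set(aln, min_identity = min_identity)
    if (is.null(anchors)) return(NULL)
    call_placements(reads[i, ], anchors, min_fragment_len = min_fragment_len,
                    sample_id = sample_id)
  })
  calls <- dplyr::bind_rows(calls[!vapply(calls, is.null, logical(1))])
  if (nrow(calls) == 0) calls <- empty_calls()
  bep <- merge_bep(calls[calls$kind == "BEP", , drop = FALSE], max_dist)
  sep <- merge_sep(calls[calls$kind == "SEP", , drop = FALSE], max_dist)
  all_clusters <- dplyr::bind_rows(bep, sep)
  kept <- filter_clusters(all_clusters, min_support)
  structure(
    list(sample_id = sample_id, calls = calls, all_clusters = all_clusters,
         clusters = kept, min_support = min_support),
    class = "novel_placements"
  )
}

#' Label cross-sample sharing of placement clusters
#'
#' Clusters from different samples are matched when they have the same kind
#' and target, breakpoints within `max_dist`, and representative sequences
#' aligning at identity >= `min_identity`.  Matched groups are labelled
#' `individual` (one sample), `population-specific` (two or more samples,
#' all from one population) or `population-shared` (samples from two or
#' more populations).
#'
#' @param placements Named list of `novel_placements` (name = sample id) or
#'   a combined cluster tibble with a `sample_id` column.
#' @param population_map Tibble with `sample_id`, `population`.
#' @param max_dist Breakpoint matching distance (default 100).
#' @param min_identity Representative identity floor (default 0.8).
#' @return Tibble of clusters with `sample_id`, `locus_id`, `n_samples`,
#'   `n_populations` and `label`.
#' @export
classify_sharing <- function(placements, population_map, max_dist = 100,
                             min_identity = 0.8) {
  population_map <- as_tibble(population_map)
  if (is.data.frame(placements)) {
    clu <- as_tibble(placements)
  } else {
    clu <- dplyr::bind_rows(lapply(placements, function(p) {
      dplyr::mutate(p$clusters, sample_id = p$sample_id)
    }))
  }
  if (nrow(clu) == 0) {
    return(dplyr::mutate(clu, locus_id = character(), n_samples = integer(),
                         n_populations = integer(), label = character()))
  }
  missing <- setdiff(unique(clu$sample_id), population_map$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample missing from population map: %s", missing[1]))
  }
  clu$row_id <- sprintf("%s__%s", clu$sample_id, clu$cluster_id)
  n <- nrow(clu)
  ava <- NULL
  if (n > 1) {
    seqs <- tibble(seq_id = clu$row_id, sequence = clu$sequence)
    ava <- minialign(seqs, seq_index(seqs), preset = "ava")
    ava <- ava[ava$query_id != ava$target_id & ava$identity >= min_identity, ]
  }
  hit_ok <- function(a, b) {
    !is.null(ava) && nrow(ava[(ava$query_id == a & ava$target_id == b) |
                              (ava$query_id == b & ava$target_id == a), ]) > 0
  }
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (clu$kind[i] != clu$kind[j]) next
        if (clu$target_id[i] != clu$target_id[j]) next
        if (clu$sample_id[i] == clu$sample_id[j]) next
        d <- bp_distance(clu$bp_start[i], clu$bp_end[i],
                         clu$bp_start[j], clu$bp_end[j])
        if (d > max_dist) next
        if (!hit_ok(clu$row_id[i], clu$row_id[j])) next
        edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(seq_len(n))
  if (length(edges) > 0) g <- g + igraph::edges(edges)
  memb <- igraph::components(g)$membership
  clu$locus_id <- sprintf("locus%04d", memb)
  pops <- population_map$population[match(clu$sample_id,
                                          population_map$sample_id)]
  per_locus <- tapply(seq_len(n), memb, function(i) {
    c(n_samples = length(unique(clu$sample_id[i])),
      n_populations = length(unique(pops[i])))
  })
  stats <- do.call(rbind, per_locus)[as.character(memb), , drop = FALSE]
  clu$n_samples <- as.integer(stats[, "n_samples"])
  clu$n_populations <- as.integer(stats[, "n_populations"])
  clu$label <- dplyr::case_when(
    clu$n_populations >= 2 ~ "population-shared",
    clu$n_samples >= 2 ~ "population-specific",
    TRUE ~ "individual"
  )
  clu$row_id <- NULL
  clu
}
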