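anchor_rec <- function(qid, qlen, qs, qe, ts, te, strand = "+",
                       target = "chr1", identity = 0.9) {
  bl <- qe - qs
  tibble::tibble(query_id = qid, query_len = qlen, q_start = qs, q_end = qe,
                 strand = strand, target_id = target, target_len = 1000000L,
                 t_start = ts, t_end = te,
                 n_matches = as.integer(round(identity * bl)), block_len = bl,
                 identity = identity)
}

test_that("anchor sets accept one or two consistent high-identity alignments", {
  # a single alignment at identity exactly 0.8 is accepted (inclusive)
  one <- anchor_rec("r", 10000L, 0L, 5000L, 10000L, 15000L, identity = 0.8)
  expect_equal(nrow(consistent_anchor_set(one)), 1L)
  below <- anchor_rec("r", 10000L, 0L, 5000L, 10000L, 15000L, identity = 0.79)
  expect_null(consistent_anchor_set(below))
  # two consistent alignments
  two <- dplyr::bind_rows(
    anchor_rec("r", 12000L, 0L, 5000L, 10000L, 15000L),
    anchor_rec("r", 12000L, 7000L, 12000L, 15000L, 20000L))
  expect_equal(nrow(consistent_anchor_set(two)), 2L)
  # different chromosomes: reject
  cross <- two
  cross$target_id[2] <- "chr2"
  expect_null(consistent_anchor_set(cross))
  # opposite strands: reject
  flip <- two
  flip$strand[2] <- "-"
  expect_null(consistent_anchor_set(flip))
  # wrong reference order for '+': reject
  swapped <- dplyr::bind_rows(
    anchor_rec("r", 12000L, 0L, 5000L, 15000L, 20000L),
    anchor_rec("r", 12000L, 7000L, 12000L, 10000L, 15000L))
  expect_null(consistent_anchor_set(swapped))
  # three alignments: reject
  three <- dplyr::bind_rows(two,
    anchor_rec("r", 12000L, 5000L, 7000L, 30000L, 32000L))
  expect_null(consistent_anchor_set(three))
  # micro-overlap on the reference within the slack is tolerated
  micro <- dplyr::bind_rows(
    anchor_rec("r", 12000L, 0L, 5000L, 10000L, 15010L),
    anchor_rec("r", 12000L, 7000L, 12000L, 15000L, 20000L))
  expect_equal(nrow(consistent_anchor_set(micro)), 2L)
  big_overlap <- dplyr::bind_rows(
    anchor_rec("r", 12000L, 0L, 5000L, 10000L, 15500L),
    anchor_rec("r", 12000L, 7000L, 12000L, 15000L, 20000L))
  expect_null(consistent_anchor_set(big_overlap))
})

test_that("gaps between or outside anchors become BEP/SEP calls", {
  read <- tibble::tibble(read_id = "r", sequence = rand_dna(12000))
  two <- dplyr::bind_rows(
    anchor_rec("r", 12000L, 0L, 5000L, 10000L, 15000L),
    anchor_rec("r", 12000L, 7000L, 12000L, 15000L, 20000L))
  bep <- call_placements(read, two)
  expect_equal(bep$kind, "BEP")
  expect_equal(bep$fragment_len, 2000L)
  expect_equal(c(bep$bp_start, bep$bp_end), c(15000L, 15000L))  # abutting
  expect_equal(bep$sequence, substring(read$sequence, 5001, 7000))
  # SEP at a read start: breakpoint at the anchor's facing boundary
  one <- anchor_rec("r", 12000L, 1500L, 6000L, 40000L, 44500L)
  sep <- call_placements(tibble::tibble(read_id = "r",
                                        sequence = rand_dna(6000)), one)
  expect_equal(sep$kind, "SEP")
  expect_equal(sep$fragment_len, 1500L)
  expect_equal(c(sep$bp_start, sep$bp_end), c(40000L, 40000L))
  # on the minus strand a read-start gap faces the anchor's target end
  one_m <- anchor_rec("r", 6000L, 1500L, 6000L, 40000L, 44500L, strand = "-")
  sep_m <- call_placements(tibble::tibble(read_id = "r",
                                          sequence = rand_dna(6000)), one_m)
  expect_equal(c(sep_m$bp_start, sep_m$bp_end), c(44500L, 44500L))
  # a gap of exactly 1000 is not called (strictly longer required)
  two_exact <- dplyr::bind_rows(
    anchor_rec("r", 11000L, 0L, 5000L, 10000L, 15000L),
    anchor_rec("r", 11000L, 6000L, 11000L, 15000L, 20000L))
  expect_equal(nrow(call_placements(
    tibble::tibble(read_id = "r", sequence = rand_dna(11000)), two_exact)), 0L)
})

mk_sep <- function(pos, read = "r1", target = "chr1", len = 1500L,
                   sample = "s") {
  tibble::tibble(kind = "SEP", sample_id = sample, read_id = read,
                 fragment_id = paste0(read, ":", pos), sequence = strrep("A", len),
                 fragment_len = len, target_id = target,
                 bp_start = as.integer(pos), bp_end = as.integer(pos),
                 strand = "+")
}

test_that("SEP merging is single linkage with an inclusive distance", {
  calls <- dplyr::bind_rows(mk_sep(1000, "r1"), mk_sep(1080, "r2"),
                            mk_sep(1300, "r3"))
  cl <- merge_sep(calls)
  expect_equal(sort(cl$support), c(1L, 2L))
  # distance exactly 100 merges
  cl2 <- merge_sep(dplyr::bind_rows(mk_sep(1000, "r1"), mk_sep(1100, "r2")))
  expect_equal(cl2$support, 2L)
  expect_equal(c(cl2$bp_start, cl2$bp_end), c(1000L, 1100L))
  # singleton passes through; non-SEP input is an error
  expect_equal(merge_sep(mk_sep(5))$support, 1L)
  bad <- mk_sep(5)
  bad$kind <- "BEP"
  expect_error(merge_sep(bad), "non-SEP")
})

test_that("SEP merging equals brute-force single linkage on random sets", {
  withr::with_seed(81, {
    for (i in 1:100) {
      n <- sample(1:60, 1)
      pos <- sample(0:5000, n, TRUE)
      calls <- dplyr::bind_rows(lapply(seq_len(n), function(k) {
        mk_sep(pos[k], read = sprintf("r%03d", k))
      }))
      cl <- merge_sep(calls, max_dist = 100)
      want <- oracle_single_linkage(pos, 100)
      expect_equal(nrow(cl), length(unique(want)))
      # membership agrees: calls in one oracle group share one cluster
      frag_cluster <- setNames(rep(cl$cluster_id, lengths(cl$member_ids)),
                               unlist(cl$member_ids))
      got <- frag_cluster[calls$fragment_id]
      expect_true(all(tapply(got, want, function(x) length(unique(x)) == 1)))
      expect_equal(sum(cl$support), n)
    }
  })
})

test_that("BEP merging needs proximity and near-full-length fragment overlap", {
  withr::with_seed(82, {
    insertion <- rand_dna(2000)
    mk_bep <- function(id, seq, pos) {
      tibble::tibble(kind = "BEP", sample_id = "s", read_id = id,
                     fragment_id = paste0(id, ":frag"), sequence = seq,
                     fragment_len = nchar(seq), target_id = "chr1",
                     bp_start = as.integer(pos), bp_end = as.integer(pos),
                     strand = "+")
    }
    # two error-laden copies of the same insertion at the same locus merge
    c1 <- mk_bep("r1", mutate_dna(insertion, 0.03, 0.01, 0.01), 50000)
    c2 <- mk_bep("r2", mutate_dna(insertion, 0.03, 0.01, 0.01), 50030)
    merged <- merge_bep(dplyr::bind_rows(c1, c2))
    expect_equal(nrow(merged), 1L)
    expect_equal(merged$support, 2L)
    # same-locus calls with unrelated fragments stay apart
    c3 <- mk_bep("r3", rand_dna(2000), 50050)
    apart <- merge_bep(dplyr::bind_rows(c1, c3))
    expect_equal(nrow(apart), 2L)
    # the identical call twice merges reflexively
    twice <- merge_bep(dplyr::bind_rows(c1, c1))
    expect_equal(twice$support, 2L)
    # far-apart copies of the same insertion stay apart (proximity fails)
    far <- merge_bep(dplyr::bind_rows(c1, mk_bep("r4", insertion, 80000)))
    expect_equal(nrow(far), 2L)
  })
})

test_that("cluster support filtering keeps at least min_support members", {
  withr::with_seed(83, {
    calls <- dplyr::bind_rows(lapply(seq_len(13), function(k) {
      pos <- c(rep(1000, 1), rep(5000, 2), rep(9000, 3), rep(13000, 7))[k]
      mk_sep(pos, read = sprintf("r%02d", k), len = sample(1200:2000, 1))
    }))
    cl <- merge_sep(calls)
    expect_setequal(cl$support, c(1L, 2L, 3L, 7L))
    kept <- filter_clusters(cl, min_support = 3)
    expect_equal(sort(kept$support), c(3L, 7L))
    expect_equal(nrow(filter_clusters(cl[0, ])), 0L)
    # representative is the longest member fragment
    for (i in seq_len(nrow(cl))) {
      members <- calls[calls$fragment_id %in% cl$member_ids[[i]], ]
      expect_equal(cl$representative_len[i], max(members$fragment_len))
    }
  })
})

test_that("sharing labels reflect sample and population spread", {
  withr::with_seed(84, {
    seqA <- rand_dna(1500)
    seqB <- rand_dna(1500)
    mk_pl <- function(sample, clusters) {
      structure(list(sample_id = sample, clusters = clusters,
                     calls = NULL, all_clusters = clusters, min_support = 3),
                class = "novel_placements")
    }
    clu <- function(id, seq, pos, sample) {
      tibble::tibble(cluster_id = id, kind = "BEP", target_id = "chr1",
                     bp_start = as.integer(pos), bp_end = as.integer(pos),
                     support = 3L, representative_id = paste0(id, ":rep"),
                     representative_len = nchar(seq), sequence = seq,
                     samples = list(sample), member_ids = list(character(3)))
    }
    pls <- list(
      s1 = mk_pl("s1", dplyr::bind_rows(clu("c1", seqA, 1000, "s1"),
                                        clu("c2", seqB, 9000, "s1"))),
      s2 = mk_pl("s2", clu("c1", mutate_dna(seqA, 0.02), 1050, "s2")),
      s3 = mk_pl("s3", clu("c1", mutate_dna(seqA, 0.02), 1020, "s3")))
    pops <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                           population = c("popA", "popA", "popB"))
    sh <- classify_sharing(pls, pops)
    lblA <- unique(sh$label[sh$bp_start < 5000])
    expect_equal(lblA, "population-shared")
    expect_equal(sh$label[sh$bp_start == 9000], "individual")
    # two samples confined to one population
    sh2 <- classify_sharing(pls[c("s1", "s2")],
                            pops[pops$sample_id %in% c("s1", "s2"), ])
    expect_equal(unique(sh2$label[sh2$bp_start < 5000]), "population-specific")
    expect_error(classify_sharing(pls, pops[1:2, ]), "missing")
  })
})
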