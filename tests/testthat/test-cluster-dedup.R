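pair_aln <- function(qid, tid, qlen, tlen, qs, qe, ts, te) {
  tibble::tibble(query_id = qid, query_len = qlen, q_start = qs, q_end = qe,
                 strand = "+", target_id = tid, target_len = tlen,
                 t_start = ts, t_end = te, n_matches = qe - qs,
                 block_len = qe - qs)
}

test_that("pair coverage is measured on the shorter sequence after merging", {
  # full coverage of the shorter partner
  a <- pair_aln("a", "b", 1000L, 400L, 0L, 400L, 0L, 400L)
  expect_equal(pair_coverage(a, 1000, 400, "a", "b"), 1)
  # equal lengths, merged blocks 0-600
  b <- pair_aln("a", "b", 1000L, 1000L, c(10L, 260L), c(310L, 610L),
                c(0L, 250L), c(300L, 600L))
  expect_equal(pair_coverage(b, 1000, 1000, "a", "b"), 0.6)
  expect_equal(pair_coverage(b[0, ], 1000, 1000, "a", "b"), 0)
  expect_error(pair_coverage(pair_aln("a", "z", 10L, 10L, 0L, 5L, 0L, 5L),
                             10, 10, "a", "b"), "not all between")
})

test_that("clusters are transitive components with a strict coverage edge", {
  frags <- tibble::tibble(
    fragment_id = c("a", "b", "c"),
    sequence = c(rand_dna(1000), rand_dna(900), rand_dna(800)))
  aln <- dplyr::bind_rows(
    pair_aln("a", "b", 1000L, 900L, 0L, 850L, 0L, 850L),   # cov b ~0.94
    pair_aln("b", "c", 900L, 800L, 0L, 700L, 0L, 700L),    # cov c 0.875
    pair_aln("a", "c", 1000L, 800L, 0L, 100L, 0L, 100L))   # cov c 0.125
  cl <- build_clusters(frags, aln, cov_threshold = 0.8)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$member_ids[[1]], c("a", "b", "c"))
  expect_equal(cl$representative_id, "a")
  # no alignments: all singletons
  cl0 <- build_clusters(frags, aln[0, ])
  expect_equal(nrow(cl0), 3L)
  expect_equal(sum(cl0$n_members), 3L)
  # coverage exactly at the threshold is NOT an edge
  exact <- pair_aln("a", "c", 1000L, 800L, 0L, 640L, 0L, 640L)  # cov = 0.8
  cl8 <- build_clusters(frags[c(1, 3), ], exact, cov_threshold = 0.8)
  expect_equal(nrow(cl8), 2L)
})

test_that("clustering equals brute-force transitive closure on random instances", {
  withr::with_seed(51, {
    for (rep in 1:60) {
      n <- sample(2:40, 1)
      ids <- sprintf("f%03d", seq_len(n))
      lens <- sample(400:3000, n, TRUE)
      frags <- tibble::tibble(fragment_id = ids,
                              sequence = vapply(lens, strrep, character(1),
                                                x = "A"))
      n_pair <- sample(0:(2 * n), 1)
      aln <- NULL
      if (n_pair > 0) {
        i <- sample(n, n_pair, TRUE)
        j <- sample(n, n_pair, TRUE)
        keep <- i != j
        i <- i[keep]; j <- j[keep]
        if (length(i) > 0) {
          short <- pmin(lens[i], lens[j])
          covlen <- vapply(short, function(s) sample.int(s, 1L), integer(1))
          aln <- pair_aln(ids[i], ids[j], lens[i], lens[j],
                          rep(0L, length(i)), covlen,
                          rep(0L, length(i)), covlen)
          # coverage applies to the shorter sequence: move block there
          fixrow <- lens[i] < lens[j]
          # (block identical on both; fine either way)
        }
      }
      if (is.null(aln)) aln <- pair_aln("x", "y", 10L, 10L, 0L, 5L, 0L, 5L)[0, ]
      cl <- build_clusters(frags, aln, cov_threshold = 0.8)
      # oracle: recompute edges per-pair with the boolean-array coverage
      edges <- list()
      if (nrow(aln) > 0) {
        key <- paste(pmin(aln$query_id, aln$target_id),
                     pmax(aln$query_id, aln$target_id))
        for (kk in unique(key)) {
          rows <- aln[key == kk, ]
          ia <- pmin(rows$query_id[1], rows$target_id[1])
          ib <- pmax(rows$query_id[1], rows$target_id[1])
          la <- lens[match(ia, ids)]; lb <- lens[match(ib, ids)]
          sid <- if (la <= lb) ia else ib
          slen <- min(la, lb)
          iv <- dplyr::bind_rows(
            tibble::tibble(start = rows$q_start[rows$query_id == sid],
                           end = rows$q_end[rows$query_id == sid]),
            tibble::tibble(start = rows$t_start[rows$target_id == sid],
                           end = rows$t_end[rows$target_id == sid]))
          if (oracle_covered_len(iv, slen) / slen > 0.8) {
            edges[[length(edges) + 1L]] <- c(ia, ib)
          }
        }
      }
      edf <- if (length(edges)) as.data.frame(do.call(rbind, edges))
             else data.frame(a = character(), b = character())
      want <- oracle_components(ids, edf)
      got <- integer(n)
      for (ci in seq_len(nrow(cl))) {
        got[match(cl$member_ids[[ci]], ids)] <- ci
      }
      # same partition (labels may differ)
      expect_equal(length(unique(want)), nrow(cl))
      expect_true(all(tapply(want, got, function(x) length(unique(x)) == 1)))
      expect_equal(sum(cl$n_members), n)
    }
  })
})

test_that("cluster output is independent of fragment input order", {
  withr::with_seed(52, {
    n <- 20
    ids <- sprintf("f%02d", 1:n)
    lens <- sample(500:2000, n, TRUE)
    frags <- tibble::tibble(fragment_id = ids,
                            sequence = vapply(lens, function(l) rand_dna(l),
                                              character(1)))
    i <- sample(n, 15, TRUE); j <- sample(n, 15, TRUE)
    keep <- i != j; i <- i[keep]; j <- j[keep]
    covlen <- pmin(lens[i], lens[j])
    aln <- pair_aln(ids[i], ids[j], lens[i], lens[j],
                    rep(0L, length(i)), covlen, rep(0L, length(i)), covlen)
    c1 <- build_clusters(frags, aln)
    perm <- sample(n)
    c2 <- build_clusters(frags[perm, ], aln[sample(nrow(aln)), ])
    expect_equal(c1, c2)
  })
})

test_that("representatives are the longest members with id tie-breaks", {
  frags <- tibble::tibble(
    fragment_id = c("x", "b", "a"),
    sequence = c(strrep("A", 400), strrep("C", 900), strrep("G", 900)))
  aln <- dplyr::bind_rows(
    pair_aln("x", "b", 400L, 900L, 0L, 400L, 0L, 400L),
    pair_aln("b", "a", 900L, 900L, 0L, 900L, 0L, 900L))
  cl <- build_clusters(frags, aln)
  expect_equal(cl$representative_id, "a")  # 900 bp, tie broken to 'a'
  reps <- cluster_representatives(cl, frags)
  expect_equal(reps$sequence, strrep("G", 900))
  # every representative is maximal in its cluster
  withr::with_seed(53, {
    n <- 30
    ids <- sprintf("g%02d", 1:n)
    lens <- sample(300:1500, n, TRUE)
    frags2 <- tibble::tibble(fragment_id = ids,
                             sequence = vapply(lens, strrep, character(1),
                                               x = "T"))
    cl2 <- build_clusters(frags2, pair_aln("x", "y", 5L, 5L, 0L, 2L, 0L, 2L)[0, ])
    reps2 <- cluster_representatives(cl2, frags2)
    for (ci in seq_len(nrow(cl2))) {
      members <- cl2$member_ids[[ci]]
      expect_equal(cl2$representative_len[ci],
                   max(lens[match(members, ids)]))
    }
  })
})
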