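mk_aln <- function(qid, qlen, qs, qe) {
  tibble::tibble(query_id = qid, query_len = qlen, q_start = qs, q_end = qe,
                 strand = "+", target_id = "ref", target_len = 100000L,
                 t_start = qs, t_end = qe,
                 n_matches = qe - qs, block_len = qe - qs)
}

test_that("aligned query intervals merge overlaps and reject mixed reads", {
  a <- mk_aln("r", 1000L, c(0L, 350L), c(400L, 600L))
  expect_equal(aligned_query_intervals(a),
               tibble::tibble(start = 0L, end = 600L))
  expect_equal(nrow(aligned_query_intervals(a[0, ])), 0L)
  b <- mk_aln("r", 1000L, c(0L, 200L, 250L), c(100L, 300L, 400L))
  expect_equal(aligned_query_intervals(b),
               tibble::tibble(start = c(0L, 200L), end = c(100L, 400L)))
  mixed <- dplyr::bind_rows(a, mk_aln("other", 1000L, 0L, 10L))
  expect_error(aligned_query_intervals(mixed), "mixed")
})

test_that("unmapped fragments keep only gaps strictly longer than the minimum", {
  read <- tibble::tibble(read_id = "r", sequence = rand_dna(1000))
  # gap of exactly 200 between blocks: below the cut
  none <- unmapped_fragments(read, tibble::tibble(start = c(0L, 600L),
                                                  end = c(400L, 1000L)))
  expect_equal(nrow(none), 0L)
  # entirely unmapped read: one full-length fragment
  full <- unmapped_fragments(read, tibble::tibble(start = integer(),
                                                  end = integer()))
  expect_equal(nrow(full), 1L)
  expect_equal(c(full$start, full$end), c(0L, 1000L))
  expect_equal(full$sequence, read$sequence)
  # 700-base tail kept
  tail1 <- unmapped_fragments(read, tibble::tibble(start = 0L, end = 300L))
  expect_equal(c(tail1$start, tail1$end), c(300L, 1000L))
  expect_equal(tail1$sequence, substring(read$sequence, 301, 1000))
  expect_error(unmapped_fragments(read, tibble::tibble(start = 0L, end = 1200L)),
               "exceeds")
})

test_that("subtracting mapped regions re-maps children onto the source read", {
  read_seq <- rand_dna(2000)
  frag <- tibble::tibble(fragment_id = "r:600-1500", source_read_id = "r",
                         start = 600L, end = 1500L,
                         sequence = substring(read_seq, 601, 1500),
                         round_created = 0L)
  # aligned [300,500) within the fragment: left piece is exactly 300 (dropped),
  # right piece 400 kept
  aln <- mk_aln("r:600-1500", 900L, 300L, 500L)
  out <- subtract_mapped(frag, aln)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(1100L, 1500L))
  expect_equal(out$sequence, substring(read_seq, 1101, 1500))
  expect_equal(out$round_created, 1L)
  # no alignments: unchanged single child
  out2 <- subtract_mapped(frag, mk_aln("x", 1L, 0L, 1L)[0, ])
  expect_equal(out2$sequence, frag$sequence)
  # fully aligned: no children
  out3 <- subtract_mapped(frag, mk_aln("r:600-1500", 900L, 0L, 900L))
  expect_equal(nrow(out3), 0L)
  expect_error(subtract_mapped(frag, mk_aln("ghost", 900L, 0L, 100L)),
               "unknown fragment")
})

test_that("interval operations agree exactly with the per-base oracle", {
  withr::with_seed(31, {
    for (i in 1:200) {
      len <- sample(50:5000, 1)
      k <- sample(0:10, 1)
      iv <- if (k == 0) tibble::tibble(start = integer(), end = integer())
      else {
        s <- vapply(seq_len(k), function(.) sample.int(len, 1L) - 1L, integer(1))
        e <- vapply(s, function(x) x + sample.int(len - x, 1L), integer(1))
        tibble::tibble(start = s, end = e)
      }
      expect_identical(as.data.frame(interval_merge(iv)),
                       as.data.frame(oracle_merge(iv, len)))
      expect_identical(as.data.frame(interval_complement(iv, len)),
                       as.data.frame(oracle_complement(iv, len)))
    }
  })
})

test_that("align-and-subtract rounds remove reference sequence and keep novel", {
  withr::with_seed(32, {
    ref <- rand_dna(30000)
    idx <- seq_index(c(ref = ref))
    novel <- rand_dna(1200)
    reads <- tibble::tibble(
      read_id = c("ref_read", "novel_read", "chimera"),
      sequence = c(substr(ref, 2001, 3600), novel,
                   paste0(rand_dna(1000), substr(ref, 10001, 11000))))
    frags <- fragments_from_reads(reads)
    rr <- run_rounds(frags, idx)
    out <- rr$fragments
    # reference copy eliminated; novel read fully survives
    expect_false(any(out$source_read_id == "ref_read"))
    expect_equal(out$sequence[out$source_read_id == "novel_read"], novel)
    # chimera: surviving child is the novel half (within aligner end slop)
    ch <- out[out$source_read_id == "chimera", ]
    expect_equal(nrow(ch), 1L)
    expect_lte(ch$start, 20L)
    expect_true(abs(ch$end - 1000L) <= 20L)
    # monotonicity of surviving bases across rounds
    expect_true(all(diff(rr$rounds$bp_out) <= 0))
    expect_true(all(rr$rounds$bp_out <= rr$rounds$bp_in))
    # survivors all strictly longer than the minimum
    expect_true(all(nchar(out$sequence) > 300))
    # fragment sequences equal the read substring at their interval
    for (i in seq_len(nrow(out))) {
      src <- reads$sequence[reads$read_id == out$source_read_id[i]]
      expect_identical(out$sequence[i],
                       substring(src, out$start[i] + 1L, out$end[i]))
    }
  })
})
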