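test_that("the generator is fully deterministic for a fixed config", {
  cfg <- sim_config(seed = 13L, ref_len = 20000L, n_insertions = 3L, depth = 4)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
  expect_identical(a$provenance$read_id, b$provenance$read_id)
})

test_that("reference composition is near-uniform with bounded repeat content", {
  ref <- sim_reference(100000L, seed = 42L)
  gc <- stringr::str_count(ref$sequence, "[GC]") / 100000
  expect_true(gc > 0.48 && gc < 0.52)
  # without planted repeats the dust fraction stays small
  plain <- sim_reference(20000L, seed = 42L, simple_repeat_frac = 0)
  m <- dust_mask(plain$sequence)
  expect_lt(sum(m$end - m$start) / 20000, 0.05)
  # with the default fraction, planted stretches are detectable
  rep5 <- sim_reference(50000L, seed = 42L, simple_repeat_frac = 0.05)
  m5 <- dust_mask(rep5$sequence)
  expect_gt(sum(m5$end - m5$start) / 50000, 0.02)
})

test_that("planted insertions are spaced, categorised and absent from the reference", {
  cfg <- sim_config(seed = 42L)
  ref <- sim_reference(cfg$ref_len, cfg$seed, cfg$simple_repeat_frac)
  pl <- plant_insertions(ref, cfg)
  tr <- pl$truth
  expect_equal(nrow(tr), 20L)
  expect_true(all(diff(sort(tr$ref_pos)) >= 5000))
  expect_true(all(tr$ref_pos > 0 & tr$ref_pos < cfg$ref_len))
  expect_equal(sum(tr$category == "shared"), 10L)
  expect_equal(sum(tr$category == "individual"), 10L)
  # novelty: no insertion aligns to the reference over a 300 bp stretch
  idx <- seq_index(ref)
  aln <- minialign(tibble::tibble(seq_id = tr$insertion_id,
                                  sequence = tr$sequence), idx,
                   preset = "sensitive")
  if (nrow(aln) > 0) expect_true(all(aln$q_end - aln$q_start < 300))
  # donors contain their assigned insertions at the recorded loci
  for (sid in cfg$samples$sample_id) {
    donor <- pl$donors[[sid]]
    for (i in seq_len(nrow(donor$loci))) {
      ins <- tr[tr$insertion_id == donor$loci$insertion_id[i], ]
      got <- substring(donor$sequence$sequence, donor$loci$donor_start[i] + 1L,
                       donor$loci$donor_end[i])
      expect_identical(got, ins$sequence)
    }
  }
})

test_that("error-free reads are exact donor substrings at roughly the target depth", {
  cfg <- sim_config(seed = 7L, ref_len = 30000L, n_insertions = 3L, depth = 10,
                    sub_rate = 0, ins_rate = 0, del_rate = 0, contam_frac = 0)
  sim <- simulate_dataset(cfg)
  donor <- sim$donors$s1$sequence$sequence
  reads <- sim$reads$s1
  for (i in seq_len(min(nrow(reads), 25))) {
    s <- reads$sequence[i]
    expect_true(grepl(s, donor, fixed = TRUE) ||
                  grepl(revcomp(s), donor, fixed = TRUE))
  }
  total <- sum(nchar(reads$sequence))
  expect_true(abs(total / nchar(donor) - 10) / 10 < 0.1)
  # error-free reads carry the maximum quality
  expect_true(all(unlist(reads$qualities[1:5]) >= 58))
})

test_that("realized read error matches the configured rates", {
  cfg <- sim_config(seed = 5L, ref_len = 20000L, n_insertions = 2L, depth = 5)
  sim <- simulate_dataset(cfg)
  pv <- sim$provenance[sim$provenance$source == "host", ]
  expect_equal(mean(pv$error_rate), 0.08, tolerance = 0.01)
  # per-base qualities track the realized error: mean read quality near the
  # Phred equivalent of 8% error (Q ~ 11)
  mq <- mean_quality(sim$reads$s1$qualities)
  expect_true(all(mq > 9 & mq < 14))
})

test_that("bad-read mode emits reads the quality filter removes", {
  cfg <- sim_config(seed = 8L, ref_len = 20000L, n_insertions = 2L, depth = 6,
                    bad_read_frac = 0.3, contam_frac = 0)
  sim <- simulate_dataset(cfg)
  out <- filter_by_quality(sim$reads$s1, min_q = 10)
  bad_ids <- sim$provenance$read_id[sim$provenance$bad]
  expect_gt(length(bad_ids), 0L)
  expect_true(all(!out$reads$read_id %in% bad_ids))
  expect_true(mean(out$report$passed) < 1)
})

test_that("contaminant reads are labelled and classified by the truth classifier", {
  cfg <- sim_config(seed = 9L, ref_len = 20000L, n_insertions = 2L, depth = 6,
                    contam_frac = 0.2)
  sim <- simulate_dataset(cfg)
  pv <- sim$provenance[sim$provenance$sample_id == "s1", ]
  frac <- mean(pv$source == "contaminant")
  expect_lt(abs(frac - 0.2), 0.05)
  frags <- fragments_from_reads(sim$reads$s1)
  calls <- sim$classifier(frags)
  expect_equal(calls$seq_id, frags$fragment_id)
  is_ct <- setNames(pv$source, pv$read_id)[frags$source_read_id] == "contaminant"
  expect_equal(calls$classified, unname(is_ct))
  expect_true(all(calls$taxid[calls$classified] == 562L))
  # classifier output survives a Kraken2-format round trip
  f <- tempfile()
  write_kraken2(calls, f)
  back <- read_kraken2(f)
  expect_equal(back$classified, calls$classified)
  expect_equal(back$lca, calls$lca)
})
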