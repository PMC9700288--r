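test_that("FASTQ records are parsed with decoded Phred+33 qualities", {
  f <- tmp_lines(c("@r1", "ACGT", "+", "IIII",
                   "@r2", "ACGTA", "+", "!!!!!"))
  reads <- read_fastq(f)
  expect_equal(reads$read_id, c("r1", "r2"))
  expect_equal(reads$qualities[[1]], rep(40L, 4))
  expect_equal(reads$qualities[[2]], rep(0L, 5))
})

test_that("malformed FASTQ raises a parse error naming the line", {
  f <- tmp_lines(c("@r1", "ACGT", "+", "III"))  # 4-base seq, 3-char qual
  expect_error(read_fastq(f), "length mismatch at line 4")
  f2 <- tmp_lines(c("@r1", "ACGT", "oops", "IIII"))
  expect_error(read_fastq(f2), "line 3 does not start with '\\+'")
  f3 <- tmp_lines(c("@r1", "ACGT", "+", "IIII", "@r2", "AC"))
  expect_error(read_fastq(f3), "truncated")
})

test_that("FASTQ round-trips byte-stably", {
  reads <- tibble::tibble(
    read_id = c("a", "b"),
    sequence = c("ACGTACGT", "TTTT"),
    qualities = list(c(40L, 40L, 2L, 13L, 0L, 7L, 39L, 20L), rep(12L, 4)))
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  expect_equal(read_fastq(f), reads)
  b1 <- readLines(f)
  write_fastq(read_fastq(f), f)
  expect_identical(readLines(f), b1)
})

test_that("FASTA reading accepts multi-line records and normalises sequences", {
  f <- tmp_lines(c(">s1 description text", "acgu", "ACGT", ">s2", "ACXTN"))
  expect_warning(fa <- read_fasta(f), "replaced 1 non-ACGTN")
  expect_equal(fa$seq_id, c("s1", "s2"))
  expect_equal(fa$sequence, c("ACGTACGT", "ACNTN"))
})

test_that("FASTA writing honours line width and round-trips", {
  rec <- tibble::tibble(seq_id = "x", sequence = rand_dna(130))
  f <- tempfile(fileext = ".fa")
  write_fasta(rec, f, line_width = 60)
  lines <- readLines(f)
  expect_equal(length(lines), 4L)  # header + 3 sequence lines
  expect_equal(nchar(lines[2:4]), c(60L, 60L, 10L))
  expect_equal(read_fasta(f), rec)
  # empty set: empty file, no error
  f2 <- tempfile(fileext = ".fa")
  write_fasta(rec[0, ], f2)
  expect_equal(file.size(f2), 0)
  expect_error(write_fasta(tibble::tibble(seq_id = "", sequence = "ACGT"),
                           tempfile()), "empty")
})

test_that("PAF lines parse into validated alignment records", {
  a <- parse_paf("r1\t1000\t0\t400\t+\tchr1\t5000\t100\t500\t380\t400\t60")
  expect_equal(a$identity, 0.95)
  expect_equal(a$strand, "+")
  b <- parse_paf("r1\t1000\t0\t400\t-\tchr1\t5000\t100\t500\t400\t400\t60")
  expect_equal(b$identity, 1)
  expect_equal(b$strand, "-")
  expect_error(parse_paf("r1\t1000\t0\t400\t+\tchr1\t5000\t100\t500\t380\t400"),
               "11 fields")
  expect_error(parse_paf("r1\t1000\t400\t400\t+\tchr1\t5000\t100\t500\t380\t400\t60"),
               "q_start < q_end")
})

test_that("PAF format/parse round-trips on random valid records", {
  withr::with_seed(11, {
    n <- 1000
    qlen <- sample(200:5000, n, TRUE)
    qs <- vapply(qlen, function(l) sample.int(l - 1L, 1L) - 1L, integer(1))
    qe <- vapply(seq_len(n), function(i) qs[i] + sample.int(qlen[i] - qs[i], 1L),
                 integer(1))
    tlen <- sample(1000:50000, n, TRUE)
    ts <- vapply(tlen, function(l) sample.int(l - 1L, 1L) - 1L, integer(1))
    te <- vapply(seq_len(n), function(i) ts[i] + sample.int(tlen[i] - ts[i], 1L),
                 integer(1))
    bl <- pmax(qe - qs, te - ts)
    nm <- vapply(bl, function(b) sample.int(b, 1L), integer(1))
    rec <- tibble::tibble(
      query_id = sprintf("q%04d", seq_len(n)), query_len = qlen,
      q_start = qs, q_end = qe,
      strand = sample(c("+", "-"), n, TRUE),
      target_id = sprintf("t%02d", sample(1:20, n, TRUE)), target_len = tlen,
      t_start = ts, t_end = te, n_matches = nm, block_len = bl,
      mapq = sample(0:255, n, TRUE))
    back <- parse_paf(format_paf(rec))
    expect_equal(back[names(rec)], rec)
  })
})

test_that("Kraken2-style classification lines parse with LCA details", {
  k <- parse_kraken2_line("C\tf1\t562\t600\t562:10 0:5")
  expect_true(k$classified)
  expect_equal(k$taxid, 562L)
  expect_equal(k$lca[[1]]$taxid, c("562", "0"))
  expect_equal(k$lca[[1]]$count, c(10L, 5L))
  u <- parse_kraken2_line("U\tf2\t0\t600\t0:566")
  expect_false(u$classified)
  amb <- parse_kraken2_line("C\tf3\t2\t600\t2:3 A:4 0:2")
  expect_equal(amb$lca[[1]]$taxid, c("2", "A", "0"))
  expect_error(parse_kraken2_line("X\tf1\t562\t600\t562:10"), "unknown status")
  expect_error(parse_kraken2_line("C\tf1\t562\t600\t562-10"), "malformed token")
})

test_that("BED5 is written 0-based half-open and reads back", {
  f <- tempfile(fileext = ".bed")
  write_bed(tibble::tibble(target_id = "chr1", start = 100L, end = 250L,
                           name = "clu1", score = 5L), f)
  expect_identical(readLines(f), "chr1\t100\t250\tclu1\t5")
  back <- read_bed(f)
  expect_equal(back$start, 100L)
  expect_equal(back$name, "clu1")
})

test_that("taxonomy nodes tables parse in both dialects", {
  tsv <- tmp_lines(c("2\t131567\tsuperkingdom", "131567\t1\tno rank",
                     "1\t1\tno rank"))
  t1 <- read_taxonomy_nodes(tsv)
  expect_s3_class(t1, "novel_taxonomy")
  dmp <- tmp_lines(c("2\t|\t131567\t|\tsuperkingdom\t|",
                     "131567\t|\t1\t|\tno rank\t|",
                     "1\t|\t1\t|\tno rank\t|"))
  t2 <- read_taxonomy_nodes(dmp)
  expect_equal(t2$parent[["2"]], 131567L)
  expect_equal(t1$parent, t2$parent)
})

test_that("the bundled synthetic nodes table supports the screening clades", {
  tax <- read_taxonomy_nodes(system.file("extdata", "nodes_synthetic.dmp",
                                         package = "novelseq"))
  expect_true(novelseq:::tax_in_clade(tax, 562L, 2L))      # E. coli in bacteria
  expect_false(novelseq:::tax_in_clade(tax, 9606L, 2L))    # human not
  expect_equal(sort(unname(tax$roots)), c(2L, 2157L, 4751L, 10239L))
})
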