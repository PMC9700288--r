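#' Simulation configuration
#'
#' Study conditions for the synthetic-data generator: a random reference
#' with a small simple-repeat content, donor genomes carrying planted novel
#' insertions (shared across samples, population-specific, or individual),
#' long reads with ONT-like lengths and substitution/insertion/deletion
#' errors with per-base qualities tied to the realized error rate, and
#' contaminant reads from a separate genome.
#'
#' @param seed Base seed; every random stream derives from it, so a config
#'   reproduces its outputs byte-for-byte.
#' @param ref_len Reference length in bp (default 100000).
#' @param n_insertions Number of planted insertions (default 20).
#' @param insertion_len_range Insertion length range in bp (default
#'   `c(500, 3000)`).
#' @param depth Mean read coverage per sample (default 30).
#' @param read_len_meanlog,read_len_sdlog Log-normal read length parameters
#'   (defaults give a mean read length around 10 kb).
#' @param min_read_len Minimum read length (default 1000).
#' @param sub_rate,ins_rate,del_rate Per-base error rates (defaults
#'   0.04/0.02/0.02, i.e. 8% total error); each must be in `[0, 0.2]`.
#' @param contam_frac Fraction of reads drawn from the contaminant genome
#'   (default 0.05).
#' @param contam_len Contaminant genome length (default 30000).
#' @param samples Tibble with `sample_id` and `population` (default two
#'   samples from two populations).
#' @param shared_fraction Fraction of insertions planted in every sample
#'   (default 0.5).
#' @param population_specific_fraction Fraction planted in all samples of
#'   one population (default 0).
#' @param simple_repeat_frac Fraction of the reference covered by planted
#'   short tandem stretches (default 0.05).
#' @param bad_read_frac Fraction of reads emitted with doubled error rates
#'   (mean quality around Q8, so the Q10 filter removes them; default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 42L,
                       ref_len = 100000L,
                       n_insertions = 20L,
                       insertion_len_range = c(500L, 3000L),
                       depth = 30,
                       read_len_meanlog = log(10000),
                       read_len_sdlog = 0.35,
                       min_read_len = 1000L,
                       sub_rate = 0.04, ins_rate = 0.02, del_rate = 0.02,
                       contam_frac = 0.05,
                       contam_len = 30000L,
                       samples = tibble(sample_id = c("s1", "s2"),
                                        population = c("popA", "popB")),
                       shared_fraction = 0.5,
                       population_specific_fraction = 0,
                       simple_repeat_frac = 0.05,
                       bad_read_frac = 0) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2)) abort("error rates must lie in [0, 0.2]")
  if (depth < 1) abort("depth must be >= 1")
  cfg <- list(seed = as.integer(seed), ref_len = as.integer(ref_len),
              n_insertions = as.integer(n_insertions),
              insertion_len_range = as.integer(insertion_len_range),
              depth = depth, read_len_meanlog = read_len_meanlog,
              read_len_sdlog = read_len_sdlog,
              min_read_len = as.integer(min_read_len),
              sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
              contam_frac = contam_frac, contam_len = as.integer(contam_len),
              samples = as_tibble(samples),
              shared_fraction = shared_fraction,
              population_specific_fraction = population_specific_fraction,
              simple_repeat_frac = simple_repeat_frac,
              bad_read_frac = bad_read_frac)
  structure(cfg, class = "sim_config")
}

#' Simulate a reference sequence
#'
#' I.i.d. uniform `ACGT` with planted short tandem stretches (unit 1--6,
#' 100--300 bp each) totalling approximately `simple_repeat_frac` of the
#' length.  Deterministic for a given seed.
#'
#' @param len Reference length (at least 10000).
#' @param seed Seed for this stream.
#' @param simple_repeat_frac Target repeat fraction (default 0.05).
#' @param seq_id Sequence name (default `"ref"`).
#' @return Tibble with `seq_id`, `sequence`.
#' @export
sim_reference <- function(len, seed, simple_repeat_frac = 0.05,
                          seq_id = "ref") {
  if (len < 10000) abort("reference length must be >= 10000")
  withr::with_seed(child_seed(seed, paste0("ref-", seq_id)), {
    s <- strsplit(random_dna(len), "", fixed = TRUE)[[1]]
    if (simple_repeat_frac > 0) {
      target <- simple_repeat_frac * len
      n_stretch <- max(1L, round(target / 200))
      gap <- len %/% (n_stretch + 1L)
      placed <- 0
      for (i in seq_len(n_stretch)) {
        if (placed >= target) break
        sl <- sample(100:300, 1)
        u <- sample(1:6, 1)
        unit <- sample(c("A", "C", "G", "T"), u, replace = TRUE)
        pos <- i * gap + sample(0:(gap %/% 4), 1)
        if (pos + sl > len) next
        s[(pos + 1):(pos + sl)] <- rep(unit, length.out = sl)
        placed <- placed + sl
      }
    }
    tibble(seq_id = seq_id, sequence = paste(s, collapse = ""))
  })
}

#' Plant novel insertions into per-sample donor genomes
#'
#' Insertion sequences are random (not reference-derived, and not
#' low-complexity, so the repeat filter does not remove true positives);
#' loci are non-overlapping and at least 5 kb apart.  Categories (`shared`,
#' `population_specific`, `individual`) are assigned per the configured
#' fractions.
#'
#' @param reference Reference tibble from [sim_reference()].
#' @param config A [sim_config()].
#' @return List with `truth` (tibble: `insertion_id`, `sequence`, `length`,
#'   `ref_pos`, `category`, `samples` list column) and `donors` (named list
#'   per sample: `sequence` tibble and `loci` tibble with donor-coordinate
#'   intervals).
#' @export
plant_insertions <- function(reference, config) {
  cfg <- config
  n <- cfg$n_insertions
  len <- nchar(reference$sequence[1])
  margin <- 2500L
  if (n > 1) {
    spacing <- (len - 2L * margin) %/% (n - 1L)
    if (spacing < 5000L) abort("too many insertions for reference length")
  } else {
    spacing <- 0L
  }
  samples <- cfg$samples
  withr::with_seed(child_seed(cfg$seed, "insertions"), {
    loci <- margin + (seq_len(n) - 1L) * spacing
    jitter_room <- max(0L, (spacing - 5000L) %/% 2L)
    if (jitter_room > 0) loci <- loci + sample(0:jitter_room, n, replace = TRUE)
    ins_len <- sample(cfg$insertion_len_range[1]:cfg$insertion_len_range[2],
                      n, replace = TRUE)
    seqs <- vapply(ins_len, random_dna, character(1))
    n_shared <- round(cfg$shared_fraction * n)
    n_popspec <- round(cfg$population_specific_fraction * n)
    category <- rep("individual", n)
    order_cat <- sample.int(n)  # decouple category from genomic position
    category[order_cat[seq_len(n_shared)]] <- "shared"
    if (n_popspec > 0) {
      category[order_cat[n_shared + seq_len(n_popspec)]] <- "population_specific"
    }
    pops <- unique(samples$population)
    assigned <- vector("list", n)
    i_ind <- 0L
    i_pop <- 0L
    for (i in seq_len(n)) {
      assigned[[i]] <- switch(category[i],
        shared = samples$sample_id,
        population_specific = {
          i_pop <- i_pop + 1L
          p <- pops[(i_pop - 1L) %% length(pops) + 1L]
          samples$sample_id[samples$population == p]
        },
        individual = {
          i_ind <- i_ind + 1L
          samples$sample_id[(i_ind - 1L) %% nrow(samples) + 1L]
        })
    }
    truth <- tibble(
      insertion_id = sprintf("ins%02d", seq_len(n)),
      sequence = seqs, length = ins_len,
      ref_pos = as.integer(loci), category = category,
      samples = assigned
    )
  })
  donors <- lapply(samples$sample_id, function(sid) {
    mine <- truth[vapply(truth$samples, function(s) sid %in% s, logical(1)), ]
    mine <- mine[order(mine$ref_pos), ]
    ref <- reference$sequence[1]
    pieces <- character(0)
    loci <- integer(0)
    prev <- 0L
    offset <- 0L
    for (i in seq_len(nrow(mine))) {
      p <- mine$ref_pos[i]
      pieces <- c(pieces, substring(ref, prev + 1L, p), mine$sequence[i])
      loci <- c(loci, p + offset)
      offset <- offset + mine$length[i]
      prev <- p
    }
    pieces <- c(pieces, substring(ref, prev + 1L, nchar(ref)))
    list(
      sequence = tibble(seq_id = paste0(sid, "_donor"),
                        sequence = paste(pieces, collapse = "")),
      loci = tibble(insertion_id = mine$insertion_id,
                    donor_start = loci, donor_end = loci + mine$length)
    )
  })
  names(donors) <- samples$sample_id
  list(truth = truth, donors = donors)
}

# Apply substitution/insertion/deletion errors to one sequence; returns the
# mutated sequence, per-base qualities tied to the realized error rate, and
# the realized rate itself.
apply_read_errors <- function(sequence, sub, ins, del) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (sub + ins + del > 0) {
    u <- runif(n)
    is_sub <- u < sub
    is_del <- u >= sub & u < sub + del
    is_ins <- u >= sub + del & u < sub + del + ins
    if (any(is_sub)) {
      codes <- match(chars[is_sub], c("A", "C", "G", "T")) - 1L
      codes <- (codes + sample(1:3, sum(is_sub), replace = TRUE)) %% 4L
      chars[is_sub] <- c("A", "C", "G", "T")[codes + 1L]
    }
    reps <- ifelse(is_del, 0L, ifelse(is_ins, 2L, 1L))
    idx <- rep(seq_len(n), reps)
    out <- chars[idx]
    dup <- c(FALSE, idx[-1] == idx[-length(idx)])
    if (any(dup)) out[dup] <- sample(c("A", "C", "G", "T"), sum(dup),
                                     replace = TRUE)
    realized <- (sum(is_sub) + sum(is_del) + sum(is_ins)) / n
  } else {
    out <- chars
    realized <- 0
  }
  q0 <- round(-10 * log10(max(realized, 1e-6)))
  q <- pmin(pmax(q0 + sample(-2:2, length(out), replace = TRUE), 1L), 60L)
  list(sequence = paste(out, collapse = ""), qualities = as.integer(q),
       realized_error = realized)
}

# Draw reads from one genome: starts uniform, lengths log-normal truncated
# to [min_read_len, genome length].
draw_reads <- function(genome_seq, n_reads, cfg, id_prefix, sub, ins, del,
                       bad_frac = 0) {
  glen <- nchar(genome_seq)
  if (n_reads == 0) {
    return(list(reads = tibble(read_id = character(), sequence = character(),
                               qualities = list()),
                meta = tibble(read_id = character(), start = integer(),
                              end = integer(), strand = character(),
                              error_rate = double(), bad = logical())))
  }
  lens <- pmin(pmax(round(rlnorm(n_reads, cfg$read_len_meanlog,
                                 cfg$read_len_sdlog)), cfg$min_read_len), glen)
  starts <- vapply(lens, function(l) sample.int(glen - l + 1L, 1L) - 1L,
                   integer(1))
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  bad <- runif(n_reads) < bad_frac
  rows <- lapply(seq_len(n_reads), function(i) {
    raw <- substring(genome_seq, starts[i] + 1L, starts[i] + lens[i])
    if (strands[i] == "-") raw <- revcomp(raw)
    f <- if (bad[i]) 2 else 1
    er <- apply_read_errors(raw, min(sub * f, 0.4), min(ins * f, 0.4),
                            min(del * f, 0.4))
    list(sequence = er$sequence, qualities = er$qualities,
         error_rate = er$realized_error)
  })
  ids <- sprintf("%s%05d", id_prefix, seq_len(n_reads))
  list(
    reads = tibble(read_id = ids,
                   sequence = vapply(rows, `[[`, character(1), "sequence"),
                   qualities = lapply(rows, `[[`, "qualities")),
    meta = tibble(read_id = ids, start = as.integer(starts),
                  end = as.integer(starts + lens), strand = strands,
                  error_rate = vapply(rows, `[[`, double(1), "error_rate"),
                  bad = bad)
  )
}

#' Simulate reads for one donor genome
#'
#' Read starts are uniform, lengths log-normal (truncated to
#' `[min_read_len, donor length]`), errors applied at the configured rates,
#' per-base qualities drawn around the Phred equivalent of the realized
#' error rate, and `contam_frac` of the reads drawn from the contaminant
#' genome.
#'
#' @param donor Donor entry from [plant_insertions()] (list with `sequence`
#'   and `loci`).
#' @param config A [sim_config()].
#' @param sample_id Sample label (used for read ids and provenance).
#' @param contaminant Contaminant genome tibble (or NULL for none).
#' @return List with `reads` (FASTQ-ready tibble) and `provenance` (tibble:
#'   `read_id`, `sample_id`, `source`, `start`, `end`, `strand`,
#'   `error_rate`, `spans` list of fully-contained insertion ids).
#' @export
sim_reads <- function(donor, config, sample_id, contaminant = NULL) {
  cfg <- config
  glen <- nchar(donor$sequence$sequence[1])
  mean_len <- exp(cfg$read_len_meanlog + cfg$read_len_sdlog^2 / 2)
  n_host <- max(1L, round(cfg$depth * glen / mean_len))
  n_contam <- if (!is.null(contaminant) && cfg$contam_frac > 0) {
    max(0L, round(cfg$contam_frac * n_host / (1 - cfg$contam_frac)))
  } else 0L
  withr::with_seed(child_seed(cfg$seed, paste0("reads-", sample_id)), {
    host <- draw_reads(donor$sequence$sequence[1], n_host, cfg,
                       paste0(sample_id, "_read"),
                       cfg$sub_rate, cfg$ins_rate, cfg$del_rate,
                       cfg$bad_read_frac)
    ctm <- draw_reads(if (n_contam > 0) contaminant$sequence[1] else "",
                      n_contam, cfg, paste0(sample_id, "_contam"),
                      cfg$sub_rate, cfg$ins_rate, cfg$del_rate)
  })
  spans <- lapply(seq_len(nrow(host$meta)), function(i) {
    loci <- donor$loci
    hit <- loci$donor_start >= host$meta$start[i] &
      loci$donor_end <= host$meta$end[i]
    loci$insertion_id[hit]
  })
  prov <- dplyr::bind_rows(
    dplyr::mutate(host$meta, sample_id = sample_id, source = "host",
                  spans = spans),
    dplyr::mutate(ctm$meta, sample_id = sample_id, source = "contaminant",
                  spans = list(character(0)))
  )
  reads <- dplyr::bind_rows(host$reads, ctm$reads)
  # interleave deterministically so contaminants are not a trailing block
  withr::with_seed(child_seed(cfg$seed, paste0("shuffle-", sample_id)), {
    ord <- sample.int(nrow(reads))
  })
  list(reads = reads[ord, ], provenance = prov[ord, ])
}

#' Simulate a full multi-sample dataset with truth tables
#'
#' @param config A [sim_config()].
#' @return A `novel_sim` object: reference, contaminant genome, per-sample
#'   reads, combined provenance, insertion truth table, a `classifier`
#'   function producing Kraken2-style calls for candidate fragments from
#'   provenance, and the built-in screening taxonomy.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  reference <- sim_reference(cfg$ref_len, cfg$seed, cfg$simple_repeat_frac)
  contaminant <- withr::with_seed(child_seed(cfg$seed, "contam"), {
    tibble(seq_id = "contam_genome", sequence = random_dna(cfg$contam_len))
  })
  planted <- plant_insertions(reference, cfg)
  per_sample <- lapply(cfg$samples$sample_id, function(sid) {
    sim_reads(planted$donors[[sid]], cfg, sid, contaminant)
  })
  names(per_sample) <- cfg$samples$sample_id
  provenance <- dplyr::bind_rows(lapply(per_sample, `[[`, "provenance"))
  structure(list(
    config = cfg,
    reference = reference,
    contaminant = contaminant,
    truth = planted$truth,
    donors = planted$donors,
    reads = lapply(per_sample, `[[`, "reads"),
    provenance = provenance,
    classifier = sim_classifier(provenance),
    taxonomy = default_taxonomy()
  ), class = "novel_sim")
}

#' Truth-based classifier emulating Kraken2 output
#'
#' Returns a function mapping a fragment tibble to Kraken2-style calls:
#' fragments from contaminant reads are classified as E. coli (taxid 562)
#' with 90% of counted k-mers in the clade; fragments from host reads are
#' unclassified.
#'
#' @param provenance Provenance tibble from the simulator.
#' @return A function `fragments -> calls tibble`.
#' @export
sim_classifier <- function(provenance) {
  src <- setNames(provenance$source, provenance$read_id)
  function(fragments) {
    fragments <- as_tibble(fragments)
    n <- nrow(fragments)
    contam <- unname(src[fragments$source_read_id]) == "contaminant"
    contam[is.na(contam)] <- FALSE
    lens <- nchar(fragments$sequence)
    tibble(
      seq_id = fragments$fragment_id,
      classified = contam,
      taxid = ifelse(contam, 562L, 0L),
      seq_len = lens,
      lca = lapply(seq_len(n), function(i) {
        k <- max(1L, lens[i] - 34L)
        if (contam[i]) {
          tibble(taxid = c("562", "0"),
                 count = c(max(1L, round(0.9 * k)), max(1L, round(0.1 * k))))
        } else {
          tibble(taxid = "0", count = k)
        }
      })
    )
  }
}

#' Write a simulated dataset to disk
#'
#' Produces `ref.fa`, `contam.fa`, one FASTQ per sample,
#' `truth_insertions.tsv`, `truth.bed`, `provenance.tsv` and
#' `kraken_nodes.tsv` under `outdir`.
#'
#' @param sim A `novel_sim` object.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$reference, file.path(outdir, "ref.fa"))
  write_fasta(sim$contaminant, file.path(outdir, "contam.fa"))
  for (sid in names(sim$reads)) {
    write_fastq(sim$reads[[sid]], file.path(outdir, paste0(sid, ".fastq")))
  }
  tr <- sim$truth
  tr$samples <- vapply(tr$samples, paste, character(1), collapse = ",")
  utils::write.table(tr, file.path(outdir, "truth_insertions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(tibble(target_id = sim$reference$seq_id[1],
                   start = sim$truth$ref_pos, end = sim$truth$ref_pos + 1L,
                   name = sim$truth$insertion_id,
                   score = sim$truth$length),
            file.path(outdir, "truth.bed"))
  pv <- sim$provenance
  pv$spans <- vapply(pv$spans, paste, character(1), collapse = ",")
  utils::write.table(pv, file.path(outdir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.novel_sim <- function(x, ...) {
  cat(sprintf(
    "<novel_sim> ref %d bp, %d insertions (%s), %d sample(s), seed %d\n",
    x$config$ref_len, nrow(x$truth),
    paste(sprintf("%d %s", table(x$truth$category),
                  names(table(x$truth$category))), collapse = ", "),
    nrow(x$config$samples), x$config$seed))
  for (sid in names(x$reads)) {
    cat(sprintf("  %s: %d reads (%.0f bp)\n", sid, nrow(x$reads[[sid]]),
                sum(nchar(x$reads[[sid]]$sequence))))
  }
  invisible(x)
}
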