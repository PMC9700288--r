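#' Pipeline configuration
#'
#' Every numeric threshold of the discovery and placement pipelines in one
#' place.  Defaults: fragments must be strictly longer than 300 bp, reads
#' below mean Q10 are dropped, three align-and-subtract rounds, contaminant
#' confidence strictly above 0.05, redundancy clustering at coverage
#' strictly above 0.8, anchor identity at least 0.8, removal of fragments
#' at least 80% masked, placement fragments strictly longer than 1000 bp,
#' 100 bp merge distance, and minimum cluster support of 3.
#'
#' @param min_fragment_len,min_mean_q,rounds,conf_threshold,cov_threshold
#'   See description.
#' @param identity_threshold,max_masked_frac,placement_min_len,merge_dist
#'   See description.
#' @param min_support,qc_first See description; `qc_first` runs the quality
#'   filter before the unmapped-read selection instead of after it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_fragment_len = 300,
                            min_mean_q = 10,
                            rounds = c("map-long", "sensitive", "map-long"),
                            conf_threshold = 0.05,
                            cov_threshold = 0.8,
                            identity_threshold = 0.8,
                            max_masked_frac = 0.8,
                            placement_min_len = 1000,
                            merge_dist = 100,
                            min_support = 3,
                            qc_first = FALSE) {
  structure(list(
    min_fragment_len = min_fragment_len, min_mean_q = min_mean_q,
    rounds = rounds, conf_threshold = conf_threshold,
    cov_threshold = cov_threshold, identity_threshold = identity_threshold,
    max_masked_frac = max_masked_frac, placement_min_len = placement_min_len,
    merge_dist = merge_dist, min_support = min_support, qc_first = qc_first
  ), class = "pipeline_config")
}

stage_row <- function(stage, n_in, n_out, unit) {
  tibble(stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
         dropped = as.integer(n_in - n_out), unit = unit)
}

#' Discover novel sequences from long reads
#'
#' Runs the full assembly-free discovery flow: select reads carrying
#' unmapped fragments longer than the minimum, quality-filter and
#' adapter-trim them, refine the fragments through the align-and-subtract
#' rounds, remove contaminants, collapse redundant fragments into coverage
#' clusters keeping the longest representative, and drop representatives
#' dominated by low-complexity or simple-repeat sequence.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `qualities`).
#' @param reference Reference tibble (or a pre-built [seq_index()]).
#' @param config A [pipeline_config()].
#' @param classifier Either NULL (skip contaminant screening), a call
#'   tibble keyed by fragment id, or a function `fragments -> calls`.
#' @param tax Taxonomy for contaminant screening (default
#'   [default_taxonomy()]).
#' @param adapters Optional adapter set for trimming (tibble or character).
#' @param sample_id Label carried into the result.
#' @return A `novel_result` object: `novel` (final representative tibble),
#'   `clusters`, `fragments`, `stages` (per-stage counters), `qc`,
#'   `contam`, `mask` and the config.
#' @export
discover_novel <- function(reads, reference, config = pipeline_config(),
                           classifier = NULL, tax = default_taxonomy(),
                           adapters = NULL, sample_id = "sample") {
  reads <- as_tibble(reads)
  ref_index <- if (inherits(reference, "seq_index")) reference
               else seq_index(reference)
  stages <- list()
  qc_report <- NULL

  qc_pass <- function(r) {
    fq <- filter_by_quality(r, min_q = config$min_mean_q)
    qc_report <<- fq$report
    kept <- fq$reads
    n_trim <- 0L
    if (!is.null(adapters)) {
      tr <- trim_adapters(kept, adapters)
      kept <- tr$reads
      n_trim <- tr$n_trimmed
    }
    stages[[length(stages) + 1L]] <<-
      stage_row("quality_filter", nrow(r), nrow(kept), "reads")
    kept
  }

  work <- reads
  if (config$qc_first) work <- qc_pass(work)

  # step 1: reads carrying an unmapped fragment longer than the minimum
  aln <- minialign(work, ref_index, preset = "map-long")
  by_read <- split(aln, aln$query_id)
  has_gap <- vapply(seq_len(nrow(work)), function(i) {
    a <- by_read[[work$read_id[i]]]
    covered <- if (is.null(a)) empty_intervals() else aligned_query_intervals(a)
    gaps <- interval_complement(covered, nchar(work$sequence[i]))
    any(gaps$end - gaps$start > config$min_fragment_len)
  }, logical(1))
  selected <- work[has_gap, , drop = FALSE]
  stages[[length(stages) + 1L]] <-
    stage_row("select_unmapped", nrow(work), nrow(selected), "reads")

  if (!config$qc_first) selected <- qc_pass(selected)

  # step 2: align-and-subtract rounds
  frags <- fragments_from_reads(selected)
  rr <- run_rounds(frags, ref_index, rounds = config$rounds,
                   min_len = config$min_fragment_len)
  frags <- rr$fragments
  stages[[length(stages) + 1L]] <-
    stage_row("align_subtract_rounds", nrow(selected), nrow(frags),
              "reads->fragments")

  # step 3a: contaminant screening
  contam_report <- tibble(fragment_id = character(), taxid = integer(),
                          confidence = double())
  if (!is.null(classifier) && nrow(frags) > 0) {
    calls <- if (is.function(classifier)) classifier(frags) else classifier
    fc <- filter_contaminants(frags, calls, tax,
                              conf_threshold = config$conf_threshold)
    contam_report <- fc$removed
    stages[[length(stages) + 1L]] <-
      stage_row("decontaminate", nrow(frags), nrow(fc$kept), "fragments")
    frags <- fc$kept
  } else {
    stages[[length(stages) + 1L]] <-
      stage_row("decontaminate", nrow(frags), nrow(frags), "fragments")
  }

  # step 3b: redundancy clustering, longest member representative
  if (nrow(frags) >= 2) {
    ava <- minialign_ava(frags)
    clusters <- build_clusters(frags, ava, cov_threshold = config$cov_threshold)
  } else {
    clusters <- build_clusters(frags, empty_paf())
  }
  reps <- if (nrow(clusters) > 0) cluster_representatives(clusters, frags)
          else tibble(seq_id = character(), sequence = character(),
                      cluster_id = character(), n_members = integer())
  stages[[length(stages) + 1L]] <-
    stage_row("cluster_dedup", nrow(frags), nrow(reps), "fragments->clusters")

  # step 3c: repeat-content filter on the representatives
  rf <- repeat_filter(reps, max_masked_frac = config$max_masked_frac)
  novel <- rf$kept
  stages[[length(stages) + 1L]] <-
    stage_row("repeat_filter", nrow(reps), nrow(novel), "representatives")

  structure(list(
    sample_id = sample_id,
    novel = as_tibble(novel),
    clusters = clusters,
    fragments = frags,
    stages = dplyr::bind_rows(stages),
    rounds = rr$rounds,
    qc = qc_report,
    contam = contam_report,
    mask = rf$annotation,
    config = config
  ), class = "novel_result")
}

#' Label final sequences as common or individual-specific across samples
#'
#' A sequence is common when it aligns to any other sample's sequence at
#' identity >= `identity_threshold`; the relation is symmetric (a hit marks
#' both sequences common).  Everything else is individual-specific.
#'
#' @param novel_sets Named list (sample id -> final sequence tibble with
#'   `seq_id`, `sequence`), at least 2 samples.
#' @param identity_threshold Inclusive identity floor (default 0.8).
#' @return Tibble with `sample_id`, `seq_id`, `length`, `label`
#'   (`"common"` / `"individual-specific"`).
#' @export
classify_common_specific <- function(novel_sets, identity_threshold = 0.8) {
  if (length(novel_sets) < 2) abort("need final sets from at least 2 samples")
  if (is.null(names(novel_sets))) abort("novel_sets must be named by sample")
  combined <- dplyr::bind_rows(lapply(names(novel_sets), function(sid) {
    s <- as_seq_tbl(novel_sets[[sid]])
    dplyr::mutate(s, sample_id = sid,
                  uid = paste0(sid, "__", .data$seq_id))
  }))
  combined$label <- "individual-specific"
  if (nrow(combined) >= 2) {
    seqs <- tibble(seq_id = combined$uid, sequence = combined$sequence)
    aln <- minialign(seqs, seq_index(seqs), preset = "ava")
    smp <- setNames(combined$sample_id, combined$uid)
    hits <- aln[smp[aln$query_id] != smp[aln$target_id] &
                aln$identity >= identity_threshold, , drop = FALSE]
    common_uid <- unique(c(hits$query_id, hits$target_id))
    combined$label[combined$uid %in% common_uid] <- "common"
  }
  tibble(sample_id = combined$sample_id, seq_id = combined$seq_id,
         length = nchar(combined$sequence), label = combined$label)
}

#' Compare recovered sequences with a simulation truth table
#'
#' Aligns every planted insertion against the final representatives of the
#' samples that carry it; an insertion is recovered when some
#' representative matches at identity >= `min_identity` covering at least
#' `min_coverage` of the insertion.
#'
#' @param results Named list of `novel_result` (name = sample id) or a
#'   single result.
#' @param sim The `novel_sim` the reads came from.
#' @param min_identity Identity floor for recovery (default 0.9).
#' @param min_coverage Minimum fraction of the insertion aligned
#'   (default 0.5).
#' @return List with `per_insertion` (tibble: `insertion_id`, `length`,
#'   `category`, `recovered`, `best_identity`), `recovery` (fraction),
#'   `n_contaminant_reps` (final representatives traced to contaminant
#'   reads).
#' @export
evaluate_recovery <- function(results, sim, min_identity = 0.9,
                              min_coverage = 0.5) {
  if (inherits(results, "novel_result")) {
    results <- setNames(list(results), results$sample_id)
  }
  src <- setNames(sim$provenance$source, sim$provenance$read_id)
  n_contam <- 0L
  rep_index <- list()
  for (sid in names(results)) {
    reps <- results[[sid]]$novel
    if (nrow(reps) > 0) {
      read_of <- sub(":.*$", "", reps$seq_id)
      n_contam <- n_contam + sum(src[read_of] == "contaminant", na.rm = TRUE)
      rep_index[[sid]] <- seq_index(
        tibble(seq_id = paste0(sid, "__", reps$seq_id),
               sequence = reps$sequence))
    }
  }
  carried <- vapply(sim$truth$samples, function(s) {
    length(intersect(s, names(results))) > 0
  }, logical(1))
  rows <- lapply(which(carried), function(i) {
    tr <- sim$truth[i, ]
    best_id <- 0
    recovered <- FALSE
    for (sid in intersect(tr$samples[[1]], names(rep_index))) {
      aln <- minialign(tibble(seq_id = tr$insertion_id,
                              sequence = tr$sequence),
                       rep_index[[sid]], preset = "map-long")
      if (nrow(aln) == 0) next
      per_target <- split(aln, aln$target_id)
      for (a in per_target) {
        cov <- interval_covered(tibble(start = a$q_start, end = a$q_end)) /
          tr$length
        idv <- max(a$identity)
        if (cov >= min_coverage) {
          best_id <- max(best_id, idv)
          if (idv >= min_identity) recovered <- TRUE
        }
      }
    }
    tibble(insertion_id = tr$insertion_id, length = tr$length,
           category = tr$category, recovered = recovered,
           best_identity = best_id)
  })
  per_insertion <- dplyr::bind_rows(rows)
  list(per_insertion = per_insertion,
       recovery = mean(per_insertion$recovered),
       n_contaminant_reps = n_contam)
}

#' Compare placement clusters with a simulation truth table
#'
#' @param placements Named list of `novel_placements` (name = sample id).
#' @param sim The `novel_sim` the reads came from.
#' @param max_dist Breakpoint tolerance in bp (default 100).
#' @return List with `bep_clusters` (tibble of surviving BEP clusters and
#'   their nearest planted locus distance), `bep_within_tol` (fraction),
#'   `per_insertion` (tibble of placeable insertions -- longer than 1 kb and
#'   spanned by at least `min_support` reads -- with a `placed` flag) and
#'   `placement_recovery` (fraction placed).
#' @export
evaluate_placements <- function(placements, sim, max_dist = 100) {
  truth <- sim$truth
  loci <- truth$ref_pos
  min_support <- placements[[1]]$min_support
  clu <- dplyr::bind_rows(lapply(names(placements), function(sid) {
    dplyr::mutate(placements[[sid]]$clusters, sample_id = sid)
  }))
  bep <- clu[clu$kind == "BEP", , drop = FALSE]
  if (nrow(bep) > 0) {
    bep$nearest_locus_dist <- vapply(seq_len(nrow(bep)), function(i) {
      min(bp_distance(bep$bp_start[i], bep$bp_end[i], loci, loci))
    }, double(1))
  } else {
    bep$nearest_locus_dist <- double()
  }
  # spanning support per (sample, insertion) from provenance
  span_counts <- list()
  pv <- sim$provenance[sim$provenance$source == "host", ]
  for (i in seq_len(nrow(pv))) {
    for (ins in pv$spans[[i]]) {
      key <- paste0(pv$sample_id[i], "::", ins)
      span_counts[[key]] <- (span_counts[[key]] %||% 0L) + 1L
    }
  }
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    if (truth$length[i] <= 1000) next
    for (sid in truth$samples[[i]]) {
      n_span <- span_counts[[paste0(sid, "::", truth$insertion_id[i])]] %||% 0L
      if (n_span < min_support) next
      sclu <- clu[clu$sample_id == sid, , drop = FALSE]
      placed <- nrow(sclu) > 0 && any(
        bp_distance(sclu$bp_start, sclu$bp_end,
                    truth$ref_pos[i], truth$ref_pos[i]) <= max_dist)
      rows[[length(rows) + 1L]] <- tibble(
        insertion_id = truth$insertion_id[i], sample_id = sid,
        length = truth$length[i], category = truth$category[i],
        n_spanning = n_span, placed = placed)
    }
  }
  per_insertion <- dplyr::bind_rows(rows)
  list(
    bep_clusters = bep,
    bep_within_tol = if (nrow(bep) > 0) mean(bep$nearest_locus_dist <= max_dist)
                     else NA_real_,
    per_insertion = per_insertion,
    placement_recovery = if (nrow(per_insertion) > 0)
      mean(per_insertion$placed) else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the final outputs of a discovery run
#'
#' `novel.fa` (final representatives), `clusters.tsv` (membership) and
#' `stages.tsv` (per-stage counters).
#'
#' @param result A `novel_result`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_novel_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(result$novel, file.path(outdir, "novel.fa"))
  members <- tidyr::unnest(
    dplyr::select(result$clusters, "cluster_id", "representative_id",
                  "member_ids"),
    "member_ids")
  utils::write.table(members, file.path(outdir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$stages, file.path(outdir, "stages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Write placement clusters as BED5 and FASTA
#'
#' BED name field is `cluster_id|kind`; score is the support count.
#'
#' @param placements A `novel_placements`.
#' @param bed_path,fasta_path Output paths (NULL to skip).
#' @return Invisibly, the cluster tibble written.
#' @export
write_placements <- function(placements, bed_path = NULL, fasta_path = NULL) {
  clu <- placements$clusters
  if (!is.null(bed_path)) {
    write_bed(tibble(target_id = clu$target_id, start = clu$bp_start,
                     end = pmax(clu$bp_end, clu$bp_start + 1L),
                     name = paste(clu$cluster_id, clu$kind, sep = "|"),
                     score = clu$support), bed_path)
  }
  if (!is.null(fasta_path)) {
    write_fasta(tibble(seq_id = clu$cluster_id, sequence = clu$sequence),
                fasta_path)
  }
  invisible(clu)
}

#' Compare sharing labels with a simulation truth table
#'
#' Matches labelled placement clusters to planted loci (breakpoint within
#' `max_dist` of the planted reference position) and compares each matched
#' locus's sharing label with the label expected from the insertion's
#' planted category and the population map.
#'
#' @param shared Labelled cluster tibble from [classify_sharing()].
#' @param sim The `novel_sim` the reads came from.
#' @param max_dist Breakpoint tolerance in bp (default 100).
#' @return List with `per_locus` (tibble: `insertion_id`, `expected`,
#'   `observed`, `match`) and `accuracy` (fraction matching).
#' @export
evaluate_sharing <- function(shared, sim, max_dist = 100) {
  truth <- sim$truth
  pops <- sim$config$samples
  expected_label <- vapply(seq_len(nrow(truth)), function(i) {
    smp <- truth$samples[[i]]
    np <- length(unique(pops$population[pops$sample_id %in% smp]))
    if (length(smp) == 1) "individual"
    else if (np >= 2) "population-shared"
    else "population-specific"
  }, character(1))
  rows <- list()
  for (lid in unique(shared$locus_id)) {
    grp <- shared[shared$locus_id == lid, , drop = FALSE]
    d <- bp_distance(min(grp$bp_start), max(grp$bp_end),
                     truth$ref_pos, truth$ref_pos)
    j <- which.min(d)
    if (d[j] > max_dist) next
    rows[[length(rows) + 1L]] <- tibble(
      locus_id = lid, insertion_id = truth$insertion_id[j],
      expected = expected_label[j], observed = grp$label[1],
      match = expected_label[j] == grp$label[1])
  }
  per_locus <- dplyr::bind_rows(rows)
  list(per_locus = per_locus,
       accuracy = if (nrow(per_locus) > 0) mean(per_locus$match) else NA_real_)
}
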