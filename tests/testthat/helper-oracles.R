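# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths (IRanges, igraph, the C++ aligner) so agreement is a real
# cross-check.

# Per-base boolean-array interval arithmetic.
oracle_mark <- function(intervals, len) {
  covered <- logical(len)
  for (i in seq_len(nrow(intervals))) {
    if (intervals$end[i] > intervals$start[i]) {
      covered[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
    }
  }
  covered
}

bool_to_intervals <- function(covered) {
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

oracle_merge <- function(intervals, len) {
  bool_to_intervals(oracle_mark(intervals, len))
}

oracle_complement <- function(intervals, len) {
  bool_to_intervals(!oracle_mark(intervals, len))
}

oracle_covered_len <- function(intervals, len) sum(oracle_mark(intervals, len))

# Reachability closure by repeated boolean matrix multiplication.
oracle_components <- function(ids, edges) {
  n <- length(ids)
  m <- diag(1, n)
  if (nrow(edges) > 0) {
    i <- match(edges[[1]], ids)
    j <- match(edges[[2]], ids)
    m[cbind(i, j)] <- 1
    m[cbind(j, i)] <- 1
  }
  repeat {
    m2 <- sign(m %*% m)
    if (identical(m2, m)) break
    m <- m2
  }
  # canonical partition label: smallest member index
  apply(m > 0, 1, function(row) min(which(row)))
}

# Brute-force single linkage of points with pairwise distance <= maxd:
# repeatedly merge any two groups containing a close pair.
oracle_single_linkage <- function(pos, maxd) {
  n <- length(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (grp[i] != grp[j] && abs(pos[i] - pos[j]) <= maxd) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  grp
}

# Naive window-rescan DUST oracle: recount triplets from scratch for every
# window position.
oracle_dust <- function(sequence, window = 64, score_threshold = 20) {
  n <- nchar(sequence)
  if (n < 3) return(tibble::tibble(start = integer(), end = integer()))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  code <- match(ch, c("A", "C", "G", "T")) - 1L
  tc <- code[1:(n - 2)] * 16L + code[2:(n - 1)] * 4L + code[3:n]
  masked <- logical(n)
  # segments of consecutive valid triplets
  valid <- !is.na(tc)
  seg_id <- cumsum(c(TRUE, diff(valid) != 0))
  for (sid in unique(seg_id[valid])) {
    tri <- which(seg_id == sid & valid)
    seg_len <- length(tri) + 2L
    w <- min(window, seg_len)
    if (w < 4) next
    wt <- w - 2L
    for (s in seq_len(length(tri) - wt + 1L)) {
      counts <- tabulate(tc[tri[s:(s + wt - 1L)]] + 1L, nbins = 64L)
      score <- 10 * sum(counts * (counts - 1) / 2) / (w - 3)
      if (score > score_threshold) {
        b0 <- tri[s]  # 1-based first base of window
        masked[b0:min(b0 + w - 1L, n)] <- TRUE
      }
    }
  }
  bool_to_intervals(masked)
}

# Full dynamic-programming identity via Biostrings (global alignment).
nw_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 1, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / cols
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Mutate a sequence at the given per-base rates.
mutate_dna <- function(s, sub = 0, ins = 0, del = 0) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  u <- runif(n)
  is_sub <- u < sub
  is_del <- u >= sub & u < sub + del
  is_ins <- u >= sub + del & u < sub + del + ins
  if (any(is_sub)) {
    codes <- match(ch[is_sub], c("A", "C", "G", "T")) - 1L
    ch[is_sub] <- c("A", "C", "G", "T")[(codes + sample(1:3, sum(is_sub),
                                                        TRUE)) %% 4L + 1L]
  }
  reps <- ifelse(is_del, 0L, ifelse(is_ins, 2L, 1L))
  idx <- rep(seq_len(n), reps)
  out <- ch[idx]
  dup <- c(FALSE, idx[-1] == idx[-length(idx)])
  if (any(dup)) out[dup] <- sample(c("A", "C", "G", "T"), sum(dup), TRUE)
  paste(out, collapse = "")
}
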