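---
title: "Assembly-free discovery and placement of non-reference sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-free discovery and placement of non-reference sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novelseq)
```

## The problem and the approach

A reference genome is a consensus over few individuals; any given genome
contains stretches of DNA — mostly insertions of a few hundred bases to a
few kilobases — that the reference simply lacks.  Short reads are poor raw
material for recovering them: a 150-bp read never spans a 2-kb insertion,
so short-read pipelines must assemble first and inherit every assembler
artefact.  A long read, by contrast, can contain an entire inserted
sequence together with flanking sequence that anchors it to the reference.

`novelseq` therefore works read-by-read, with no assembly step.  Its
discovery pipeline has three stages:

1. **Candidate selection and QC.**  Reads are aligned to the reference and
   kept when some maximal unaligned read interval is strictly longer than
   300 bp — the operational definition of a novel-sequence candidate.
   Kept reads must have probability-space mean quality of at least Q10:
   the per-read quality is $-10\log_{10}\bar p_e$ with
   $\bar p_e = \tfrac1n\sum_i 10^{-Q_i/10}$, the convention of standard
   nanopore QC tools (the arithmetic mean of Phred scores would flatter
   bad reads).  End adapters are then trimmed by semi-global alignment of
   each adapter (and its reverse complement) against 150-bp end windows,
   cutting at the adapter's inner boundary (identity ≥ 0.75 over ≥ 10
   adapter bases, repeated to exhaustion).  The selection step runs before
   QC by default; `pipeline_config(qc_first = TRUE)` swaps the order.

2. **Iterated align-and-subtract.**  Each candidate read seeds one
   full-length fragment; three rounds of alignment against the reference
   (presets `map-long`, `sensitive`, `map-long`; the sensitive preset uses
   a minimum chain span of 31 with 15-mer seeds) remove *every* aligned
   query interval, and surviving complement pieces of ≤ 300 bp are
   discarded.  Two readings of the removal rule are possible — we remove
   aligned portions unconditionally and additionally drop short survivors,
   which is the reading consistent with the pipeline's purpose of keeping
   only confidently-unaligned sequence.  No identity floor is applied
   within the rounds: the aligner presets already bound spurious hits, and
   a reported alignment is evidence of reference homology either way.
   Total surviving bases are non-increasing over rounds by construction.

3. **Screening, redundancy collapse, repeat filter.**  Fragments carrying
   a Kraken2-style classification into archaea, bacteria, fungi or viral
   clades — or labelled as plasmid/UniVec library sequence — are removed
   when the classification confidence strictly exceeds 0.05.  Confidence
   is *recomputed* from the per-fragment LCA k-mer string
   ($C/Q$: clade k-mers over counted k-mers, ambiguous entries excluded,
   taxid-0 k-mers in the denominator only) so the rule is enforceable on
   output produced with any upstream `--confidence` setting; unclassified
   fragments are kept, since they can never exceed a confidence threshold.
   Remaining fragments are all-vs-all aligned; two fragments connect when
   the merged alignment blocks cover strictly more than 80% of the
   *shorter* fragment, and clusters are the connected components of that
   graph.  Coverage of the shorter sequence (rather than reciprocal
   coverage) is the reading compatible with keeping the *longest* member
   as the cluster representative — reciprocal coverage would forbid
   clusters of unequal length; a `reciprocal = TRUE` switch implements the
   other reading.  Finally, representatives that are at least 80% covered
   by low-complexity or simple-tandem-repeat sequence are dropped: raw
   long reads are least accurate exactly in such regions, so
   repeat-dominated survivors are more likely error artefacts than novel
   sequence.  We treat the 80% boundary as inclusive (conservative
   removal); it is configurable.

## Placement calling

To position novel sequences on the reference, reads are aligned and
filtered to anchors with identity ≥ 0.8 (inclusive).  A read is used when
exactly one anchor remains, or exactly two *consistent* anchors: same
target and strand, collinear in the strand-appropriate order, and
non-overlapping on read and reference up to a 100-bp micro-homology slack.
The slack is deliberate: insertion junctions frequently share a few bases
with the reference on either side, and alignment end-extension can step a
few bases across a junction, so the two flanking alignments of a genuine
insertion routinely overlap by a handful of base pairs.  Requiring exact
disjointness would discard most true split reads (in our simulations,
roughly four of five).

Unmapped read intervals strictly longer than 1,000 bp then become calls:
between two anchors, a **BEP** whose breakpoint interval spans the facing
anchor boundaries (zero-width when they abut; reduced to the midpoint when
they overlap); outside a single anchor at a read end, a **SEP** with a
zero-width breakpoint at the anchor's facing boundary.  SEPs merge by
single linkage when breakpoints are within 100 bp (inclusive).  BEPs merge
when breakpoints are within 100 bp *and* the fragments overlap
near-full-length — the merged aligned length on the shorter fragment must
be within 100 bp of that fragment's length.  The overlap condition is the
only reading we found that uses both the overlap and the length; a
`proximity_only` switch disables it.  Clusters with fewer than three
supporting fragments are discarded.  SEP and BEP clusters are never merged
with each other.

Across samples, clusters match when breakpoints are within 100 bp and the
representatives align at identity ≥ 0.8; matched loci are labelled
`individual` (one sample), `population-specific` (≥ 2 samples, one
population) or `population-shared` (≥ 2 populations).  The same ≥ 0.8
identity rule, applied to the final sequence sets directly, yields the
`common` vs `individual-specific` sequence labels of
`classify_common_specific()`.

## The built-in aligner

All alignment runs through a self-contained seed-and-extend aligner
(`seq_index()`, `minialign()`, Rcpp): exact canonical 15-mer seeds (no
minimizer subsampling — desk-scale references make full indexing cheap and
keep results fully deterministic), per-(target, strand) collinear chaining
with seed gaps ≤ 500 bp (≤ 200 for the sensitive preset) and per-step
diagonal drift ≤ 64, banded global DP between consecutive seed runs, and
banded semi-global extension at the chain ends.  Match counts come from
the actual DP path, so `identity = n_matches / block_len` is an alignment
identity, not a seed statistic.  K-mers occurring more than 64 times in
the index (128 for sensitive) are skipped, which keeps simple-repeat
stretches from flooding the chainer; chains cross such stretches through
the DP gap fill instead.  Chains are extracted per (target, strand) group
independently, so all-vs-all queries report every overlapping partner
rather than only the best one.  Ties in chaining are broken toward the
leftmost query start; all tie-breaks are fixed, and repeated runs are
bit-identical.  The aligner does not aim to reproduce any external
aligner's output; production runs can substitute external PAF at every
stage.

## The simulator, and what passing tests mean

`simulate_dataset()` emulates the study design the pipeline targets: a
uniform-random reference (default 100 kb) with ~5% planted short tandem
stretches; 20 insertions of 500–3,000 bp of uniform-random sequence
planted ≥ 5 kb apart at recorded loci, split 50/50 between shared-by-all
and individual-specific (a population-specific fraction is available);
two samples from two populations; reads with log-normal lengths (mean
≈ 10 kb, truncated at 1 kb — ONT-like), uniform starts, both strands,
~30× depth, and substitution/insertion/deletion errors at 4%/2%/2% (8%
total, typical of recent nanopore chemistry); per-base qualities drawn
around the Phred equivalent of each read's realized error (±2 jitter), so
the Q10 filter is meaningfully exercisable, with a `bad_read_frac` mode
emitting ~Q8 reads that must be dropped; and 5% of reads drawn from a
separate 30-kb contaminant genome, recorded in the provenance table and
classified as E. coli by the bundled truth classifier.  All streams derive
from one seed; identical configs give byte-identical outputs.

Insertions are random sequence, deliberately *not* low-complexity, so the
repeat filter cannot remove true positives — poly-A decoys are planted
separately in tests to exercise the 80% mask rule.  The simulator does not
model homopolymer-biased ONT error profiles, pore signal, haplotypes or
structural rearrangements other than insertions; passing tests therefore
demonstrate the pipeline's logic and thresholds under idealised noise, not
performance on real flow-cell data, where error structure and repeat
content are harsher.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere (PAF/BED native); FASTQ
  qualities are Phred+33 only.
* All strict/inclusive boundaries follow their stated rules exactly:
  fragment length > 300, confidence > 0.05, coverage > 0.8, masked
  fraction ≥ 0.8, anchor identity ≥ 0.8, placement fragment > 1,000,
  SEP distance ≤ 100, support ≥ 3.
* Representative ties (equal lengths) break to the lexicographically
  smallest fragment id; placement representative ties to the smallest
  read id; cluster ids order by representative length, so output is
  independent of input order.
* Low-complexity masking scores triplet composition
  $10\sum_t c_t(c_t-1)/2 \,/\, (L-3)$ in sliding 64-bp windows (threshold
  20); any window above threshold is masked and overlapping windows merge.
  `N` breaks windows and is never masked by itself.  Tandem masking scans
  unit sizes 1–6 with greedy extension at ≤ 10% cumulative mismatch and a
  20-bp minimum span.
* Empty inputs flow through: empty FASTA/call/alignment sets are identity
  cases, not errors; a read trimmed to nothing is dropped and counted.
* Simulation sizes in the test-suite follow the package's default study
  conditions (100-kb reference, two samples at 30×) with smaller
  configurations for targeted unit checks.

## Known limitations

* Fragments are raw read sub-sequences; no consensus polishing or error
  correction is applied (deliberately — correction at modest depth loses
  novel sequence), so representative identity is bounded by read accuracy.
* Middle-of-read adapters are not split; adapter search is end-anchored.
* The contaminant screen is only as good as the supplied classification;
  the package consumes Kraken2-style output and does not classify.
* Placement assumes simple insertions relative to the reference;
  inversions, translocations and nested events are out of scope.
* Reads spanning two nearby insertions produce three or more anchors and
  are rejected by the one-or-two-anchor rule; placement support for
  closely spaced insertions is correspondingly reduced.
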