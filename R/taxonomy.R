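#' Build a taxonomy for contaminant screening
#'
#' Holds the child-to-parent map used to walk ancestor chains, the clade
#' roots treated as contaminants (archaea, bacteria, fungi, viral by
#' default), and optional sequence-library labels (plasmid / UniVec), which
#' are libraries rather than taxa and are matched by sequence id.
#'
#' @param nodes Tibble with columns `child`, `parent` (integer taxids) and
#'   optionally `rank`.
#' @param roots Named integer vector of contaminant clade roots.
#' @param labels Optional tibble with columns `seq_id`, `library`
#'   (`"plasmid"` or `"UniVec"`).
#' @return A `novel_taxonomy` object.
#' @export
taxonomy <- function(nodes,
                     roots = c(archaea = 2157L, bacteria = 2L,
                               fungi = 4751L, viral = 10239L),
                     labels = NULL) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("child", "parent") %in% names(nodes)))
  if (length(roots) == 0) abort("taxonomy requires at least one clade root")
  parent <- setNames(as.integer(nodes$parent), as.character(nodes$child))
  structure(
    list(parent = parent, roots = roots,
         labels = if (!is.null(labels)) as_tibble(labels) else NULL),
    class = "novel_taxonomy"
  )
}

#' Read an NCBI-style taxonomy nodes table
#'
#' Accepts either the `nodes.dmp` dialect (fields separated by `\t|\t`) or a
#' plain 3-column TSV of `child`, `parent`, `rank`.
#'
#' @param path Path to the nodes table.
#' @inheritParams taxonomy
#' @return A `novel_taxonomy` object.
#' @export
read_taxonomy_nodes <- function(path,
                                roots = c(archaea = 2157L, bacteria = 2L,
                                          fungi = 4751L, viral = 10239L),
                                labels = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sep <- if (any(grepl("|", lines, fixed = TRUE))) "\\s*\\|\\s*" else "\t"
  fields <- strsplit(lines, sep)
  if (any(lengths(fields) < 2)) {
    abort(sprintf("taxonomy parse error: line %d has fewer than 2 fields",
                  which(lengths(fields) < 2)[1]))
  }
  nodes <- tibble(
    child = as.integer(vapply(fields, `[`, character(1), 1)),
    parent = as.integer(vapply(fields, `[`, character(1), 2)),
    rank = vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_,
                  character(1))
  )
  taxonomy(nodes, roots = roots, labels = labels)
}

# Ancestors of a taxid including itself, walking to the root (taxid 1).
# Unknown taxids raise an error naming the taxid; 0 has no ancestors.
tax_ancestors <- function(tax, taxid) {
  if (taxid == 0L) return(integer())
  chain <- integer()
  cur <- taxid
  repeat {
    chain <- c(chain, cur)
    if (cur == 1L) break
    p <- unname(tax$parent[match(as.character(cur), names(tax$parent))])
    if (is.na(p)) abort(sprintf("unknown taxid in taxonomy: %d", cur))
    if (p == cur) break
    cur <- p
  }
  chain
}

# TRUE if `taxid` lies within the clade rooted at `root`.
tax_in_clade <- function(tax, taxid, root) {
  if (taxid == 0L) return(FALSE)
  root %in% tax_ancestors(tax, taxid)
}

#' A small built-in taxonomy for screening simulated data
#'
#' Covers the contaminant clade roots (archaea, bacteria, fungi, viral), an
#' E. coli lineage used by the simulator's contaminant calls, and a human
#' lineage.  Synthetic: a stand-in for the NCBI taxonomy at desk scale.
#'
#' @inheritParams taxonomy
#' @return A `novel_taxonomy` object.
#' @export
default_taxonomy <- function(labels = NULL) {
  nodes <- tibble(
    child  = c(1L, 131567L, 2L, 2157L, 2759L, 4751L, 33208L, 9606L,
               10239L, 543L, 561L, 562L, 33154L),
    parent = c(1L, 1L, 131567L, 131567L, 131567L, 33154L, 2759L, 33208L,
               1L, 2L, 543L, 561L, 2759L),
    rank   = c("no rank", "no rank", "superkingdom", "superkingdom",
               "superkingdom", "kingdom", "kingdom", "species",
               "superkingdom", "family", "genus", "species", "clade")
  )
  taxonomy(nodes, labels = labels)
}

#' @export
print.novel_taxonomy <- function(x, ...) {
  cat(sprintf("<novel_taxonomy> %d nodes; contaminant roots: %s\n",
              length(x$parent),
              paste(sprintf("%s(%d)", names(x$roots), x$roots), collapse = ", ")))
  if (!is.null(x$labels)) {
    cat(sprintf("  %d library labels\n", nrow(x$labels)))
  }
  invisible(x)
}
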