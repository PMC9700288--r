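#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.novel_result <- function(x, ...) {
  cat(sprintf("<novel_result> sample %s\n", x$sample_id))
  print(x$stages, n = nrow(x$stages))
  cat(sprintf("final: %d novel sequence(s), %.0f bp\n",
              nrow(x$novel), sum(nchar(x$novel$sequence))))
  invisible(x)
}

#' Tidy per-stage counters of a discovery run
#'
#' @param x A `novel_result`.
#' @param ... Unused.
#' @return Tibble of stage, counts in/out and dropped.
#' @export
tidy.novel_result <- function(x, ...) x$stages

#' One-row summary of a discovery run
#'
#' @param x A `novel_result`.
#' @param ... Unused.
#' @return One-row tibble: read/fragment/cluster counts and final bases.
#' @export
glance.novel_result <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_reads_in = x$stages$n_in[x$stages$stage == "select_unmapped"][1],
    n_reads_selected = x$stages$n_out[x$stages$stage == "select_unmapped"][1],
    n_fragments = nrow(x$fragments),
    n_clusters = nrow(x$clusters),
    n_novel = nrow(x$novel),
    novel_bp = sum(nchar(x$novel$sequence))
  )
}

#' Funnel plot of the discovery stages
#'
#' @param object A `novel_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.novel_result <- function(object, ...) {
  d <- object$stages
  d$stage <- factor(d$stage, levels = rev(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_out, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), hjust = -0.1,
                       size = 3) +
    ggplot2::labs(x = "items surviving stage", y = NULL,
                  title = sprintf("Discovery funnel (%s)", object$sample_id)) +
    ggplot2::theme_minimal()
}

#' @export
print.novel_placements <- function(x, ...) {
  cat(sprintf(
    "<novel_placements> sample %s: %d call(s), %d cluster(s) (%d with support >= %d)\n",
    x$sample_id, nrow(x$calls), nrow(x$all_clusters), nrow(x$clusters),
    x$min_support))
  invisible(x)
}

#' Tidy placement clusters
#'
#' @param x A `novel_placements`.
#' @param ... Unused.
#' @return Tibble of surviving clusters.
#' @export
tidy.novel_placements <- function(x, ...) x$clusters

#' One-row summary of a placement run
#'
#' @param x A `novel_placements`.
#' @param ... Unused.
#' @return One-row tibble of call and cluster counts by kind.
#' @export
glance.novel_placements <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_calls = nrow(x$calls),
    n_bep_calls = sum(x$calls$kind == "BEP"),
    n_sep_calls = sum(x$calls$kind == "SEP"),
    n_clusters = nrow(x$clusters),
    n_bep_clusters = sum(x$clusters$kind == "BEP"),
    n_sep_clusters = sum(x$clusters$kind == "SEP")
  )
}

#' Breakpoint map of placement clusters
#'
#' Supported clusters along the reference, coloured by kind, sized by
#' support.
#'
#' @param object A `novel_placements`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.novel_placements <- function(object, ...) {
  d <- object$clusters
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bp_start, y = .data$support,
                                  colour = .data$kind)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$representative_len),
                        alpha = 0.7) +
    ggplot2::facet_wrap(~target_id, ncol = 1) +
    ggplot2::labs(x = "reference position (bp)", y = "supporting fragments",
                  title = sprintf("Novel placements (%s)", object$sample_id)) +
    ggplot2::theme_minimal()
}
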