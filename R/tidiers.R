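#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-term statistics of an enrichment fit
#'
#' @param x a `ddi_enrichment`.
#' @param ... unused.
#' @return a tibble with one row per tested term: `term`, `frequency`,
#'   `null_mean`, `null_sd`, `z`, `p_raw`, `p_adjusted`, `significant`.
#' @export
tidy.ddi_enrichment <- function(x, ...) {
  tibble::as_tibble(x$stats)
}

#' One-row summary of an enrichment fit
#'
#' @param x a `ddi_enrichment`.
#' @param ... unused.
#' @return a one-row tibble: drug, group sizes, sample size per iteration,
#'   candidate/tested/significant counts, sampling iterations and seed.
#' @export
glance.ddi_enrichment <- function(x, ...) {
  tibble::tibble(
    drug = x$drug,
    n_group_a = x$n_group_a,
    n_group_b = x$n_group_b,
    sample_size = x$sample_size,
    n_candidates = x$n_candidates,
    n_tested = x$n_tested,
    n_significant = nrow(x$significant),
    sample_times = x$params$sample_times,
    cutoff = x$params$cutoff,
    alpha = x$params$alpha,
    seed = x$params$seed
  )
}

#' Plot an enrichment fit
#'
#' Frequency against evidence strength (-log10 adjusted p, with exact zeros
#' drawn at the top of the scale), coloured by significance.
#'
#' @param object a `ddi_enrichment`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ddi_enrichment <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No tested terms"))
  }
  pos <- df$p_adjusted[df$p_adjusted > 0]
  cap <- if (length(pos) > 0) -log10(min(pos)) + 1 else 1
  df$neg_log10_padj <- ifelse(df$p_adjusted > 0, -log10(df$p_adjusted), cap)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$frequency, y = .data$neg_log10_padj, colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Group A co-occurrence frequency",
      y = expression(-log[10] ~ "adjusted p"),
      colour = "significant",
      title = sprintf("DDI term enrichment: %s", object$drug)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a term co-occurrence network
#'
#' Convenience rendering with a Fruchterman-Reingold layout; edge width is
#' proportional to the shared-record count.
#'
#' @param object a `term_network`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.term_network <- function(object, seed = 42, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "Empty network"))
  }
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(
    term = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]
  )
  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0) {
    seg <- dplyr::left_join(object$edges, nodes, by = c(term_a = "term")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(nodes, by = c(term_b = "term"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   linewidth = .data$weight),
      colour = "grey70", alpha = 0.7
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 2))
  }
  p +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        colour = "steelblue", size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$term),
                       vjust = -1, size = 3) +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
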