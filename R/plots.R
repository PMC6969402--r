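#' Upset-style plot of strategy combinations
#'
#' Bar chart of the number of transcripts in each realized combination of
#' prioritization strategies, ordered by size, with combinations meeting
#' the minimum-strategy filter highlighted.
#'
#' @param object a `vp_priority` from [prioritize()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.vp_priority <- function(object, ...) {
  df <- object$combinations
  df$n_strategies <- lengths(strsplit(df$combination, "+", fixed = TRUE))
  df$passes <- df$n_strategies >= object$min_strategies
  df$combination <- factor(df$combination,
                           levels = df$combination[order(-df$n)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combination, y = .data$n,
                                   fill = .data$passes)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
      name = paste0(">= ", object$min_strategies, " strategies")) +
    ggplot2::labs(x = "strategy combination", y = "transcripts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dot plot of enrichment results
#'
#' Categories against overlap size, colored by BH-adjusted significance.
#'
#' @param object a `vp_enrichment` from [hypergeom_enrich()].
#' @param top show at most this many categories (by q-value).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.vp_enrichment <- function(object, top = 20, ...) {
  df <- head(as_tibble(tidy(object)), top)
  df$category_id <- factor(df$category_id,
                           levels = rev(df$category_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap, y = .data$category_id,
                                   color = -log10(.data$q_value),
                                   shape = .data$significant)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_viridis_c(name = "-log10(q)") +
    ggplot2::labs(x = "genes in overlap", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-transcript density change between epochs
#'
#' Scatter of the two per-epoch changes in nonsynonymous SNP density, with
#' an optional highlight set (e.g. the prioritized transcripts).
#'
#' @param metrics `vp_metrics` covering the three focal lines.
#' @param panel `vp_panel`.
#' @param highlight character vector of transcript ids to mark.
#' @return a ggplot.
#' @export
plot_density_deltas <- function(metrics, panel, highlight = character(0)) {
  fl <- focal_lines(panel)
  d1 <- density_delta(metrics, fl[1], fl[2])
  d2 <- density_delta(metrics, fl[2], fl[3])
  df <- dplyr::inner_join(d1, d2, by = "transcript_id", suffix = c("1", "2"))
  df$highlight <- df$transcript_id %in% highlight
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta1, y = .data$delta2,
                                   color = .data$highlight)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "#c0392b"),
                                guide = "none") +
    ggplot2::labs(x = "density change 1957 to 1978 (per bp)",
                  y = "density change 1978 to Ross 308 (per bp)") +
    ggplot2::theme_minimal()
}
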