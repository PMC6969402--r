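#' SNP-dense gene set for one line
#'
#' Aggregates transcript metrics to the gene level (nonsynonymous SNP count
#' summed over a gene's transcripts, divided by their summed CDS length) and
#' returns the genes whose density reaches the nearest-rank `q` percentile
#' among genes with at least one nonsynonymous SNP in that line.
#'
#' @param metrics `vp_metrics` tibble.
#' @param line single line id.
#' @param q percentile (default 0.90).
#' @return character vector of gene ids.
#' @export
snp_dense_genes <- function(metrics, line, q = 0.90) {
  m <- metrics[metrics$line_id == line, , drop = FALSE]
  if (nrow(m) == 0) abort(paste0("no metrics for line '", line, "'."))
  g <- m |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_nonsyn = sum(.data$n_nonsyn),
                     cds_length = sum(.data$cds_length), .groups = "drop") |>
    dplyr::mutate(density = .data$n_nonsyn / .data$cds_length) |>
    dplyr::filter(.data$n_nonsyn > 0)
  if (nrow(g) == 0) return(character(0))
  thr <- nearest_rank_percentile(g$density, q)
  sort(g$gene_id[g$density >= thr])
}

#' Hypergeometric over-representation test
#'
#' Tests each gene-set category for over-representation of `query` genes
#' within `universe` using the upper-tail hypergeometric probability
#' P[X >= overlap], followed by Benjamini-Hochberg adjustment across the
#' tested categories. Categories with fewer than `min_category` genes in the
#' universe are dropped before testing. All tested categories are returned
#' (sorted by q then p) with a `significant` flag at `alpha`; nothing is
#' silently filtered by significance.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param universe character vector: the gene universe.
#' @param categories tidy tibble `category_id, gene_id` (as from
#'   [read_gmt()]); genes outside the universe are ignored.
#' @param min_category minimum universe genes per category (default 3).
#' @param alpha significance threshold on the BH-adjusted p (default 0.05).
#' @return a `vp_enrichment` tibble: `category_id, category_size, overlap,
#'   query_size, universe_size, overlap_genes, p_value, q_value, significant`.
#' @export
hypergeom_enrich <- function(query, universe, categories, min_category = 3,
                             alpha = 0.05) {
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe)) {
    abort("`query` must be a subset of `universe`.")
  }
  cats <- categories[categories$gene_id %in% universe, , drop = FALSE] |>
    dplyr::distinct(.data$category_id, .data$gene_id)
  sizes <- cats |> dplyr::count(.data$category_id, name = "category_size")
  keep <- sizes$category_id[sizes$category_size >= min_category]
  cats <- cats[cats$category_id %in% keep, , drop = FALSE]
  N <- length(universe); k <- length(query)
  res <- cats |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(
      category_size = dplyr::n(),
      overlap = sum(.data$gene_id %in% query),
      overlap_genes = paste(sort(.data$gene_id[.data$gene_id %in% query]),
                            collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      query_size = k,
      universe_size = N,
      # upper tail P[X >= overlap], X ~ Hypergeom(N, category_size, k)
      p_value = phyper(.data$overlap - 1, .data$category_size,
                       N - .data$category_size, k, lower.tail = FALSE)
    )
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < alpha
  res <- res[order(res$q_value, res$p_value, res$category_id), ,
             drop = FALSE]
  res <- res[, c("category_id", "category_size", "overlap", "query_size",
                 "universe_size", "overlap_genes", "p_value", "q_value",
                 "significant")]
  class(res) <- c("vp_enrichment", class(res))
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate q-values:
#' `q(i) = min_{j >= i} m * p(j) / j` over the ascending p-values, returned
#' in the input order. Thin validating wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no NA.")
  }
  p.adjust(p, method = "BH")
}
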