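#' Tidy a strategy-combination result
#'
#' Returns the per-transcript membership table: one row per transcript,
#' one logical column per strategy, the number of strategies that selected
#' it, and whether it passed the combination filter.
#'
#' @param x a `vp_priority` object from [prioritize()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.vp_priority <- function(x, ...) {
  out <- x$membership
  out$prioritized <- out$n_strategies >= x$min_strategies
  out
}

#' @rdname tidy.vp_priority
#' @export
glance.vp_priority <- function(x, ...) {
  strat_cols <- setdiff(names(x$membership), c("transcript_id", "n_strategies"))
  sizes <- vapply(strat_cols, function(nm) sum(x$membership[[nm]]), integer(1))
  out <- as_tibble(as.list(setNames(sizes, paste0("n_", strat_cols))))
  out$n_union <- sum(x$membership$n_strategies > 0)
  out$n_prioritized <- length(x$prioritized)
  out$min_strategies <- x$min_strategies
  out
}

#' Tidy an enrichment result
#'
#' The enrichment table is already tidy; `tidy()` strips the class and
#' `glance()` summarises it.
#'
#' @param x a `vp_enrichment` tibble from [hypergeom_enrich()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.vp_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "vp_enrichment")
  as_tibble(out)
}

#' @rdname tidy.vp_enrichment
#' @export
glance.vp_enrichment <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_significant = sum(x$significant),
    min_q = if (nrow(x)) min(x$q_value) else NA_real_,
    universe_size = if (nrow(x)) x$universe_size[1] else NA_integer_,
    query_size = if (nrow(x)) x$query_size[1] else NA_integer_
  )
}

#' Tidy a pipeline run
#'
#' @param x a `vp_run` from [run_pipeline()].
#' @param ... unused.
#' @return `tidy()`: the membership table with a `planted` truth column;
#'   `glance()`: one row of headline counts.
#' @export
tidy.vp_run <- function(x, ...) {
  out <- tidy(x$priority)
  out$planted <- out$transcript_id %in% x$cohort$truth$planted
  out
}

#' @rdname tidy.vp_run
#' @export
glance.vp_run <- function(x, ...) {
  g <- glance(x$priority)
  g$n_variants <- x$report$counts$n_variants
  g$n_alignment_sites <- x$report$counts$n_alignment_sites
  g
}
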