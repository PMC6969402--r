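#' Strategy 1: greatest accumulation of nonsynonymous SNP density
#'
#' Compares the increase in nonsynonymous SNP density over the first epoch
#' (1957 -> 1978) with the increase over the second (1978 -> Ross 308). A
#' transcript is selected iff both changes are strictly positive and at
#' least one of them reaches the 95th nearest-rank percentile of its
#' population. By default the percentile populations are the transcripts
#' passing the both-positive precondition (the eligibility clause precedes
#' the percentile clause); `population = "all"` ranks against the whole
#' catalog instead. The two epochs are ranked separately.
#'
#' @param metrics `vp_metrics` covering the three focal lines.
#' @param panel a `vp_panel` (focal roles define the temporal order).
#' @param q percentile (default 0.95).
#' @param population `"eligible"` (default) or `"all"`.
#' @return sorted character vector of transcript ids.
#' @export
strategy1 <- function(metrics, panel, q = 0.95,
                      population = c("eligible", "all")) {
  population <- match.arg(population)
  fl <- focal_lines(panel)
  d1 <- density_delta(metrics, fl[1], fl[2])
  d2 <- density_delta(metrics, fl[2], fl[3])
  d <- dplyr::inner_join(d1, d2, by = "transcript_id",
                         suffix = c("1", "2"))
  eligible <- d$delta1 > 0 & d$delta2 > 0
  if (!any(eligible)) return(character(0))
  pop1 <- if (population == "eligible") d$delta1[eligible] else d$delta1
  pop2 <- if (population == "eligible") d$delta2[eligible] else d$delta2
  t1 <- nearest_rank_percentile(pop1, q)
  t2 <- nearest_rank_percentile(pop2, q)
  sel <- eligible & (d$delta1 >= t1 | d$delta2 >= t2)
  sort(d$transcript_id[sel])
}

#' Strategy 2: densest burden of line-exclusive variants
#'
#' Scores each transcript by two length-normalized counts of coding SNPs
#' (synonymous + nonsynonymous): variants exclusive to the 1978-and/or-Ross
#' subset (absent from every other line, including 1957), and variants
#' exclusive to Ross 308 alone. A transcript is selected iff either density
#' reaches the 90th nearest-rank percentile of its statistic's population
#' (transcripts with at least one qualifying variant).
#'
#' @param variants `vp_variants` tibble.
#' @param catalog `vp_catalog` tibble.
#' @param panel `vp_panel` (background = every non-focal line).
#' @param q percentile (default 0.90).
#' @param nonsyn_only restrict the qualifying class to nonsynonymous SNPs.
#' @return sorted character vector of transcript ids.
#' @export
strategy2 <- function(variants, catalog, panel, q = 0.90,
                      nonsyn_only = FALSE) {
  fl <- focal_lines(panel)
  classes <- if (nonsyn_only) "nonsynonymous" else c("synonymous", "nonsynonymous")
  coding <- variants[variants$consequence %in% classes &
                       !is.na(variants$transcript_id), , drop = FALSE]
  all_lines <- panel$line_id
  excl_density <- function(targets) {
    bg <- setdiff(all_lines, targets)
    keys <- exclusive_to(variants, targets, bg)
    hit <- coding[variant_key(coding) %in% keys, , drop = FALSE]
    counts <- table(factor(hit$transcript_id, levels = catalog$transcript_id))
    as.integer(counts) / catalog$cds_length
  }
  d_a <- excl_density(fl[2:3])   # exclusive to 1978 and/or Ross
  d_b <- excl_density(fl[3])     # exclusive to Ross only
  sel <- rep(FALSE, nrow(catalog))
  if (any(d_a > 0)) {
    ta <- nearest_rank_percentile(d_a[d_a > 0], q)
    sel <- sel | (d_a > 0 & d_a >= ta)
  }
  if (any(d_b > 0)) {
    tb <- nearest_rank_percentile(d_b[d_b > 0], q)
    sel <- sel | (d_b > 0 & d_b >= tb)
  }
  sort(catalog$transcript_id[sel])
}

#' Strategy 3: high-impact variants restricted to the later lines
#'
#' Selects transcripts carrying a high-impact variant (frameshift,
#' start-loss or stop-gain) whose key occurs in the 1978 or Ross 308 line
#' but not in the 1957 line. The test is per variant key, so a high-impact
#' variant shared by all three lines never fires.
#'
#' @param variants `vp_variants` tibble.
#' @param panel `vp_panel`.
#' @return sorted character vector of transcript ids.
#' @export
strategy3 <- function(variants, panel) {
  fl <- focal_lines(panel)
  hi <- variants[variants$consequence %in% high_impact_levels() &
                   !is.na(variants$transcript_id), , drop = FALSE]
  if (nrow(hi) == 0) return(character(0))
  in_late <- vapply(hi$lines, function(l) any(fl[2:3] %in% l), logical(1))
  in_1957 <- vapply(hi$lines, function(l) fl[1] %in% l, logical(1))
  sort(unique(hi$transcript_id[in_late & !in_1957]))
}

#' Strategy 4: monotonically decreasing mean SIFT score
#'
#' Eligible transcripts have a defined mean SIFT score (at least one scored
#' variant) in all three focal lines. Selected iff the mean strictly
#' decreases at both steps (1957 -> 1978 -> Ross 308; plateaus fail) and the
#' transcript sits in the bottom 50th percentile of mean SIFT for the 1978
#' line or for the Ross 308 line (nearest-rank over each line's scored
#' transcripts, ties included).
#'
#' @param metrics `vp_metrics` covering the three focal lines.
#' @param panel `vp_panel`.
#' @param q bottom-percentile (default 0.50).
#' @return sorted character vector of transcript ids.
#' @export
strategy4 <- function(metrics, panel, q = 0.50) {
  fl <- focal_lines(panel)
  w <- metrics |>
    dplyr::filter(.data$line_id %in% fl) |>
    dplyr::select("transcript_id", "line_id", "mean_sift") |>
    tidyr::pivot_wider(names_from = "line_id", values_from = "mean_sift")
  m57 <- w[[fl[1]]]; m78 <- w[[fl[2]]]; mro <- w[[fl[3]]]
  eligible <- !is.na(m57) & !is.na(m78) & !is.na(mro)
  decreasing <- eligible & (m78 < m57) & (mro < m78)
  # bottom-percentile populations: all transcripts scored in that line
  pop78 <- m78[!is.na(m78)]; popro <- mro[!is.na(mro)]
  low78 <- rep(FALSE, nrow(w)); lowro <- rep(FALSE, nrow(w))
  if (length(pop78) > 0) {
    low78 <- !is.na(m78) & m78 <= nearest_rank_percentile(pop78, q)
  }
  if (length(popro) > 0) {
    lowro <- !is.na(mro) & mro <= nearest_rank_percentile(popro, q)
  }
  sort(w$transcript_id[decreasing & (low78 | lowro)])
}

#' Strategy 5: accumulation of deleterious variants
#'
#' Selects transcripts whose count of deleterious variants (SIFT < 0.05) is
#' non-decreasing at both steps with a strict overall increase from 1957 to
#' Ross 308 (set `strict_per_step = TRUE` to require a strict increase at
#' each step), and whose deleterious density in Ross 308 reaches the 99th
#' nearest-rank percentile over transcripts with at least one deleterious
#' variant in Ross 308.
#'
#' @param metrics `vp_metrics` covering the three focal lines.
#' @param panel `vp_panel`.
#' @param q percentile (default 0.99).
#' @param strict_per_step require strict increase at each step.
#' @return sorted character vector of transcript ids.
#' @export
strategy5 <- function(metrics, panel, q = 0.99, strict_per_step = FALSE) {
  fl <- focal_lines(panel)
  w <- metrics |>
    dplyr::filter(.data$line_id %in% fl) |>
    dplyr::select("transcript_id", "line_id", "n_deleterious",
                  "deleterious_density") |>
    tidyr::pivot_wider(names_from = "line_id",
                       values_from = c("n_deleterious", "deleterious_density"))
  n57 <- w[[paste0("n_deleterious_", fl[1])]]
  n78 <- w[[paste0("n_deleterious_", fl[2])]]
  nro <- w[[paste0("n_deleterious_", fl[3])]]
  dro <- w[[paste0("deleterious_density_", fl[3])]]
  increasing <- if (strict_per_step) {
    (n78 > n57) & (nro > n78)
  } else {
    (n78 >= n57) & (nro >= n78) & (nro > n57)
  }
  pop <- dro[nro > 0]
  if (length(pop) == 0) return(character(0))
  thr <- nearest_rank_percentile(pop, q)
  sort(w$transcript_id[increasing & nro > 0 & dro >= thr])
}

#' Combine strategy selections into a prioritized set
#'
#' Builds the per-transcript strategy-membership table, the combination
#' (upset-style) counts over every realized non-empty subset of strategies,
#' and the final prioritized set of transcripts selected by at least
#' `min_strategies` strategies.
#'
#' @param strategy_sets named list of character vectors (e.g.
#'   `list(S1 = ..., ..., S5 = ...)`).
#' @param universe character vector: the transcript universe (membership
#'   rows are emitted for all of it).
#' @param min_strategies minimum number of strategies (default 3).
#' @return an object of class `vp_priority` with elements `membership`
#'   (tibble: transcript_id, one logical column per strategy,
#'   `n_strategies`), `combinations` (tibble: `combination`, `n` over
#'   transcripts selected by >= 1 strategy), `prioritized` (character) and
#'   `min_strategies`.
#' @export
prioritize <- function(strategy_sets, universe, min_strategies = 3) {
  if (is.null(names(strategy_sets)) || any(!nzchar(names(strategy_sets)))) {
    abort("`strategy_sets` must be a named list.")
  }
  stray <- setdiff(unique(unlist(strategy_sets)), universe)
  if (length(stray) > 0) {
    abort(paste0("strategy selections outside the universe: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  membership <- tibble(transcript_id = sort(unique(universe)))
  for (nm in names(strategy_sets)) {
    membership[[nm]] <- membership$transcript_id %in% strategy_sets[[nm]]
  }
  flags <- as.matrix(membership[, names(strategy_sets), drop = FALSE])
  membership$n_strategies <- as.integer(rowSums(flags))
  any_sel <- membership$n_strategies > 0
  combo <- apply(flags[any_sel, , drop = FALSE], 1, function(r) {
    paste(names(strategy_sets)[r], collapse = "+")
  })
  tab <- table(combo)
  combinations <- tibble(combination = names(tab), n = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  out <- list(
    membership = membership,
    combinations = combinations,
    prioritized = membership$transcript_id[membership$n_strategies >= min_strategies],
    min_strategies = min_strategies
  )
  class(out) <- "vp_priority"
  out
}

#' @exportS3Method base::print
print.vp_priority <- function(x, ...) {
  cat("Strategy combination filter (min strategies =", x$min_strategies, ")\n")
  strat_cols <- setdiff(names(x$membership), c("transcript_id", "n_strategies"))
  for (nm in strat_cols) {
    cat(sprintf("  %s: %d transcripts\n", nm, sum(x$membership[[nm]])))
  }
  cat(sprintf("  selected by >= %d strategies: %d transcripts\n",
              x$min_strategies, length(x$prioritized)))
  invisible(x)
}
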