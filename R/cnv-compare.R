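#' Filter raw CNV calls
#'
#' Keeps calls longer than 1000 bp whose fraction of multi-mapping reads is
#' below 0.5 (both thresholds strict: a 1000 bp call and a call with
#' multimap fraction exactly 0.5 are dropped). Idempotent.
#'
#' @param cnvs `vp_cnvs` tibble.
#' @param min_size calls must be strictly longer than this (default 1000 bp).
#' @param max_multimap multimap fraction must be strictly below this
#'   (default 0.5).
#' @return filtered `vp_cnvs` tibble.
#' @export
filter_cnvs <- function(cnvs, min_size = 1000, max_multimap = 0.5) {
  if (anyNA(cnvs$multimap_fraction)) {
    abort("CNV records are missing multimap_fraction.")
  }
  cnv_table(cnvs[cnvs$size > min_size & cnvs$multimap_fraction < max_multimap,
                 , drop = FALSE])
}

#' Shared CNVs between two lines
#'
#' Two CNVs are shared when they lie on the same chromosome, have the same
#' type (a gain never shares with a loss), and overlap by more than
#' `min_frac` of the length of *both* calls (reciprocal, strict: an exact
#' 50% overlap is not shared). `reciprocal = FALSE` relaxes the rule to
#' either direction.
#'
#' @param set_a,set_b filtered `vp_cnvs` tibbles.
#' @param min_frac overlap fraction (default 0.5).
#' @param reciprocal require the fraction in both directions (default TRUE).
#' @return tibble of shared pairs: `idx_a, idx_b` (row indices into the
#'   inputs), `chrom, cnv_type, overlap_bp, frac_a, frac_b`.
#' @export
shared_cnvs <- function(set_a, set_b, min_frac = 0.5, reciprocal = TRUE) {
  empty <- tibble(idx_a = integer(), idx_b = integer(), chrom = character(),
                  cnv_type = character(), overlap_bp = integer(),
                  frac_a = numeric(), frac_b = numeric())
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)
  gr_a <- IRanges::IRanges(set_a$start, set_a$end)
  gr_b <- IRanges::IRanges(set_b$start, set_b$end)
  hits <- IRanges::findOverlaps(gr_a, gr_b)
  ia <- S4Vectors::queryHits(hits); ib <- S4Vectors::subjectHits(hits)
  same <- set_a$chrom[ia] == set_b$chrom[ib] &
    set_a$cnv_type[ia] == set_b$cnv_type[ib]
  ia <- ia[same]; ib <- ib[same]
  if (length(ia) == 0) return(empty)
  ov <- pmin(set_a$end[ia], set_b$end[ib]) -
    pmax(set_a$start[ia], set_b$start[ib]) + 1L
  fa <- ov / set_a$size[ia]
  fb <- ov / set_b$size[ib]
  keep <- if (reciprocal) fa > min_frac & fb > min_frac else
    fa > min_frac | fb > min_frac
  tibble(idx_a = ia[keep], idx_b = ib[keep],
         chrom = set_a$chrom[ia[keep]], cnv_type = set_a$cnv_type[ia[keep]],
         overlap_bp = as.integer(ov[keep]),
         frac_a = fa[keep], frac_b = fb[keep])
}

#' Three-way CNV sharing classification
#'
#' For each line's CNV set, classifies every call by which of the other two
#' lines it shares a CNV with (mutual pairwise sharing; see [shared_cnvs()]).
#' A call is "common to all" iff it has a shared partner in each other line.
#' Classes are mutually exclusive per call.
#'
#' @param cnv_sets named list of three filtered `vp_cnvs` tibbles.
#' @param min_frac,reciprocal passed to [shared_cnvs()].
#' @return list with `per_cnv` (tibble: `line_id, idx, class`) and `counts`
#'   (tibble: `line_id, class, n`), where class is `"unique"`,
#'   `"shared_with_<line>"` or `"common_all"`.
#' @export
three_way_shared <- function(cnv_sets, min_frac = 0.5, reciprocal = TRUE) {
  if (length(cnv_sets) != 3 || is.null(names(cnv_sets))) {
    abort("`cnv_sets` must be a named list of three CNV tables.")
  }
  ids <- names(cnv_sets)
  per <- list()
  for (a in ids) {
    others <- setdiff(ids, a)
    flags <- matrix(FALSE, nrow(cnv_sets[[a]]), length(others),
                    dimnames = list(NULL, others))
    for (b in others) {
      pairs <- shared_cnvs(cnv_sets[[a]], cnv_sets[[b]], min_frac, reciprocal)
      flags[unique(pairs$idx_a), b] <- TRUE
    }
    cls <- apply(flags, 1, function(r) {
      if (all(r)) "common_all"
      else if (!any(r)) "unique"
      else paste0("shared_with_", names(r)[r])
    })
    per[[a]] <- tibble(line_id = a,
                       idx = seq_len(nrow(cnv_sets[[a]])),
                       class = if (nrow(cnv_sets[[a]]) > 0) cls else character(0))
  }
  per_cnv <- dplyr::bind_rows(per)
  counts <- per_cnv |> dplyr::count(.data$line_id, .data$class)
  list(per_cnv = per_cnv, counts = counts)
}

#' Genes overlapped by CNVs
#'
#' Assigns a gene to the gain (or loss) list when at least 50% of its
#' genomic span (inclusive: exactly half counts) is covered by the union of
#' the same-type CNVs. Genes without span coordinates are skipped with a
#' warning.
#'
#' @param cnvs filtered `vp_cnvs` tibble (one line).
#' @param gene_spans tibble `gene_id, chrom, gene_start, gene_end`.
#' @param min_frac covered fraction required (default 0.5, inclusive).
#' @return list with character vectors `gains` and `losses`.
#' @export
cnv_gene_overlap <- function(cnvs, gene_spans, min_frac = 0.5) {
  no_span <- is.na(gene_spans$gene_start) | is.na(gene_spans$gene_end)
  if (any(no_span)) {
    warn(paste0("skipping ", sum(no_span), " gene(s) without span coordinates."))
    gene_spans <- gene_spans[!no_span, , drop = FALSE]
  }
  one_type <- function(type) {
    cc <- cnvs[cnvs$cnv_type == type, , drop = FALSE]
    if (nrow(cc) == 0 || nrow(gene_spans) == 0) return(character(0))
    covered <- vapply(seq_len(nrow(gene_spans)), function(i) {
      g <- gene_spans[i, ]
      same <- cc[cc$chrom == g$chrom, , drop = FALSE]
      if (nrow(same) == 0) return(0L)
      ir <- IRanges::reduce(IRanges::IRanges(same$start, same$end))
      inter <- IRanges::intersect(
        ir, IRanges::IRanges(g$gene_start, g$gene_end))
      sum(IRanges::width(inter))
    }, integer(1))
    span_len <- gene_spans$gene_end - gene_spans$gene_start + 1L
    sort(gene_spans$gene_id[covered / span_len >= min_frac])
  }
  list(gains = one_type("gain"), losses = one_type("loss"))
}

#' Summary statistics for a CNV set
#'
#' Table-style summary of one line's filtered calls: counts, size
#' statistics, genomic coverage breadth (fraction of the genome covered by
#' the union of calls, overlaps merged) and, when gene spans are supplied,
#' the numbers of genes overlapping gains and losses.
#'
#' @param cnvs filtered `vp_cnvs` tibble.
#' @param genome_size total genome size in bp.
#' @param gene_spans optional tibble for [cnv_gene_overlap()].
#' @return one-row tibble of class `vp_cnv_summary`.
#' @export
summarize_cnvs <- function(cnvs, genome_size, gene_spans = NULL) {
  if (genome_size <= 0) abort("`genome_size` must be positive.")
  breadth <- if (nrow(cnvs) == 0) 0 else {
    un <- 0L
    for (ch in unique(cnvs$chrom)) {
      cc <- cnvs[cnvs$chrom == ch, ]
      un <- un + sum(IRanges::width(
        IRanges::reduce(IRanges::IRanges(cc$start, cc$end))))
    }
    un / genome_size
  }
  out <- tibble(
    n_cnvs = nrow(cnvs),
    median_size = if (nrow(cnvs)) median(cnvs$size) else NA_real_,
    mean_size = if (nrow(cnvs)) mean(cnvs$size) else NA_real_,
    min_size = if (nrow(cnvs)) min(cnvs$size) else NA_integer_,
    max_size = if (nrow(cnvs)) max(cnvs$size) else NA_integer_,
    breadth = breadth,
    n_gains = sum(cnvs$cnv_type == "gain"),
    n_losses = sum(cnvs$cnv_type == "loss")
  )
  if (!is.null(gene_spans)) {
    ov <- cnv_gene_overlap(cnvs, gene_spans)
    out$genes_with_gain <- length(ov$gains)
    out$genes_with_loss <- length(ov$losses)
  }
  class(out) <- c("vp_cnv_summary", class(out))
  out
}
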