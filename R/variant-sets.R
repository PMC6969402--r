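#' Variants shared by every named line
#'
#' Returns the keys of variants present in all of `lines` — the "common
#' core" of the compared genomes (position/allele intersection, as computed
#' upstream by tools like vcf-isec).
#'
#' @param variants a `vp_variants` tibble.
#' @param lines character vector of line ids, non-empty.
#' @return character vector of variant keys (`chrom:pos:ref:alt`).
#' @export
shared_core <- function(variants, lines) {
  if (length(lines) == 0) abort("`lines` must be non-empty.")
  check_known_lines(variants, lines)
  keys <- variant_key(variants)
  keep <- vapply(variants$lines, function(l) all(lines %in% l), logical(1))
  unique(keys[keep])
}

#' Variants exclusive to a set of target lines
#'
#' Keys present in at least one `target_lines` line and absent from every
#' `background_lines` line — the "unique variant" operation used to find
#' variants private to the fast-growing broiler lines relative to all other
#' breeds.
#'
#' @param variants a `vp_variants` tibble.
#' @param target_lines,background_lines disjoint character vectors of line ids.
#' @return character vector of variant keys.
#' @export
exclusive_to <- function(variants, target_lines, background_lines) {
  if (length(intersect(target_lines, background_lines)) > 0) {
    abort("target and background line sets must be disjoint.")
  }
  check_known_lines(variants, c(target_lines, background_lines))
  keys <- variant_key(variants)
  in_target <- vapply(variants$lines, function(l) any(target_lines %in% l),
                      logical(1))
  in_bg <- vapply(variants$lines, function(l) any(background_lines %in% l),
                  logical(1))
  # a key can occur on several rows (same site annotated once); resolve at key level
  tgt_keys <- unique(keys[in_target])
  bg_keys <- unique(keys[in_bg])
  setdiff(tgt_keys, bg_keys)
}

check_known_lines <- function(variants, lines) {
  known <- unique(unlist(variants$lines))
  unknown <- setdiff(lines, known)
  if (length(unknown) > 0 && nrow(variants) > 0) {
    abort(paste0("unknown line id(s): ", paste(unknown, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Per-line consequence summary
#'
#' Counts one line's variant records by consequence class (the in-repo
#' equivalent of a per-breed "SNPs by feature and impact" summary table).
#' Every vocabulary class appears in the output, zero-filled, so summaries
#' from different lines align row-for-row.
#'
#' @param variants a `vp_variants` tibble.
#' @param line single line id.
#' @return tibble `consequence, n` covering [consequence_levels()].
#' @export
summarize_by_consequence <- function(variants, line) {
  if (length(line) != 1) abort("`line` must be a single line id.")
  present <- vapply(variants$lines, function(l) line %in% l, logical(1))
  counts <- table(factor(variants$consequence[present],
                         levels = consequence_levels()))
  tibble(consequence = consequence_levels(), n = as.integer(counts))
}

#' Venn-style membership counts over the focal lines
#'
#' Classifies every variant key by the exact subset of `lines` it occurs in
#' and tallies the classes (the cross-line sharing structure of the panel).
#'
#' @param variants a `vp_variants` tibble.
#' @param lines line ids to classify against (order fixes the label order).
#' @return tibble `membership, n` where membership is e.g. `"1957+ross308"`.
#' @export
count_memberships <- function(variants, lines) {
  if (length(lines) == 0) abort("`lines` must be non-empty.")
  keys <- variant_key(variants)
  member <- vapply(variants$lines, function(l) {
    paste(lines[lines %in% l], collapse = "+")
  }, character(1))
  keep <- !duplicated(keys) & nzchar(member)
  tab <- table(member[keep])
  tibble(membership = names(tab), n = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
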