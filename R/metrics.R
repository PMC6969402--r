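#' Per-(transcript, line) burden metrics
#'
#' For each transcript in the catalog and each requested line, computes the
#' variant-burden statistics that drive the prioritization strategies:
#'
#' * `n_snps_total` — all variant records assigned to the transcript and
#'   present in the line;
#' * `n_nonsyn` and `nonsyn_density` — nonsynonymous SNPs and their count
#'   divided by CDS length (per bp). CDS length, not genomic span, is the
#'   denominator: these are coding-impact densities;
#' * `n_scored`, `mean_sift` — variants carrying a SIFT score and their
#'   plain arithmetic mean (NA when nothing is scored);
#' * `n_deleterious`, `deleterious_density` — SIFT strictly below 0.05
#'   (a score of exactly 0.05 counts as tolerated);
#' * `n_high_impact` — frameshift, start-loss and stop-gain variants.
#'
#' Transcripts with no variants in a line get explicit zero rows so that
#' between-line deltas are defined everywhere. Each variant record carries a
#' single transcript assignment (the annotation's canonical transcript);
#' no fan-out to sibling transcripts is performed, so per-line sums over
#' transcripts conserve the record counts.
#'
#' @param variants a `vp_variants` tibble.
#' @param catalog a `vp_catalog` tibble.
#' @param lines line ids to compute (default: all lines seen in `variants`).
#' @param sift_cutoff deleterious threshold, strict (default 0.05).
#' @return tibble with one row per (transcript, line).
#' @export
transcript_metrics <- function(variants, catalog, lines = NULL,
                               sift_cutoff = 0.05) {
  lines <- lines %||% sort(unique(unlist(variants$lines)))
  tx <- variants[!is.na(variants$transcript_id), , drop = FALSE]
  unknown <- setdiff(unique(tx$transcript_id), catalog$transcript_id)
  if (length(unknown) > 0) {
    abort(paste0("variants reference transcript id(s) absent from the catalog: ",
                 paste(head(unknown, 10), collapse = ", ")))
  }
  base <- tidyr::expand_grid(
    transcript_id = catalog$transcript_id, line_id = lines
  )
  if (nrow(tx) > 0) {
    long <- tibble(
      transcript_id = rep(tx$transcript_id, lengths(tx$lines)),
      line_id = unlist(tx$lines),
      consequence = rep(tx$consequence, lengths(tx$lines)),
      sift = rep(tx$sift, lengths(tx$lines))
    ) |>
      dplyr::filter(.data$line_id %in% lines)
    agg <- long |>
      dplyr::group_by(.data$transcript_id, .data$line_id) |>
      dplyr::summarise(
        n_snps_total = dplyr::n(),
        n_nonsyn = sum(.data$consequence == "nonsynonymous"),
        n_scored = sum(!is.na(.data$sift)),
        mean_sift = ifelse(sum(!is.na(.data$sift)) > 0,
                           mean(.data$sift, na.rm = TRUE), NA_real_),
        n_deleterious = sum(!is.na(.data$sift) & .data$sift < sift_cutoff),
        n_high_impact = sum(.data$consequence %in% high_impact_levels()),
        .groups = "drop"
      )
  } else {
    agg <- tibble(transcript_id = character(), line_id = character(),
                  n_snps_total = integer(), n_nonsyn = integer(),
                  n_scored = integer(), mean_sift = numeric(),
                  n_deleterious = integer(), n_high_impact = integer())
  }
  out <- base |>
    dplyr::left_join(agg, by = c("transcript_id", "line_id")) |>
    dplyr::mutate(dplyr::across(
      c("n_snps_total", "n_nonsyn", "n_scored", "n_deleterious",
        "n_high_impact"),
      ~ tidyr::replace_na(as.integer(.x), 0L)
    )) |>
    dplyr::left_join(catalog[, c("transcript_id", "gene_id", "cds_length")],
                     by = "transcript_id") |>
    dplyr::mutate(
      nonsyn_density = .data$n_nonsyn / .data$cds_length,
      deleterious_density = .data$n_deleterious / .data$cds_length
    ) |>
    dplyr::select("transcript_id", "gene_id", "line_id", "cds_length",
                  "n_snps_total", "n_nonsyn", "nonsyn_density", "n_scored",
                  "mean_sift", "n_deleterious", "deleterious_density",
                  "n_high_impact")
  class(out) <- c("vp_metrics", class(out))
  out
}

#' Per-transcript change in nonsynonymous SNP density
#'
#' Signed elementwise difference `later - earlier` of `nonsyn_density`,
#' defined for every transcript of the shared catalog (explicit zeros from
#' [transcript_metrics()] make this total).
#'
#' @param metrics a `vp_metrics` tibble covering both lines.
#' @param line_earlier,line_later line ids in temporal order.
#' @return tibble `transcript_id, delta` (delta in SNPs per bp).
#' @export
density_delta <- function(metrics, line_earlier, line_later) {
  a <- metrics[metrics$line_id == line_earlier, c("transcript_id", "nonsyn_density")]
  b <- metrics[metrics$line_id == line_later, c("transcript_id", "nonsyn_density")]
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("metrics must contain rows for both lines.")
  }
  if (!setequal(a$transcript_id, b$transcript_id)) {
    abort("the two metric sets cover different catalogs.")
  }
  dplyr::inner_join(a, b, by = "transcript_id",
                    suffix = c("_earlier", "_later")) |>
    dplyr::transmute(
      transcript_id = .data$transcript_id,
      delta = .data$nonsyn_density_later - .data$nonsyn_density_earlier
    )
}
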