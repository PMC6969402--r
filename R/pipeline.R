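#' Pipeline run configuration
#'
#' Collects every parameter that affects pipeline output. The defaults are
#' the study's stated thresholds: percentiles 0.95/0.90/0.50/0.99 for
#' Strategies 1/2/4/5, SIFT deleterious cutoff 0.05 (strict), at least 3
#' strategies for the final filter, 90th-percentile SNP-dense genes with
#' min-3-gene categories at BH-adjusted alpha 0.05, CNV size > 1000 bp and
#' multimap < 0.5 with > 50% reciprocal sharing and >= 50% gene overlap,
#' and depth thresholds > 10 (Illumina) / > 5 (SOLiD).
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param q1,q2,q4,q5 strategy percentiles.
#' @param sift_cutoff deleterious SIFT threshold (strict).
#' @param min_strategies combination filter threshold.
#' @param enrich_q SNP-dense gene percentile.
#' @param min_category minimum universe genes per category.
#' @param alpha enrichment significance level on q-values.
#' @param cnv_min_size,cnv_max_multimap,cnv_min_frac CNV filter/sharing
#'   parameters.
#' @param illumina_min,solid_min depth thresholds (strict).
#' @return a `vp_run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       q1 = 0.95, q2 = 0.90, q4 = 0.50, q5 = 0.99,
                       sift_cutoff = 0.05, min_strategies = 3,
                       enrich_q = 0.90, min_category = 3, alpha = 0.05,
                       cnv_min_size = 1000, cnv_max_multimap = 0.5,
                       cnv_min_frac = 0.5,
                       illumina_min = 10, solid_min = 5) {
  cfg <- list(sim = sim, q1 = q1, q2 = q2, q4 = q4, q5 = q5,
              sift_cutoff = sift_cutoff, min_strategies = min_strategies,
              enrich_q = enrich_q, min_category = min_category, alpha = alpha,
              cnv_min_size = cnv_min_size, cnv_max_multimap = cnv_max_multimap,
              cnv_min_frac = cnv_min_frac,
              illumina_min = illumina_min, solid_min = solid_min)
  class(cfg) <- "vp_run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> metrics -> strategies -> combination filter ->
#' enrichment -> CNV comparison -> phylogenetic SNP matrix on a synthetic
#' cohort, optionally writing every stage's table plus a machine-readable
#' JSON report to `outdir`. The report records all parameters, per-stage
#' record counts and the prioritized transcript list; re-running with the
#' same config and seed reproduces every output byte-for-byte.
#'
#' @param config a [run_config()].
#' @param seed integer seed driving every stage's randomness.
#' @param outdir output directory (created); NULL skips writing.
#' @return a `vp_run` list: `cohort`, `metrics`, `strategies`, `priority`
#'   (`vp_priority`), `enrichment` (per focal line), `cnv` (sets, sharing,
#'   summaries), `alignment`, `report`.
#' @export
run_pipeline <- function(config = run_config(), seed = 1, outdir = NULL) {
  stopifnot(inherits(config, "vp_run_config"))
  cohort <- generate_cohort(config$sim, seed = seed)
  panel <- cohort$panel
  fl <- focal_lines(panel)

  metrics <- transcript_metrics(cohort$variants, cohort$catalog,
                                lines = panel$line_id,
                                sift_cutoff = config$sift_cutoff)
  strategies <- list(
    S1 = strategy1(metrics, panel, q = config$q1),
    S2 = strategy2(cohort$variants, cohort$catalog, panel, q = config$q2),
    S3 = strategy3(cohort$variants, panel),
    S4 = strategy4(metrics, panel, q = config$q4),
    S5 = strategy5(metrics, panel, q = config$q5)
  )
  priority <- prioritize(strategies, cohort$catalog$transcript_id,
                         min_strategies = config$min_strategies)

  gene_sets <- simulate_gene_sets(cohort$catalog, seed = seed)
  universe <- sort(unique(gene_sets$gene_id))
  enrichment <- lapply(setNames(fl, fl), function(l) {
    dense <- intersect(snp_dense_genes(metrics, l, q = config$enrich_q),
                       universe)
    hypergeom_enrich(dense, universe, gene_sets,
                     min_category = config$min_category,
                     alpha = config$alpha)
  })

  cnv_panel <- generate_cnv_panel(seed = seed, lines = fl)
  cnv_filtered <- lapply(cnv_panel$cnvs, filter_cnvs,
                         min_size = config$cnv_min_size,
                         max_multimap = config$cnv_max_multimap)
  cnv_sharing <- three_way_shared(cnv_filtered, min_frac = config$cnv_min_frac)
  gene_spans <- cohort$catalog[, c("gene_id", "chrom", "gene_start", "gene_end")]
  cnv_summaries <- dplyr::bind_rows(lapply(names(cnv_filtered), function(l) {
    s <- summarize_cnvs(cnv_filtered[[l]], cnv_panel$genome_size, gene_spans)
    s$line_id <- l
    s
  }))

  cov <- generate_coverage_masks(panel, illumina_min = config$illumina_min,
                                 solid_min = config$solid_min, seed = seed)
  regions <- qualifying_regions(cov$masks, panel,
                                illumina_min = config$illumina_min,
                                solid_min = config$solid_min)
  retained <- presence_filter(cov$snps, panel, regions)
  alignment <- if (nrow(retained) > 0) {
    build_snp_alignment(retained, panel, outgroup = "red_jungle_fowl")
  } else NULL

  report <- list(
    parameters = config[setdiff(names(config), "sim")],
    sim_parameters = unclass(config$sim),
    seed = seed,
    counts = list(
      n_variants = nrow(cohort$variants),
      n_transcripts = nrow(cohort$catalog),
      strategy_sizes = lapply(strategies, length),
      n_prioritized = length(priority$prioritized),
      n_cnvs_filtered = lapply(cnv_filtered, nrow),
      n_qualifying_regions = nrow(regions),
      n_alignment_sites = if (is.null(alignment)) 0L else ncol(alignment$matrix)
    ),
    prioritized = priority$prioritized
  )

  out <- list(cohort = cohort, metrics = metrics, strategies = strategies,
              priority = priority, enrichment = enrichment,
              cnv = list(sets = cnv_filtered, sharing = cnv_sharing,
                         summaries = cnv_summaries),
              alignment = alignment, report = report)
  class(out) <- "vp_run"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_variant_table(cohort$variants, file.path(outdir, "variants.tsv"))
    readr::write_tsv(as_tibble(cohort$catalog), file.path(outdir, "catalog.tsv"),
                     progress = FALSE)
    readr::write_tsv(metrics, file.path(outdir, "transcript_metrics.tsv"),
                     progress = FALSE)
    readr::write_tsv(priority$membership, file.path(outdir, "membership.tsv"),
                     progress = FALSE)
    readr::write_tsv(priority$combinations, file.path(outdir, "combinations.tsv"),
                     progress = FALSE)
    for (l in names(enrichment)) {
      readr::write_tsv(enrichment[[l]],
                       file.path(outdir, paste0("enrichment_", l, ".tsv")),
                       progress = FALSE)
    }
    readr::write_tsv(cnv_summaries, file.path(outdir, "cnv_summaries.tsv"),
                     progress = FALSE)
    readr::write_tsv(cnv_sharing$counts, file.path(outdir, "cnv_sharing.tsv"),
                     progress = FALSE)
    if (!is.null(alignment)) {
      write_alignment_fasta(alignment, file.path(outdir, "snp_alignment.fasta"))
      write_alignment_phylip(alignment, file.path(outdir, "snp_alignment.phy"))
      write_site_map(alignment, file.path(outdir, "snp_sites.tsv"))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @exportS3Method base::print
print.vp_run <- function(x, ...) {
  cat("varprior pipeline run\n")
  cat("  variants:", x$report$counts$n_variants,
      " transcripts:", x$report$counts$n_transcripts, "\n")
  cat("  strategy sizes:",
      paste(names(x$strategies), vapply(x$strategies, length, integer(1)),
            sep = "=", collapse = " "), "\n")
  cat("  prioritized (>=", x$priority$min_strategies, "strategies):",
      length(x$priority$prioritized), "\n")
  if (!is.null(x$alignment)) {
    cat("  SNP alignment:", nrow(x$alignment$matrix), "x",
        ncol(x$alignment$matrix), "\n")
  }
  invisible(x)
}
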