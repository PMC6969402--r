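#' Default simulation configuration
#'
#' Parameters of the synthetic cohort generator. The defaults define the
#' study conditions the package is tested under: a three-line longitudinal
#' design (1957 -> 1978 -> Ross 308, Illumina-sequenced) against a
#' background panel of two Illumina and five SOLiD lines, 2,000 transcripts
#' of log-normal CDS length, a per-transcript pool of annotated variants
#' whose cross-line presence patterns are exchangeable across the focal
#' lines under the null, and 20 planted transcripts engineered to
#' accumulate deleterious burden monotonically across the epochs.
#'
#' @param n_transcripts number of transcripts (default 2000).
#' @param n_planted number of planted signal transcripts (default 20).
#' @param cds_meanlog,cds_sdlog,cds_min log-normal CDS length parameters
#'   (bp), with a lower clamp.
#' @param pool_rate expected variants per CDS bp per transcript (default
#'   0.01: a 1.5 kb transcript carries ~15 segregating variants across the
#'   whole panel).
#' @param pattern_probs probabilities of the cross-line presence patterns
#'   (must sum to 1): `core_all` (every line), `focal_shared` (all three
#'   focal lines), `focal_pair` (a uniform pair of focal lines),
#'   `focal_single` (one focal line), `background_single` (one background
#'   line).
#' @param consequence_probs named probabilities over the transcript-variant
#'   consequence classes (must sum to 1).
#' @param sift_p_low probability that a null missense score is drawn from
#'   `U(0, 0.05)` (the deleterious tail); the remainder is Beta(2, 1),
#'   skewed toward tolerated.
#' @param n_intergenic expected intergenic variants (Poisson).
#' @param planted planted effect sizes, a list:
#'   `s2_density` (Ross-exclusive nonsynonymous SNPs per CDS bp),
#'   `s1_density1`/`s1_density2` (extra nonsynonymous density per epoch for
#'   Strategy-1-engineered transcripts), `s4_n_core` (shared scored
#'   baseline variants), `s4_n_1978` (deleterious variants appearing in
#'   1978), `s4_n_ross` (near-zero-SIFT variants appearing in Ross 308),
#'   `n_s1` / `n_s5` (how many planted transcripts are additionally
#'   engineered for Strategies 1 and 5), `s5_density` (deleterious density
#'   of the Strategy-5 extremes).
#' @return a `vp_sim_config` list.
#' @export
sim_config <- function(n_transcripts = 2000,
                       n_planted = 20,
                       cds_meanlog = log(1500), cds_sdlog = 0.45,
                       cds_min = 500,
                       pool_rate = 0.01,
                       pattern_probs = c(core_all = 0.20, focal_shared = 0.10,
                                         focal_pair = 0.15, focal_single = 0.25,
                                         background_single = 0.30),
                       consequence_probs = c(synonymous = 0.32,
                                             nonsynonymous = 0.40,
                                             intronic = 0.12, utr5 = 0.04,
                                             utr3 = 0.04,
                                             frameshift_indel = 0.03,
                                             nonframeshift_indel = 0.03,
                                             stop_gain = 0.015,
                                             stop_loss = 0.003,
                                             start_loss = 0.002),
                       sift_p_low = 0.05,
                       n_intergenic = 200,
                       planted = list(s2_density = 0.025,
                                      s1_density1 = 0.020,
                                      s1_density2 = 0.022,
                                      s4_n_core = 2, s4_n_1978 = 4,
                                      s4_n_ross = 2,
                                      n_s1 = 10, n_s5 = 3,
                                      s5_density = 0.02)) {
  if (abs(sum(pattern_probs) - 1) > 1e-8) {
    abort("pattern_probs must sum to 1.")
  }
  if (abs(sum(consequence_probs) - 1) > 1e-8) {
    abort("consequence_probs must sum to 1.")
  }
  if (n_planted > n_transcripts) {
    abort("n_planted cannot exceed n_transcripts.")
  }
  cfg <- list(
    n_transcripts = n_transcripts, n_planted = n_planted,
    cds_meanlog = cds_meanlog, cds_sdlog = cds_sdlog, cds_min = cds_min,
    pool_rate = pool_rate, pattern_probs = pattern_probs,
    consequence_probs = consequence_probs, sift_p_low = sift_p_low,
    n_intergenic = n_intergenic, planted = planted
  )
  class(cfg) <- "vp_sim_config"
  cfg
}

#' Default line panel of the simulated study
#'
#' Three Illumina-sequenced focal lines in temporal order plus two Illumina
#' and five SOLiD background lines.
#'
#' @return a `vp_panel` tibble.
#' @export
default_panel <- function() {
  line_panel(
    line_id = c("line_1957", "line_1978", "ross308",
                paste0("bg_ill_", 1:2), paste0("bg_sol_", 1:5)),
    platform = c("illumina", "illumina", "illumina",
                 rep("illumina", 2), rep("solid", 5)),
    role = c("focal_1957", "focal_1978", "focal_ross308", rep("background", 7))
  )
}

# lookup of presence-pattern codes -> line-id vectors
pattern_lookup <- function(panel) {
  fl <- focal_lines(panel); bg <- background_lines(panel)
  pairs <- utils::combn(fl, 2, simplify = FALSE)
  lk <- c(
    list(ALL = panel$line_id, FOCAL = fl),
    setNames(pairs, paste0("P", seq_along(pairs))),
    setNames(as.list(fl), paste0("F", seq_along(fl))),
    setNames(as.list(bg), paste0("B", seq_along(bg)))
  )
  lk
}

null_sift <- function(n, p_low) {
  low <- runif(n) < p_low
  out <- rbeta(n, 2, 1)
  out[low] <- runif(sum(low), 0, 0.05)
  out
}

#' Generate a synthetic multi-line cohort
#'
#' Produces an annotated variant table, a transcript catalog (1:1 with
#' genes, with genomic spans on five toy chromosomes) and ground-truth
#' labels for the planted transcripts. Null transcripts receive presence
#' patterns exchangeable across the three focal lines, so between-line
#' contrasts are centered under the null. Planted transcripts are
#' engineered so that each prioritization strategy has positive controls:
#' all planted transcripts accumulate Ross-exclusive nonsynonymous variants
#' (Strategy 2), a late-line high-impact variant (Strategy 3) and a
#' monotonically decreasing mean SIFT score with growing deleterious counts
#' (Strategies 4 and 5's increase clause); subsets additionally receive
#' large per-epoch density increments (Strategy 1) or extreme deleterious
#' densities (Strategy 5's 99th-percentile clause, which by construction
#' can only be attained by ~1% of the eligible population).
#'
#' @param config a [sim_config()] list.
#' @param seed integer seed; the same seed yields byte-identical output.
#' @param panel a `vp_panel` (default [default_panel()]).
#' @return list with `variants` (`vp_variants`), `catalog` (`vp_catalog`
#'   incl. `chrom`, `gene_start`, `gene_end`), `panel`, and `truth` (list:
#'   `planted` ids, `engineered` tibble of per-strategy flags).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1,
                            panel = default_panel()) {
  withr::local_seed(seed)
  n <- config$n_transcripts
  fl <- focal_lines(panel)
  lk <- pattern_lookup(panel)

  # ---- catalog: 1:1 transcript/gene, sequential spans on 5 chromosomes ----
  L <- pmax(config$cds_min, round(rlnorm(n, config$cds_meanlog, config$cds_sdlog)))
  tid <- sprintf("T%05d", seq_len(n))
  gid <- sprintf("G%05d", seq_len(n))
  chrom <- paste0("chr", (seq_len(n) - 1) %% 5 + 1)
  span_len <- 2L * L + 200L
  gene_start <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gene_start[idx] <- cumsum(c(1L, head(span_len[idx], -1) + 1000L))
  }
  catalog <- tibble(
    transcript_id = tid, gene_id = gid, cds_length = as.integer(L),
    chrom = chrom, gene_start = gene_start,
    gene_end = gene_start + span_len - 1L
  )
  class(catalog) <- c("vp_catalog", class(catalog))

  truth_planted <- character(0)
  engineered <- tibble(transcript_id = character(), S1 = logical(),
                       S2 = logical(), S3 = logical(), S4 = logical(),
                       S5 = logical())

  # ---- null variant pool ----
  n_pool <- rpois(n, config$pool_rate * L)
  null_tbl <- NULL
  if (sum(n_pool) > 0) {
    t_idx <- rep(seq_len(n), n_pool)
    N <- length(t_idx)
    pat_type <- sample(names(config$pattern_probs), N, TRUE,
                       prob = config$pattern_probs)
    code <- character(N)
    code[pat_type == "core_all"] <- "ALL"
    code[pat_type == "focal_shared"] <- "FOCAL"
    i <- pat_type == "focal_pair"
    code[i] <- paste0("P", sample.int(3, sum(i), TRUE))
    i <- pat_type == "focal_single"
    code[i] <- paste0("F", sample.int(3, sum(i), TRUE))
    i <- pat_type == "background_single"
    code[i] <- paste0("B", sample.int(length(background_lines(panel)),
                                      sum(i), TRUE))
    csq <- sample(names(config$consequence_probs), N, TRUE,
                  prob = config$consequence_probs)
    sift <- rep(NA_real_, N)
    ns <- csq == "nonsynonymous"
    sift[ns] <- null_sift(sum(ns), config$sift_p_low)
    null_tbl <- tibble(t = t_idx, code = code, consequence = csq, sift = sift)
  }

  # ---- planted engineering ----
  plant_tbl <- NULL
  if (config$n_planted > 0) {
    truth_planted <- sort(sample(tid, config$n_planted))
    pp <- config$planted
    rows <- vector("list", config$n_planted)
    eng <- vector("list", config$n_planted)
    for (k in seq_len(config$n_planted)) {
      ti <- match(truth_planted[k], tid)
      Lk <- L[ti]
      is_s1 <- k <= pp$n_s1
      is_s5 <- k <= pp$n_s5
      add <- list()
      # shared scored baseline (keeps mean SIFT defined in 1957)
      add$core <- tibble(code = "ALL", consequence = "nonsynonymous",
                         sift = runif(pp$s4_n_core, 0.5, 0.9))
      # Strategy 2: Ross-exclusive nonsynonymous burden
      n2 <- max(6L, round(pp$s2_density * Lk))
      add$s2 <- tibble(code = "F3", consequence = "nonsynonymous",
                       sift = runif(n2, 0.05, 0.2))
      # Strategy 4/5: deleterious variants appearing in 1978, lower in Ross
      add$s4a <- tibble(code = "P3", consequence = "nonsynonymous",
                        sift = runif(pp$s4_n_1978, 0.02, 0.045))
      add$s4b <- tibble(code = "F3", consequence = "nonsynonymous",
                        sift = runif(pp$s4_n_ross, 0, 0.02))
      # Strategy 3: a late-line high-impact variant, absent from 1957
      add$s3 <- tibble(code = if (k %% 2 == 0) "P3" else "F3",
                       consequence = "stop_gain", sift = NA_real_)
      if (is_s1) {
        add$s1a <- tibble(code = "P3", consequence = "nonsynonymous",
                          sift = runif(round(pp$s1_density1 * Lk), 0.1, 0.25))
        add$s1b <- tibble(code = "F3", consequence = "nonsynonymous",
                          sift = runif(round(pp$s1_density2 * Lk), 0.02, 0.1))
      }
      if (is_s5) {
        n5 <- round((pp$s5_density + 0.005 * k) * Lk)
        add$s5 <- tibble(code = "F3", consequence = "nonsynonymous",
                         sift = runif(n5, 0, 0.01))
      }
      tb <- dplyr::bind_rows(add)
      tb$t <- ti
      rows[[k]] <- tb
      eng[[k]] <- tibble(transcript_id = truth_planted[k],
                         S1 = is_s1, S2 = TRUE, S3 = TRUE, S4 = TRUE,
                         S5 = is_s5)
    }
    plant_tbl <- dplyr::bind_rows(rows)
    engineered <- dplyr::bind_rows(eng)
  }
  # NOTE: "P3" = {line_1978, ross308}, "F3" = {ross308} in pattern_lookup()
  # (pairs from combn(fl, 2): P1 = 1957+1978, P2 = 1957+ross, P3 = 1978+ross)
  all_tbl <- dplyr::bind_rows(null_tbl, plant_tbl)

  variants <- if (is.null(all_tbl) || nrow(all_tbl) == 0) {
    variant_table(tibble(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         consequence = character(), sift = numeric(),
                         transcript_id = character(), gene_id = character(),
                         lines = list()))
  } else {
    # positions: unique within each transcript's (disjoint) gene span
    all_tbl <- all_tbl[order(all_tbl$t), , drop = FALSE]
    pos <- integer(nrow(all_tbl))
    for (ti in unique(all_tbl$t)) {
      idx <- which(all_tbl$t == ti)
      pos[idx] <- gene_start[ti] +
        sort(sample.int(span_len[ti], length(idx))) - 1L
    }
    ref <- sample(c("A", "C", "G", "T"), nrow(all_tbl), TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1), USE.NAMES = FALSE)
    is_fs <- all_tbl$consequence == "frameshift_indel"
    alt[is_fs] <- paste0(ref[is_fs], "A")
    is_nf <- all_tbl$consequence == "nonframeshift_indel"
    alt[is_nf] <- paste0(ref[is_nf], "AGT")
    variant_table(tibble(
      chrom = chrom[all_tbl$t], pos = pos, ref = ref, alt = alt,
      consequence = all_tbl$consequence, sift = all_tbl$sift,
      transcript_id = tid[all_tbl$t], gene_id = gid[all_tbl$t],
      lines = lk[all_tbl$code]
    ))
  }

  # intergenic variants (no transcript assignment)
  n_ig <- rpois(1, config$n_intergenic)
  if (n_ig > 0) {
    ig_pos <- max(catalog$gene_end) + sort(sample.int(10 * n_ig + 10, n_ig))
    ig_ref <- sample(c("A", "C", "G", "T"), n_ig, TRUE)
    ig_alt <- vapply(ig_ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                     character(1), USE.NAMES = FALSE)
    ig_code <- sample(c("ALL", "FOCAL", paste0("F", 1:3),
                        paste0("B", seq_along(background_lines(panel)))),
                      n_ig, TRUE)
    ig <- variant_table(tibble(
      chrom = "chr1", pos = ig_pos, ref = ig_ref, alt = ig_alt,
      consequence = "intergenic", sift = NA_real_,
      transcript_id = NA_character_, gene_id = NA_character_,
      lines = lk[ig_code]
    ))
    variants <- variant_table(dplyr::bind_rows(variants, ig))
  }

  list(
    variants = variants, catalog = catalog, panel = panel,
    truth = list(planted = truth_planted, engineered = engineered)
  )
}

#' Simulate GO/KEGG-style gene sets
#'
#' Assigns each catalog gene a Poisson number of categories drawn from a
#' fixed pool, in tidy GMT form.
#'
#' @param catalog `vp_catalog` tibble.
#' @param n_categories number of categories in the pool.
#' @param mean_sets_per_gene Poisson mean of per-gene category count.
#' @param seed integer seed.
#' @return tibble `category_id, description, gene_id`.
#' @export
simulate_gene_sets <- function(catalog, n_categories = 40,
                               mean_sets_per_gene = 1.2, seed = 1) {
  withr::local_seed(seed)
  cats <- sprintf("CAT%03d", seq_len(n_categories))
  k <- rpois(nrow(catalog), mean_sets_per_gene)
  genes <- rep(catalog$gene_id, k)
  tibble(
    category_id = unlist(lapply(k, function(m) sample(cats, min(m, n_categories)))),
    description = "simulated gene set",
    gene_id = genes
  )
}

#' Generate a three-line CNV panel with engineered sharing
#'
#' Each focal line receives null CNV calls of log-normal size (some below
#' the 1 kb filter, some with high multi-mapping fractions, to exercise the
#' filters). On a dedicated chromosome, `n_shared` triples of same-type
#' CNVs are engineered with pairwise reciprocal overlap `shared_frac`
#' (default 0.8, safely above the sharing rule), and `n_nonshared` 1957/1978
#' pairs with overlap `nonshared_frac` (default 0.4, below the rule) so the
#' sharing boundary is exercised in both directions.
#'
#' @param n_null null CNVs per line.
#' @param n_shared engineered shared triples.
#' @param n_nonshared engineered below-threshold pairs.
#' @param shared_frac,nonshared_frac engineered reciprocal overlaps.
#' @param seed integer seed.
#' @param lines ids of the three lines.
#' @return list with `cnvs` (named list of `vp_cnvs`), `genome_size`, and
#'   `truth` (tibble of engineered triples with their intervals).
#' @export
generate_cnv_panel <- function(n_null = 60, n_shared = 25, n_nonshared = 10,
                               shared_frac = 0.8, nonshared_frac = 0.4,
                               seed = 1,
                               lines = c("line_1957", "line_1978", "ross308")) {
  withr::local_seed(seed)
  stopifnot(length(lines) == 3)
  chrom_null <- paste0("chr", 1:5)
  chrom_len <- 2e6
  empty_set <- tibble(chrom = character(), start = integer(), end = integer(),
                      cnv_type = character(), multimap_fraction = numeric(),
                      line_id = character())
  mk_null <- function(line) {
    if (n_null == 0) return(empty_set)
    size <- pmax(200L, round(rlnorm(n_null, log(3000), 0.9)))
    start <- as.integer(floor(runif(n_null, 1, chrom_len - max(size))))
    mm <- rbeta(n_null, 1, 8)
    hi <- runif(n_null) < 0.1
    mm[hi] <- runif(sum(hi), 0.4, 0.8)
    tibble(chrom = sample(chrom_null, n_null, TRUE),
           start = start, end = start + size - 1L,
           cnv_type = sample(c("gain", "loss"), n_null, TRUE, c(0.2, 0.8)),
           multimap_fraction = mm, line_id = line)
  }
  sets <- lapply(lines, mk_null)
  names(sets) <- lines
  truth <- NULL
  if (n_shared > 0) {
    size <- round(runif(n_shared, 4000, 8000))
    shift <- round((1 - shared_frac) * size)
    base <- cumsum(rep(30000L, n_shared)) + 1L
    type <- sample(c("gain", "loss"), n_shared, TRUE)
    for (j in 1:3) {
      s <- base + (j - 1L) * shift
      sets[[lines[j]]] <- dplyr::bind_rows(sets[[lines[j]]],
        tibble(chrom = "chrE", start = as.integer(s),
               end = as.integer(s + size - 1L), cnv_type = type,
               multimap_fraction = 0.05, line_id = lines[j]))
    }
    truth <- tibble(triple = seq_len(n_shared), chrom = "chrE",
                    start = as.integer(base), size = as.integer(size),
                    cnv_type = type, overlap_frac = (size - shift) / size)
  }
  if (n_nonshared > 0) {
    size <- round(runif(n_nonshared, 4000, 8000))
    shift <- round((1 - nonshared_frac) * size)
    base <- 1e6 + cumsum(rep(30000L, n_nonshared)) + 1L
    type <- sample(c("gain", "loss"), n_nonshared, TRUE)
    for (j in 1:2) {
      s <- base + (j - 1L) * shift
      sets[[lines[j]]] <- dplyr::bind_rows(sets[[lines[j]]],
        tibble(chrom = "chrE", start = as.integer(s),
               end = as.integer(s + size - 1L), cnv_type = type,
               multimap_fraction = 0.05, line_id = lines[j]))
    }
  }
  list(cnvs = lapply(sets, cnv_table),
       genome_size = 5 * chrom_len + 2e6,
       truth = truth)
}

#' Generate per-line coverage masks and a phylogenetic SNP panel
#'
#' Builds step-function depth masks over a toy chromosome such that the
#' qualifying-region truth is known exactly by construction: in `n_good`
#' engineered intervals every line's depth clears its platform threshold;
#' in every other segment at least one line is forced at or below its
#' threshold (so strict thresholds fail there). A panel of SNPs is then
#' planted inside and outside the good intervals with presence patterns
#' that pass or fail the platform-presence rule.
#'
#' @param panel `vp_panel`.
#' @param genome_size toy chromosome length (default 10000 bp).
#' @param segment bp per depth segment (default 500).
#' @param n_good engineered qualifying intervals.
#' @param n_snps SNP panel size.
#' @param illumina_min,solid_min depth thresholds (strict).
#' @param seed integer seed.
#' @return list with `masks`, `snps` (`vp_variants`), and `truth` (list:
#'   `qualifying` intervals tibble, `snp_truth` per-SNP tibble with the
#'   expected retention flag).
#' @export
generate_coverage_masks <- function(panel = default_panel(),
                                    genome_size = 10000, segment = 500,
                                    n_good = 6, n_snps = 60,
                                    illumina_min = 10, solid_min = 5,
                                    seed = 1) {
  withr::local_seed(seed)
  breaks <- seq(1, genome_size, by = segment)
  segs <- tibble(start = as.integer(breaks),
                 end = as.integer(pmin(breaks + segment - 1, genome_size)))
  n_seg <- nrow(segs)
  good <- sort(sample.int(n_seg, min(n_good, n_seg)))
  thr <- setNames(ifelse(panel$platform == "illumina", illumina_min, solid_min),
                  panel$line_id)
  masks <- list()
  for (l in panel$line_id) {
    depth <- thr[[l]] + 1L + rpois(n_seg, 15)
    masks[[l]] <- tibble(line_id = l, chrom = "chrT",
                         start = segs$start, end = segs$end, depth = depth)
  }
  # force failure of every non-good segment in one (rotating) line
  bad <- setdiff(seq_len(n_seg), good)
  for (i in seq_along(bad)) {
    l <- panel$line_id[(i - 1) %% nrow(panel) + 1]
    masks[[l]]$depth[bad[i]] <- sample.int(thr[[l]] + 1L, 1) - 1L  # 0..thr
  }
  masks <- dplyr::bind_rows(masks)

  ill <- panel$line_id[panel$platform == "illumina"]
  sol <- panel$line_id[panel$platform == "solid"]
  pos <- sort(sample.int(genome_size, n_snps))
  in_good <- vapply(pos, function(p) {
    any(p >= segs$start[good] & p <= segs$end[good])
  }, logical(1))
  # presence patterns: random platform counts covering the rule boundary
  n_ill <- pmin(sample(0:2, n_snps, TRUE), length(ill))
  n_sol <- pmin(sample(0:3, n_snps, TRUE), length(sol))
  keep <- n_ill + n_sol > 0
  pos <- pos[keep]; in_good <- in_good[keep]
  n_ill <- n_ill[keep]; n_sol <- n_sol[keep]
  lines <- lapply(seq_along(pos), function(i) {
    c(if (n_ill[i] > 0) sample(ill, n_ill[i]) else character(0),
      if (n_sol[i] > 0) sample(sol, n_sol[i]) else character(0))
  })
  ref <- sample(c("A", "C", "G", "T"), length(pos), TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  snps <- variant_table(tibble(
    chrom = "chrT", pos = pos, ref = ref, alt = alt,
    consequence = "intergenic", sift = NA_real_,
    transcript_id = NA_character_, gene_id = NA_character_, lines = lines
  ))
  truth <- list(
    qualifying = tibble(chrom = "chrT", start = segs$start[good],
                        end = segs$end[good]),
    snp_truth = tibble(chrom = "chrT", pos = pos, in_good = in_good,
                       n_illumina = n_ill, n_solid = n_sol,
                       expect_retained = in_good & n_ill >= 1 & n_sol >= 2)
  )
  list(masks = masks, snps = snps, truth = truth)
}
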