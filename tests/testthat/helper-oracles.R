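# Independent brute-force reimplementations used as oracles.
# These deliberately avoid the package's vectorized/IRanges code paths:
# everything is plain loops and base R.

o_percentile <- function(values, q) {
  v <- sort(values)
  v[ceiling(q * length(v))]
}

# naive per-(transcript, line) metrics from a variant table
o_metrics_line <- function(variants, catalog, line, sift_cutoff = 0.05) {
  out <- data.frame(transcript_id = catalog$transcript_id,
                    n_nonsyn = 0L, n_scored = 0L, mean_sift = NA_real_,
                    n_deleterious = 0L, n_high_impact = 0L,
                    cds_length = catalog$cds_length)
  for (i in seq_len(nrow(variants))) {
    tid <- variants$transcript_id[i]
    if (is.na(tid)) next
    if (!(line %in% variants$lines[[i]])) next
    j <- which(out$transcript_id == tid)
    if (variants$consequence[i] == "nonsynonymous") {
      out$n_nonsyn[j] <- out$n_nonsyn[j] + 1L
    }
    if (!is.na(variants$sift[i])) {
      out$n_scored[j] <- out$n_scored[j] + 1L
      if (variants$sift[i] < sift_cutoff) {
        out$n_deleterious[j] <- out$n_deleterious[j] + 1L
      }
    }
    if (variants$consequence[i] %in% c("frameshift_indel", "start_loss", "stop_gain")) {
      out$n_high_impact[j] <- out$n_high_impact[j] + 1L
    }
  }
  for (j in seq_len(nrow(out))) {
    tid <- out$transcript_id[j]
    sc <- numeric(0)
    for (i in seq_len(nrow(variants))) {
      if (!is.na(variants$transcript_id[i]) && variants$transcript_id[i] == tid &&
          line %in% variants$lines[[i]] && !is.na(variants$sift[i])) {
        sc <- c(sc, variants$sift[i])
      }
    }
    if (length(sc) > 0) out$mean_sift[j] <- sum(sc) / length(sc)
  }
  out$nonsyn_density <- out$n_nonsyn / out$cds_length
  out$deleterious_density <- out$n_deleterious / out$cds_length
  out
}

o_strategy1 <- function(variants, catalog, fl, q = 0.95) {
  m <- lapply(fl, function(l) o_metrics_line(variants, catalog, l))
  d1 <- m[[2]]$nonsyn_density - m[[1]]$nonsyn_density
  d2 <- m[[3]]$nonsyn_density - m[[2]]$nonsyn_density
  elig <- d1 > 0 & d2 > 0
  if (!any(elig)) return(character(0))
  t1 <- o_percentile(d1[elig], q)
  t2 <- o_percentile(d2[elig], q)
  sort(catalog$transcript_id[elig & (d1 >= t1 | d2 >= t2)])
}

o_key <- function(variants, i) {
  paste(variants$chrom[i], variants$pos[i], variants$ref[i], variants$alt[i],
        sep = ":")
}

o_line_keys <- function(variants, line) {
  ks <- character(0)
  for (i in seq_len(nrow(variants))) {
    if (line %in% variants$lines[[i]]) ks <- c(ks, o_key(variants, i))
  }
  unique(ks)
}

o_shared_core <- function(variants, lines) {
  sets <- lapply(lines, function(l) o_line_keys(variants, l))
  Reduce(intersect, sets)
}

o_exclusive <- function(variants, targets, background) {
  tgt <- unique(unlist(lapply(targets, function(l) o_line_keys(variants, l))))
  bg <- unique(unlist(lapply(background, function(l) o_line_keys(variants, l))))
  setdiff(tgt, bg)
}

o_strategy2 <- function(variants, catalog, panel, q = 0.90) {
  fl <- c(panel$line_id[panel$role == "focal_1957"],
          panel$line_id[panel$role == "focal_1978"],
          panel$line_id[panel$role == "focal_ross308"])
  coding <- variants[variants$consequence %in% c("synonymous", "nonsynonymous") &
                       !is.na(variants$transcript_id), , drop = FALSE]
  dens <- function(targets) {
    bg <- setdiff(panel$line_id, targets)
    keys <- o_exclusive(variants, targets, bg)
    d <- numeric(nrow(catalog))
    for (j in seq_len(nrow(catalog))) {
      cnt <- 0L
      for (i in seq_len(nrow(coding))) {
        if (coding$transcript_id[i] == catalog$transcript_id[j] &&
            o_key(coding, i) %in% keys) cnt <- cnt + 1L
      }
      d[j] <- cnt / catalog$cds_length[j]
    }
    d
  }
  da <- dens(fl[2:3]); db <- dens(fl[3])
  sel <- rep(FALSE, nrow(catalog))
  if (any(da > 0)) sel <- sel | (da > 0 & da >= o_percentile(da[da > 0], q))
  if (any(db > 0)) sel <- sel | (db > 0 & db >= o_percentile(db[db > 0], q))
  sort(catalog$transcript_id[sel])
}

o_strategy3 <- function(variants, fl) {
  hits <- character(0)
  for (i in seq_len(nrow(variants))) {
    if (is.na(variants$transcript_id[i])) next
    if (!(variants$consequence[i] %in% c("frameshift_indel", "start_loss", "stop_gain"))) next
    l <- variants$lines[[i]]
    if ((fl[2] %in% l || fl[3] %in% l) && !(fl[1] %in% l)) {
      hits <- c(hits, variants$transcript_id[i])
    }
  }
  sort(unique(hits))
}

o_strategy4 <- function(variants, catalog, fl, q = 0.50) {
  m <- lapply(fl, function(l) o_metrics_line(variants, catalog, l))
  m57 <- m[[1]]$mean_sift; m78 <- m[[2]]$mean_sift; mro <- m[[3]]$mean_sift
  elig <- !is.na(m57) & !is.na(m78) & !is.na(mro)
  dec <- elig & m78 < m57 & mro < m78
  sel <- rep(FALSE, nrow(catalog))
  p78 <- m78[!is.na(m78)]; pro <- mro[!is.na(mro)]
  for (j in seq_len(nrow(catalog))) {
    if (!dec[j]) next
    ok <- FALSE
    if (length(p78) > 0 && !is.na(m78[j]) && m78[j] <= o_percentile(p78, q)) ok <- TRUE
    if (length(pro) > 0 && !is.na(mro[j]) && mro[j] <= o_percentile(pro, q)) ok <- TRUE
    sel[j] <- ok
  }
  sort(catalog$transcript_id[sel])
}

o_strategy5 <- function(variants, catalog, fl, q = 0.99) {
  m <- lapply(fl, function(l) o_metrics_line(variants, catalog, l))
  n57 <- m[[1]]$n_deleterious; n78 <- m[[2]]$n_deleterious
  nro <- m[[3]]$n_deleterious; dro <- m[[3]]$deleterious_density
  inc <- n78 >= n57 & nro >= n78 & nro > n57
  pop <- dro[nro > 0]
  if (length(pop) == 0) return(character(0))
  thr <- o_percentile(pop, q)
  sort(catalog$transcript_id[inc & nro > 0 & dro >= thr])
}

# O(n^2) CNV reciprocal-sharing check
o_cnv_shared <- function(a, b, min_frac = 0.5, reciprocal = TRUE) {
  pairs <- NULL
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j] || a$cnv_type[i] != b$cnv_type[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1
      if (ov <= 0) next
      fa <- ov / (a$end[i] - a$start[i] + 1)
      fb <- ov / (b$end[j] - b$start[j] + 1)
      hit <- if (reciprocal) fa > min_frac && fb > min_frac else
        fa > min_frac || fb > min_frac
      if (hit) pairs <- rbind(pairs, c(i, j))
    }
  }
  pairs
}

# base-by-base gene/CNV coverage
o_gene_overlap <- function(cnvs, gene_spans, min_frac = 0.5) {
  gains <- character(0); losses <- character(0)
  for (g in seq_len(nrow(gene_spans))) {
    span <- gene_spans$gene_start[g]:gene_spans$gene_end[g]
    for (type in c("gain", "loss")) {
      cc <- cnvs[cnvs$cnv_type == type & cnvs$chrom == gene_spans$chrom[g], ,
                 drop = FALSE]
      covered <- rep(FALSE, length(span))
      for (i in seq_len(nrow(cc))) {
        covered <- covered | (span >= cc$start[i] & span <= cc$end[i])
      }
      if (sum(covered) / length(span) >= min_frac) {
        if (type == "gain") gains <- c(gains, gene_spans$gene_id[g])
        else losses <- c(losses, gene_spans$gene_id[g])
      }
    }
  }
  list(gains = sort(gains), losses = sort(losses))
}

# base-by-base CNV union breadth on a toy genome (single implicit coordinate
# space; chromosomes handled by disjoint coordinate blocks in the fixtures)
o_breadth <- function(cnvs, genome_size) {
  covered <- rep(FALSE, genome_size)
  for (i in seq_len(nrow(cnvs))) {
    covered[cnvs$start[i]:min(cnvs$end[i], genome_size)] <- TRUE
  }
  sum(covered) / genome_size
}

# base-by-base qualifying regions on a toy genome
o_qualifying <- function(masks, panel, genome_size,
                         illumina_min = 10, solid_min = 5) {
  ok <- rep(TRUE, genome_size)
  for (r in seq_len(nrow(panel))) {
    l <- panel$line_id[r]
    thr <- if (panel$platform[r] == "illumina") illumina_min else solid_min
    depth <- rep(0L, genome_size)
    mm <- masks[masks$line_id == l, , drop = FALSE]
    for (i in seq_len(nrow(mm))) {
      depth[mm$start[i]:min(mm$end[i], genome_size)] <- mm$depth[i]
    }
    ok <- ok & depth > thr
  }
  which(ok)
}

o_presence <- function(snps, panel, min_illumina = 1, min_solid = 2) {
  ill <- panel$line_id[panel$platform == "illumina"]
  sol <- panel$line_id[panel$platform == "solid"]
  keep <- logical(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    l <- snps$lines[[i]]
    keep[i] <- sum(ill %in% l) >= min_illumina && sum(sol %in% l) >= min_solid
  }
  keep
}

# exact hypergeometric upper tail by enumeration
o_hyper_tail <- function(overlap, category_size, query_size, universe_size) {
  total <- 0
  for (j in seq(overlap, min(category_size, query_size))) {
    total <- total + choose(category_size, j) *
      choose(universe_size - category_size, query_size - j)
  }
  total / choose(universe_size, query_size)
}

# independent BH step-up
o_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    val <- min(prev, m * p[ord[i]] / i)
    q[ord[i]] <- min(val, 1)
    prev <- val
  }
  q
}
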