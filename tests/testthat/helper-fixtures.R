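# Fixture builders. All randomness is seeded by the caller.

mini_panel <- function() {
  line_panel(
    line_id = c("line_1957", "line_1978", "ross308", "bg_ill_1",
                "bg_sol_1", "bg_sol_2", "bg_sol_3"),
    platform = c("illumina", "illumina", "illumina", "illumina",
                 "solid", "solid", "solid"),
    role = c("focal_1957", "focal_1978", "focal_ross308",
             rep("background", 4))
  )
}

# a random annotated variant table + catalog over a small transcript set
rand_cohort <- function(seed, n_tx = 30, mean_variants = 4,
                        panel = mini_panel()) {
  withr::local_seed(seed)
  tid <- sprintf("t%03d", seq_len(n_tx))
  catalog <- tibble::tibble(
    transcript_id = tid,
    gene_id = sprintf("g%03d", seq_len(n_tx)),
    cds_length = sample(100:500, n_tx, replace = TRUE)
  )
  n_i <- rpois(n_tx, mean_variants)
  N <- sum(n_i)
  if (N == 0) n_i[1] <- N <- 1
  csq <- sample(consequence_levels()[consequence_levels() != "intergenic"],
                N, TRUE,
                prob = c(0.25, 0.35, 0.1, 0.04, 0.04, 0.06, 0.04, 0.08,
                         0.02, 0.02))
  sift <- ifelse(csq == "nonsynonymous", round(runif(N), 3), NA_real_)
  lines <- lapply(seq_len(N), function(i) {
    k <- sample(seq_len(nrow(panel)), 1)
    sample(panel$line_id, k)
  })
  variants <- variant_table(tibble::tibble(
    chrom = "chr1",
    pos = sample.int(1e6, N),
    ref = sample(c("A", "C", "G", "T"), N, TRUE),
    alt = sample(c("A", "C", "G", "T"), N, TRUE),  # ref==alt irrelevant for keys
    consequence = csq, sift = sift,
    transcript_id = rep(tid, n_i),
    gene_id = rep(catalog$gene_id, n_i),
    lines = lines
  ))
  list(variants = variants, catalog = catalog, panel = panel)
}

rand_cnv_set <- function(seed, n = 40, line = "x", coord_max = 4000) {
  withr::local_seed(seed)
  size <- sample(50:800, n, replace = TRUE)
  start <- sample.int(coord_max - max(size), n, replace = TRUE)
  cnv_table(tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = start, end = start + size - 1L,
    cnv_type = sample(c("gain", "loss"), n, TRUE),
    multimap_fraction = round(runif(n), 3),
    line_id = line
  ))
}

demo_variant_tsv <- function(path) {
  writeLines(c(
    "chrom\tpos\tref\talt\tconsequence\tsift\ttranscript_id\tgene_id\tlines_present",
    "chr1\t100\tA\tG,T\tnonsynonymous\t0.03\tt001\tg001\tline_1957;line_1978",
    "chr1\t200\tC\tT\tsynonymous\t.\tt001\tg001\tross308",
    "chr2\t300\tG\tA\tstop_gain\t.\tt002\tg002\tross308",
    "chr2\t400\tACG\tA\tframeshift_indel\t.\tt002\tg002\tline_1978;ross308",
    "chr2\t500\tT\tC\tintergenic\t.\t.\t.\tbg_sol_1"
  ), path)
  path
}

demo_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations from Ensembl VEP. Format: Allele|Consequence|SIFT|Feature|Gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "line_1957", "line_1978", "ross308", sep = "\t"),
    paste("chr1", "1000", ".", "A", "G", "50", "PASS",
          "CSQ=G|missense_variant|deleterious(0.02)|t001|g001",
          "GT", "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "2000", ".", "C", "T,G", "50", "PASS",
          paste0("CSQ=T|synonymous_variant||t001|g001,",
                 "G|stop_gained||t001|g001"),
          "GT", "0/1", "1/2", "2/2", sep = "\t"),
    paste("chr2", "3000", ".", "G", "A", "50", "PASS",
          "CSQ=A|intergenic_variant|||",
          "GT", "./.", "0/0", "0/1", sep = "\t")
  ), path)
  path
}

demo_gtf <- function(path, n_tx = 5, seed = 7) {
  withr::local_seed(seed)
  lines <- character(0)
  exon_truth <- list()
  pos <- 1000L
  for (i in seq_len(n_tx)) {
    tid <- sprintf("t%03d", i); gid <- sprintf("g%03d", i)
    n_exons <- sample(1:4, 1)
    lens <- sample(30:300, n_exons, replace = TRUE)
    for (e in seq_len(n_exons)) {
      lines <- c(lines, paste(
        "chr1", "test", "CDS", pos, pos + lens[e] - 1L, ".", "+", "0",
        sprintf('gene_id "%s"; transcript_id "%s";', gid, tid), sep = "\t"))
      pos <- pos + lens[e] + 50L
    }
    exon_truth[[tid]] <- lens
    pos <- pos + 500L
  }
  writeLines(lines, path)
  exon_truth
}

demo_gmt <- function(path) {
  writeLines(c(
    "GO:0006952\tdefense_response\tgeneA\tgeneB",
    "KEGG:04620\ttoll_like_receptor\tgeneB\tgeneC\tgeneD"
  ), path)
  path
}

demo_cnvnator <- function(path) {
  writeLines(c(
    paste("deletion", "chr2:1001-5000", "4000", "0.3", "1e-5", "1e-5",
          "1e-5", "1e-5", "0.1", sep = "\t"),
    paste("duplication", "chr1:2001-4000", "2000", "1.8", "1e-5", "1e-5",
          "1e-5", "1e-5", "0.45", sep = "\t")
  ), path)
  path
}

two_platform_panel <- function() {
  line_panel(
    line_id = c("ill_a", "ill_b", "sol_a", "sol_b"),
    platform = c("illumina", "illumina", "solid", "solid"),
    role = c("focal_1957", "focal_1978", "focal_ross308", "background")
  )
}

flat_masks <- function(panel, depth, len = 1000L) {
  dplyr::bind_rows(lapply(seq_len(nrow(panel)), function(i) {
    tibble::tibble(line_id = panel$line_id[i], chrom = "chrT",
                   start = 1L, end = len, depth = depth[i])
  }))
}

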