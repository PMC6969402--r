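test_that("depth thresholds are strict per platform", {
  panel <- two_platform_panel()
  # illumina at exactly 10 fails; solid at exactly 5 fails
  m <- flat_masks(panel, c(11L, 10L, 6L, 6L))
  expect_equal(nrow(qualifying_regions(m, panel)), 0)
  m2 <- flat_masks(panel, c(11L, 11L, 6L, 5L))
  expect_equal(nrow(qualifying_regions(m2, panel)), 0)
  m3 <- flat_masks(panel, c(11L, 11L, 6L, 6L))
  r <- qualifying_regions(m3, panel)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(1L, 1000L))
  # missing mask errors
  expect_error(qualifying_regions(m3[m3$line_id != "sol_b", ], panel),
               "sol_b")
})

test_that("qualifying regions match base-by-base evaluation on random masks", {
  panel <- two_platform_panel()
  for (seed in 1:8) {
    withr::local_seed(seed)
    genome <- 2000L
    masks <- dplyr::bind_rows(lapply(panel$line_id, function(l) {
      # random step function: segments of random depth
      brk <- sort(sample.int(genome - 1, 8))
      starts <- c(1L, brk + 1L); ends <- c(brk, genome)
      tibble::tibble(line_id = l, chrom = "chrT", start = starts, end = ends,
                     depth = sample(0:20, length(starts), TRUE))
    }))
    r <- qualifying_regions(masks, panel)
    got <- integer(0)
    for (i in seq_len(nrow(r))) got <- c(got, r$start[i]:r$end[i])
    expect_equal(got, o_qualifying(masks, panel, genome))
  }
})

test_that("relaxing a depth threshold never shrinks the qualifying regions", {
  panel <- two_platform_panel()
  withr::local_seed(33)
  masks <- dplyr::bind_rows(lapply(panel$line_id, function(l) {
    tibble::tibble(line_id = l, chrom = "chrT",
                   start = seq(1L, 901L, by = 100L),
                   end = seq(100L, 1000L, by = 100L),
                   depth = sample(0:20, 10, TRUE))
  }))
  strict <- qualifying_regions(masks, panel, illumina_min = 10, solid_min = 5)
  relaxed <- qualifying_regions(masks, panel, illumina_min = 8, solid_min = 4)
  cover <- function(r) sum(r$end - r$start + 1)
  expect_gte(cover(relaxed), cover(strict))
})

test_that("platform-presence filter needs one Illumina and two SOLiD carriers", {
  panel <- two_platform_panel()
  mk_snp <- function(pos, lines) {
    tibble::tibble(chrom = "chrT", pos = pos, ref = "A", alt = "G",
                   consequence = "intergenic", sift = NA_real_,
                   transcript_id = NA_character_, gene_id = NA_character_,
                   lines = list(lines))
  }
  snps <- variant_table(dplyr::bind_rows(
    mk_snp(10L, c("ill_a", "sol_a")),            # 1 solid: dropped
    mk_snp(20L, c("sol_a", "sol_b")),            # 0 illumina: dropped
    mk_snp(30L, c("ill_a", "sol_a", "sol_b"))    # passes
  ))
  kept <- presence_filter(snps, panel)
  expect_equal(kept$pos, 30L)
  expect_equal(o_presence(snps, panel), c(FALSE, FALSE, TRUE))
  # region restriction applies first
  regions <- tibble::tibble(chrom = "chrT", start = 100L, end = 200L)
  expect_equal(nrow(presence_filter(snps, panel, regions)), 0)
})

test_that("alignment columns carry alt for carriers and ref elsewhere", {
  panel <- two_platform_panel()
  snps <- variant_table(tibble::tibble(
    chrom = "chrT", pos = c(5L, 15L, 25L), ref = c("A", "C", "G"),
    alt = c("G", "T", "A"),
    consequence = "intergenic", sift = NA_real_,
    transcript_id = NA_character_, gene_id = NA_character_,
    lines = list(c("ill_a", "sol_a", "sol_b"),
                 c("ill_b", "sol_a", "sol_b"),
                 c("ill_a", "ill_b", "sol_a", "sol_b"))
  ))
  aln <- build_snp_alignment(snps, panel, outgroup = "rjf")
  expect_equal(dim(aln$matrix), c(5L, 3L))
  expect_equal(unname(aln$matrix["ill_a", ]), c("G", "C", "A"))
  expect_equal(unname(aln$matrix["ill_b", ]), c("A", "T", "A"))
  expect_equal(unname(aln$matrix["rjf", ]), c("A", "C", "G"))  # all-reference
  # every column is polymorphic across panel + outgroup
  expect_true(all(apply(aln$matrix, 2, function(col) length(unique(col)) > 1)))
  # site map aligns with columns
  expect_equal(aln$sites$pos, c(5L, 15L, 25L))
  # zero retained SNPs is an explicit error
  expect_error(build_snp_alignment(snps[0, ], panel), "relaxing")
})

test_that("FASTA and PHYLIP serializations decode to the same matrix", {
  panel <- two_platform_panel()
  cov <- generate_coverage_masks(panel, seed = 12, n_snps = 40)
  keep <- presence_filter(cov$snps, panel)
  aln <- build_snp_alignment(keep, panel, outgroup = "rjf")
  fa <- withr::local_tempfile(fileext = ".fasta")
  ph <- withr::local_tempfile(fileext = ".phy")
  write_alignment_fasta(aln, fa)
  write_alignment_phylip(aln, ph)
  m_fa <- read_alignment_fasta(fa)
  m_ph <- read_alignment_phylip(ph)
  expect_identical(m_fa, aln$matrix)
  expect_identical(m_ph, aln$matrix)
})
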