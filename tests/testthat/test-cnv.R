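mk_cnv <- function(start, end, type = "gain", chrom = "chr1", mm = 0.1,
                   line = "x") {
  cnv_table(tibble::tibble(chrom = chrom, start = start, end = end,
                           cnv_type = type, multimap_fraction = mm,
                           line_id = line))
}

test_that("CNV filters are strict at both boundaries and idempotent", {
  x <- cnv_table(tibble::tibble(
    chrom = "chr1", start = c(1L, 1L, 1L, 1L),
    end = c(1000L, 1001L, 1500L, 1500L),
    cnv_type = "gain",
    multimap_fraction = c(0.1, 0.1, 0.5, 0.49),
    line_id = "x"
  ))
  f <- filter_cnvs(x)
  # size 1000 dropped (needs > 1000); multimap 0.5 dropped (needs < 0.5)
  expect_equal(nrow(f), 2)
  expect_equal(f$end, c(1001L, 1500L))
  expect_identical(as.data.frame(filter_cnvs(f)), as.data.frame(f))
  x$multimap_fraction[1] <- NA
  expect_error(filter_cnvs(x), "multimap_fraction")
  # random predicate scan
  r <- rand_cnv_set(13, n = 60)
  fr <- filter_cnvs(r, min_size = 300, max_multimap = 0.5)
  keep <- r$size > 300 & r$multimap_fraction < 0.5
  expect_equal(nrow(fr), sum(keep))
})

test_that("sharing requires strict reciprocal 50% overlap and same type", {
  a <- mk_cnv(1001L, 2000L)            # 1000 bp
  b <- mk_cnv(1501L, 2500L)            # overlap 500 = exactly half
  expect_equal(nrow(shared_cnvs(a, b)), 0)
  b2 <- mk_cnv(1201L, 2200L)           # overlap 800 > half both sides
  expect_equal(nrow(shared_cnvs(a, b2)), 1)
  # gain vs loss never share
  b3 <- mk_cnv(1201L, 2200L, type = "loss")
  expect_equal(nrow(shared_cnvs(a, b3)), 0)
  # one-directional mode relaxes the rule
  big <- mk_cnv(1L, 10000L)
  expect_equal(nrow(shared_cnvs(a, big)), 0)
  expect_equal(nrow(shared_cnvs(a, big, reciprocal = FALSE)), 1)
})

test_that("pairwise sharing matches the O(n^2) oracle and is symmetric", {
  for (seed in 1:8) {
    a <- rand_cnv_set(seed, n = 30, line = "A")
    b <- rand_cnv_set(seed + 100, n = 30, line = "B")
    got <- shared_cnvs(a, b)
    want <- o_cnv_shared(a, b)
    got_pairs <- got[order(got$idx_a, got$idx_b), c("idx_a", "idx_b")]
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(as.matrix(got_pairs), want, ignore_attr = TRUE)
    }
    # symmetry
    rev <- shared_cnvs(b, a)
    expect_setequal(paste(got$idx_a, got$idx_b),
                    paste(rev$idx_b, rev$idx_a))
  }
})

test_that("three-way classification finds engineered common CNVs", {
  panel <- generate_cnv_panel(n_null = 0, n_shared = 5, n_nonshared = 3,
                              seed = 4)
  res <- three_way_shared(panel$cnvs)
  counts <- res$counts
  common <- counts[counts$class == "common_all", ]
  expect_equal(sum(common$n), 15)  # 5 triples x 3 lines
  # the non-shared engineered pairs (overlap 0.4) never class as shared
  expect_equal(sum(counts$n[grepl("shared_with", counts$class)]), 0)
  # disjoint sets are all unique
  dis <- list(
    A = mk_cnv(1L, 2000L, line = "A"),
    B = mk_cnv(10001L, 12000L, line = "B"),
    C = mk_cnv(20001L, 22000L, line = "C")
  )
  rd <- three_way_shared(dis)
  expect_true(all(rd$per_cnv$class == "unique"))
})

test_that("gene overlap uses an inclusive 50% of the gene span", {
  genes <- tibble::tibble(gene_id = c("g40", "g50", "g100"),
                          chrom = "chr1",
                          gene_start = c(1001L, 2001L, 3001L),
                          gene_end = c(2000L, 3000L, 4000L))
  cnvs <- cnv_table(tibble::tibble(
    chrom = "chr1",
    start = c(1001L, 2001L, 3001L),
    end = c(1400L, 2500L, 4000L),   # cover 40%, 50%, 100%
    cnv_type = "gain", multimap_fraction = 0.1, line_id = "x"
  ))
  ov <- cnv_gene_overlap(cnvs, genes)
  expect_false("g40" %in% ov$gains)   # 40% < half
  expect_true("g50" %in% ov$gains)    # exactly half counts (inclusive)
  expect_true("g100" %in% ov$gains)
  expect_length(ov$losses, 0)
  # union semantics: two abutting CNVs jointly cover the gene
  two <- cnv_table(tibble::tibble(
    chrom = "chr1", start = c(1001L, 1301L), end = c(1300L, 1600L),
    cnv_type = "gain", multimap_fraction = 0.1, line_id = "x"
  ))
  expect_true("g40" %in% cnv_gene_overlap(two, genes[1, ])$gains)
  # genes without spans are skipped with a warning
  gna <- genes; gna$gene_start[1] <- NA
  expect_warning(cnv_gene_overlap(cnvs, gna), "without span")
})

test_that("gene overlap matches base-by-base counting on random sets", {
  withr::local_seed(44)
  for (i in 1:6) {
    cnvs <- rand_cnv_set(i + 50, n = 25, coord_max = 3000)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:12), chrom = sample(c("chr1", "chr2"), 12, TRUE),
      gene_start = sample.int(2500, 12)
    )
    genes$gene_end <- genes$gene_start + sample(50:400, 12, TRUE)
    got <- cnv_gene_overlap(cnvs, genes)
    want <- o_gene_overlap(cnvs, genes)
    expect_equal(got$gains, want$gains)
    expect_equal(got$losses, want$losses)
  }
})

test_that("summaries report union breadth and size statistics", {
  x <- cnv_table(tibble::tibble(
    chrom = "chr1", start = c(1L, 3001L, 5001L),
    end = c(2000L, 7000L, 11000L),
    cnv_type = c("gain", "loss", "loss"),
    multimap_fraction = 0.1, line_id = "x"
  ))
  s <- summarize_cnvs(x, genome_size = 100000)
  expect_equal(s$n_cnvs, 3L)
  expect_equal(s$median_size, 4000)
  expect_equal(s$mean_size, 4000)
  expect_equal(s$n_gains, 1L); expect_equal(s$n_losses, 2L)
  # overlapping intervals counted once: union = 2000 + (3001..11000) = 10000
  expect_equal(s$breadth, 0.1)
  # fully overlapping duplicates don't inflate breadth
  dup <- cnv_table(dplyr::bind_rows(x, x))
  expect_equal(summarize_cnvs(dup, 100000)$breadth, 0.1)
  # base-by-base equivalence on random sets
  for (seed in 1:5) {
    r <- rand_cnv_set(seed + 200, n = 30, coord_max = 4000)
    r1 <- r[r$chrom == "chr1", ]
    expect_equal(summarize_cnvs(r1, 5000)$breadth, o_breadth(r1, 5000))
  }
  expect_error(summarize_cnvs(x, 0), "positive")
})
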