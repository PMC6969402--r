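test_that("metric arithmetic matches hand computations", {
  catalog <- tibble::tibble(transcript_id = "t1", gene_id = "g1",
                            cds_length = 1000L)
  v <- variant_table(tibble::tibble(
    chrom = "chr1", pos = 1:8 * 10L, ref = "A", alt = "G",
    consequence = c(rep("nonsynonymous", 5), "synonymous", "stop_gain",
                    "frameshift_indel"),
    sift = c(0.01, 0.03, 0.50, NA, NA, NA, NA, NA),
    transcript_id = "t1", gene_id = "g1",
    lines = rep(list("L1"), 8)
  ))
  m <- transcript_metrics(v, catalog, lines = "L1")
  expect_equal(m$n_nonsyn, 5L)
  expect_equal(m$nonsyn_density, 0.005)
  expect_equal(m$n_scored, 3L)
  expect_equal(m$mean_sift, 0.18)       # mean of {0.01, 0.03, 0.50}
  expect_equal(m$n_deleterious, 2L)     # 0.01 and 0.03 < 0.05
  expect_equal(m$deleterious_density, 0.002)
  expect_equal(m$n_high_impact, 2L)     # stop_gain + frameshift
  expect_equal(m$n_snps_total, 8L)
})

test_that("SIFT exactly 0.05 is tolerated (strict cutoff)", {
  catalog <- tibble::tibble(transcript_id = "t1", gene_id = "g1",
                            cds_length = 100L)
  v <- variant_table(tibble::tibble(
    chrom = "c", pos = c(1L, 2L), ref = "A", alt = "G",
    consequence = "nonsynonymous", sift = c(0.05, 0.049999),
    transcript_id = "t1", gene_id = "g1", lines = list("L1", "L1")
  ))
  m <- transcript_metrics(v, catalog, lines = "L1")
  expect_equal(m$n_deleterious, 1L)
})

test_that("transcripts without variants get explicit zero rows", {
  catalog <- tibble::tibble(transcript_id = c("t1", "t2"),
                            gene_id = c("g1", "g2"),
                            cds_length = c(100L, 200L))
  v <- variant_table(tibble::tibble(
    chrom = "c", pos = 1L, ref = "A", alt = "G",
    consequence = "nonsynonymous", sift = 0.2,
    transcript_id = "t1", gene_id = "g1", lines = list("L1")
  ))
  m <- transcript_metrics(v, catalog, lines = c("L1", "L2"))
  expect_equal(nrow(m), 4)
  t2 <- m[m$transcript_id == "t2", ]
  expect_true(all(t2$n_snps_total == 0))
  expect_true(all(is.na(t2$mean_sift)))
  expect_true(all(t2$nonsyn_density == 0))
})

test_that("unknown transcript references error with the offending ids", {
  catalog <- tibble::tibble(transcript_id = "t1", gene_id = "g1",
                            cds_length = 100L)
  v <- variant_table(tibble::tibble(
    chrom = "c", pos = 1L, ref = "A", alt = "G",
    consequence = "nonsynonymous", sift = 0.2,
    transcript_id = "tX", gene_id = "g1", lines = list("L1")
  ))
  expect_error(transcript_metrics(v, catalog), "tX")
})

test_that("metrics equal an independent per-variant recomputation", {
  for (seed in 1:6) {
    co <- rand_cohort(seed, n_tx = 20, mean_variants = 6)
    lines <- sample(co$panel$line_id, 2)
    m <- transcript_metrics(co$variants, co$catalog, lines = lines)
    for (l in lines) {
      o <- o_metrics_line(co$variants, co$catalog, l)
      got <- m[m$line_id == l, ][match(o$transcript_id,
                                       m$transcript_id[m$line_id == l]), ]
      expect_equal(got$n_nonsyn, o$n_nonsyn)
      expect_equal(got$nonsyn_density, o$nonsyn_density)
      expect_equal(got$n_scored, o$n_scored)
      expect_equal(got$mean_sift, o$mean_sift)
      expect_equal(got$n_deleterious, o$n_deleterious)
      expect_equal(got$deleterious_density, o$deleterious_density)
      expect_equal(got$n_high_impact, o$n_high_impact)
    }
  }
})

test_that("mean SIFT is invariant to variant order", {
  co <- rand_cohort(21, n_tx = 10, mean_variants = 6)
  m1 <- transcript_metrics(co$variants, co$catalog)
  shuffled <- co$variants[sample(nrow(co$variants)), ]
  m2 <- transcript_metrics(shuffled, co$catalog)
  ord <- function(x) x[order(x$transcript_id, x$line_id), ]
  expect_equal(ord(m1)$mean_sift, ord(m2)$mean_sift)
})

test_that("density deltas are elementwise differences, zeros included", {
  catalog <- tibble::tibble(transcript_id = c("t1", "t2"),
                            gene_id = c("g1", "g2"),
                            cds_length = c(1000L, 1000L))
  v <- variant_table(tibble::tibble(
    chrom = "c", pos = c(1L, 2L, 3L, 4L, 5L), ref = "A", alt = "G",
    consequence = "nonsynonymous", sift = NA_real_,
    transcript_id = c("t1", "t1", "t1", "t1", "t1"),
    gene_id = "g1",
    lines = list("early", "early", c("early", "late"), "late", "late")
  ))
  m <- transcript_metrics(v, catalog, lines = c("early", "late"))
  d <- density_delta(m, "early", "late")
  expect_equal(d$delta[d$transcript_id == "t1"], 0.003 - 0.003)
  expect_equal(d$delta[d$transcript_id == "t2"], 0)
  # random cohorts: delta equals subtraction of the oracle densities
  co <- rand_cohort(31)
  lines <- co$panel$line_id[1:2]
  m <- transcript_metrics(co$variants, co$catalog, lines = lines)
  d <- density_delta(m, lines[1], lines[2])
  o1 <- o_metrics_line(co$variants, co$catalog, lines[1])
  o2 <- o_metrics_line(co$variants, co$catalog, lines[2])
  expect_equal(d$delta[match(o1$transcript_id, d$transcript_id)],
               o2$nonsyn_density - o1$nonsyn_density)
})
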