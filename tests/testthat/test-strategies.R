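# small deterministic cohort helpers -----------------------------------------

metrics_from <- function(co) {
  transcript_metrics(co$variants, co$catalog, lines = co$panel$line_id)
}

test_that("strategy 1 requires positive changes at both epochs", {
  panel <- mini_panel()
  catalog <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                            gene_id = paste0("g", 1:3),
                            cds_length = rep(1000L, 3))
  # t1: flat then up (delta1 = 0 -> excluded); t2: up twice, huge second
  # epoch; t3: up twice, modest
  mk <- function(tid, n57, n78, nro) {
    n <- n57 + n78 + nro
    if (n == 0) return(NULL)
    tibble::tibble(
      chrom = "c", pos = seq_len(n), ref = "A", alt = "G",
      consequence = "nonsynonymous", sift = NA_real_, transcript_id = tid,
      gene_id = tid,
      lines = c(rep(list(c("line_1957", "line_1978", "ross308")), n57),
                rep(list(c("line_1978", "ross308")), n78),
                rep(list("ross308"), nro))
    )
  }
  rows <- dplyr::bind_rows(mk("t1", 2, 0, 3), mk("t2", 1, 2, 30),
                           mk("t3", 1, 2, 3))
  rows$pos <- seq_len(nrow(rows))
  rows$gene_id <- sub("t", "g", rows$transcript_id)
  v <- variant_table(rows)
  m <- transcript_metrics(v, catalog, lines = panel$line_id)
  sel <- strategy1(m, panel)
  expect_false("t1" %in% sel)  # delta1 = 0 fails positivity
  expect_true("t2" %in% sel)   # dominant second-epoch increase
})

test_that("strategy 3 fires on late-line high impact and not on shared keys", {
  panel <- mini_panel()
  v <- variant_table(tibble::tibble(
    chrom = "c", pos = c(1L, 2L), ref = "A", alt = "G",
    consequence = "stop_gain", sift = NA_real_,
    transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
    lines = list("ross308", c("line_1957", "line_1978", "ross308"))
  ))
  expect_equal(strategy3(v, panel), "t1")
})

test_that("strategy 4 requires monotone decrease plus a low-percentile line", {
  panel <- mini_panel()
  catalog <- tibble::tibble(transcript_id = paste0("t", 1:4),
                            gene_id = paste0("g", 1:4),
                            cds_length = rep(300L, 4))
  # means per line engineered through single-variant sift values
  mk <- function(tid, s57, s78, sro, posbase) {
    tibble::tibble(
      chrom = "c", pos = posbase + 1:3, ref = "A", alt = "G",
      consequence = "nonsynonymous", sift = c(s57, s78, sro),
      transcript_id = tid, gene_id = sub("t", "g", tid),
      lines = list("line_1957", "line_1978", "ross308")
    )
  }
  v <- variant_table(dplyr::bind_rows(
    mk("t1", 0.40, 0.30, 0.10, 0),    # decreasing, low late means
    mk("t2", 0.10, 0.30, 0.20, 10),   # non-monotone
    mk("t3", 0.90, 0.85, 0.80, 20),   # decreasing but high means
    mk("t4", 0.50, 0.45, 0.40, 30)
  ))
  m <- transcript_metrics(v, catalog, lines = panel$line_id)
  sel <- strategy4(m, panel)
  expect_true("t1" %in% sel)
  expect_false("t2" %in% sel)
  # t3 decreases but sits above both line medians
  expect_false("t3" %in% sel)
})

test_that("strategy 5 needs both the increase and the extreme density", {
  panel <- mini_panel()
  catalog <- tibble::tibble(transcript_id = paste0("t", 1:3),
                            gene_id = paste0("g", 1:3),
                            cds_length = c(300L, 300L, 3000L))
  mk <- function(tid, n57, n78, nro, posbase) {
    n <- n57 + n78 + nro
    tibble::tibble(
      chrom = "c", pos = posbase + seq_len(n), ref = "A", alt = "G",
      consequence = "nonsynonymous", sift = 0.01, transcript_id = tid,
      gene_id = sub("t", "g", tid),
      lines = c(rep(list(c("line_1957", "line_1978", "ross308")), n57),
                rep(list(c("line_1978", "ross308")), n78),
                rep(list("ross308"), nro))
    )
  }
  v <- variant_table(dplyr::bind_rows(
    mk("t1", 1, 2, 3, 0),     # 1 -> 3 -> 6 on a short CDS: densest
    mk("t3", 1, 2, 3, 100)    # same counts on 10x the CDS: low density
  ))
  m <- transcript_metrics(v, catalog, lines = panel$line_id)
  sel <- strategy5(m, panel)
  expect_true("t1" %in% sel)
  # t2 has zero deleterious everywhere: no increase, never selected
  expect_false("t2" %in% sel)
})

test_that("strategies match brute-force reimplementations on random cohorts", {
  fl <- c("line_1957", "line_1978", "ross308")
  for (seed in 1:10) {
    co <- rand_cohort(seed, n_tx = 25, mean_variants = 5)
    m <- metrics_from(co)
    expect_identical(strategy1(m, co$panel),
                     o_strategy1(co$variants, co$catalog, fl), info = seed)
    expect_identical(strategy2(co$variants, co$catalog, co$panel),
                     o_strategy2(co$variants, co$catalog, co$panel),
                     info = seed)
    expect_identical(strategy3(co$variants, co$panel),
                     o_strategy3(co$variants, fl), info = seed)
    expect_identical(strategy4(m, co$panel),
                     o_strategy4(co$variants, co$catalog, fl), info = seed)
    expect_identical(strategy5(m, co$panel),
                     o_strategy5(co$variants, co$catalog, fl), info = seed)
  }
})

test_that("combination filter accounts for every selected transcript once", {
  sets <- list(S1 = c("a", "b"), S2 = c("b", "c"), S3 = c("b", "d"),
               S4 = c("b"), S5 = c("b", "c"))
  pr <- prioritize(sets, letters[1:6], min_strategies = 3)
  expect_equal(pr$prioritized, "b")  # c is in only two strategies
  expect_equal(sum(pr$combinations$n),
               length(unique(unlist(sets))))  # conservation over the union
  expect_equal(pr$combinations$n[pr$combinations$combination ==
                                   "S1+S2+S3+S4+S5"], 1L)
  # a transcript in only two strategies is excluded at min 3
  expect_false("a" %in% pr$prioritized)
  # raising the threshold never enlarges the set
  for (k in 1:5) {
    pk <- prioritize(sets, letters[1:6], min_strategies = k)$prioritized
    pk1 <- prioritize(sets, letters[1:6], min_strategies = k + 1)$prioritized
    expect_true(all(pk1 %in% pk))
  }
  # min_strategies above the number of strategies gives an empty set
  expect_length(prioritize(sets, letters[1:6], min_strategies = 6)$prioritized, 0)
})

test_that("combination counts equal a brute-force subset tally on random sets", {
  withr::local_seed(99)
  for (i in 1:10) {
    universe <- sprintf("t%02d", 1:40)
    sets <- lapply(setNames(1:5, paste0("S", 1:5)), function(...) {
      sample(universe, sample(0:15, 1))
    })
    pr <- prioritize(sets, universe)
    # brute force: per transcript, its exact membership signature
    sig <- vapply(universe, function(t) {
      paste(names(sets)[vapply(sets, function(s) t %in% s, logical(1))],
            collapse = "+")
    }, character(1))
    sig <- sig[nzchar(sig)]
    tab <- sort(table(sig))
    got <- setNames(pr$combinations$n, pr$combinations$combination)
    expect_equal(sort(got)[names(tab)], as.integer(tab), ignore_attr = TRUE)
    expect_equal(sum(pr$combinations$n), length(unique(unlist(sets))))
  }
})
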