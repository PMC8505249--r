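# Promoter 2x2 construction, the exact test, and the resampling null.

test_that("fisher_2x2 reproduces hand-enumerated and reference values", {
  expect_equal(fisher_2x2(2, 2, 2, 2)$p, 1)
  expect_equal(fisher_2x2(5, 0, 0, 5)$p, 2 / 252)
  # transposition and row swap leave the exact P unchanged
  set.seed(71)
  for (i in 1:30) {
    tb <- matrix(rpois(4, 6), 2, 2)
    p <- fisher_2x2(tb)$p
    expect_equal(fisher_2x2(t(tb))$p, p)
    expect_equal(fisher_2x2(tb[2:1, ])$p, p)
    expect_equal(p, fisher.test(tb)$p.value, tolerance = 1e-10)
  }
  # degenerate margins
  dg <- fisher_2x2(0, 0, 3, 4)
  expect_true(dg$degenerate); expect_equal(dg$p, 1)
  expect_true(fisher_2x2(3, 0, 2, 0)$degenerate)
  inf <- fisher_2x2(5, 0, 2, 3)
  expect_true(inf$or_degenerate); expect_true(is.infinite(inf$odds_ratio))
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("promoter tables match a per-promoter double-loop oracle", {
  set.seed(72)
  for (rep in 1:50) {
    promoters <- data.frame(chrom = "c1",
                            start = seq(0, 1900, 100),
                            end = seq(90, 1990, 100))
    dmrs <- random_bed(sample(0:8, 1), "c1", 2000L, 150L)
    loci <- random_bed(sample(0:8, 1), "c1", 2000L, 300L)
    tab <- build_promoter_table(dmrs, loci, promoters)
    ov <- function(p, set) {
      if (!nrow(set)) return(FALSE)
      any(set$chrom == p$chrom & set$start < p$end & set$end > p$start)
    }
    a <- b <- c_ <- d <- 0
    for (i in seq_len(nrow(promoters))) {
      p <- promoters[i, ]
      dh <- ov(p, dmrs); gh <- ov(p, loci)
      if (dh && gh) a <- a + 1 else if (dh) b <- b + 1
      else if (gh) c_ <- c_ + 1 else d <- d + 1
    }
    expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(a, b, c_, d))
    expect_equal(tab$a + tab$b + tab$c + tab$d, tab$total)
  }
})

test_that("promoter table edge cases behave as stated", {
  promoters <- data.frame(chrom = "c1", start = c(0, 100), end = c(50, 150))
  none <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  tab <- build_promoter_table(none, none, promoters)
  expect_equal(c(tab$a, tab$b), c(0, 0))
  expect_equal(tab$c + tab$d, tab$total)
  whole <- data.frame(chrom = "c1", start = 0, end = 10000)
  tab2 <- build_promoter_table(data.frame(chrom = "c1", start = 0, end = 10),
                               whole, promoters)
  expect_equal(tab2$b, 0)  # every DMR promoter is jointly overlapped
  expect_error(build_promoter_table(none, none, promoters[0, ]),
               "empty promoter universe")
})

test_that("empirical enrichment handles degenerate and median cases", {
  promoters <- data.frame(chrom = "c1", start = seq(0, 990, 10),
                          end = seq(8, 998, 10))
  whole <- data.frame(chrom = "c1", start = 0, end = 1000)
  dmrs <- promoters[1:10, ]
  res <- empirical_enrichment(dmrs, whole, promoters, n_iter = 500, seed = 1)
  expect_equal(unname(res$empirical_p["enrichment"]), 1)
  expect_equal(unname(res$empirical_p["depletion"]), 1)
  # observed at the null median: both tails near 0.5
  loci <- promoters[seq(1, 100, 2), ]  # loci hit half the universe
  res2 <- empirical_enrichment(promoters[c(1, 2, 3, 4), ], loci, promoters,
                               n_iter = 2000, seed = 2)
  expect_gt(min(res2$empirical_p), 0.2)
})

test_that("the resampling null is reproducible and seed-sensitive", {
  promoters <- data.frame(chrom = "c1", start = seq(0, 990, 10),
                          end = seq(8, 998, 10))
  loci <- promoters[1:30, ]
  dmrs <- promoters[c(5, 20, 40, 60, 80), ]
  a <- empirical_enrichment(dmrs, loci, promoters, n_iter = 300, seed = 9)
  b <- empirical_enrichment(dmrs, loci, promoters, n_iter = 300, seed = 9)
  expect_identical(a$empirical_p, b$empirical_p)
  expect_identical(a$null_summary, b$null_summary)
  c_ <- empirical_enrichment(dmrs, loci, promoters, n_iter = 300, seed = 10)
  expect_false(identical(a$null_summary$counts, c_$null_summary$counts))
  # invariants of the result object
  expect_equal(sum(a$null_summary$counts), a$n_iter)
  expect_true(all(a$empirical_p > 0 & a$empirical_p <= 1))
  expect_error(empirical_enrichment(dmrs, loci, promoters, n_iter = 10),
               "seed")
})

test_that("the interval-shuffle null mode runs and respects the seed", {
  promoters <- data.frame(chrom = "c1", start = seq(0, 9900, 100),
                          end = seq(80, 9980, 100))
  loci <- promoters[1:20, ]
  dmrs <- promoters[c(2, 10, 30), ]
  cl <- data.frame(chrom = "c1", length = 10000)
  a <- empirical_enrichment(dmrs, loci, promoters, n_iter = 50, seed = 3,
                            mode = "interval_shuffle", chrom_lengths = cl)
  b <- empirical_enrichment(dmrs, loci, promoters, n_iter = 50, seed = 3,
                            mode = "interval_shuffle", chrom_lengths = cl)
  expect_identical(a$empirical_p, b$empirical_p)
  expect_error(empirical_enrichment(dmrs, loci, promoters, n_iter = 10,
                                    seed = 3, mode = "interval_shuffle"),
               "chrom_lengths")
})
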