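# Genomic-context classification, composition tests, gene-set enrichment.

test_that("CpG context follows the island/shore/shelf distance definitions", {
  islands <- data.frame(chrom = "c1", start = 10000, end = 11000)
  classify <- function(s, e)
    classify_cpg_context(data.frame(chrom = "c1", start = s, end = e),
                         islands)
  expect_equal(classify(10200, 10300), "island")
  expect_equal(classify(11500, 11600), "shore")   # within 2 kb downstream
  expect_equal(classify(8500, 8600), "shore")     # within 2 kb upstream
  expect_equal(classify(13500, 13600), "shelf")   # 2-4 kb downstream
  expect_equal(classify(6500, 6600), "shelf")     # 2-4 kb upstream
  expect_equal(classify(50000, 50100), "open_sea")
  # precedence: interval touching island and shore is an island interval
  expect_equal(classify(10900, 11500), "island")
  expect_equal(classify(12500, 13500), "shore")
})

test_that("context labels are invariant to island fragmentation", {
  set.seed(21)
  for (rep in 1:20) {
    islands <- bed_merge(random_bed(4, "c1", 40000L, 800L))
    iv <- random_bed(12, "c1", 48000L, 400L)
    whole <- classify_cpg_context(iv, islands)
    # split each island into adjacent fragments
    frags <- do.call(rbind, lapply(seq_len(nrow(islands)), function(i) {
      s <- islands$start[i]; e <- islands$end[i]
      mid <- s + max(1, (e - s) %/% 3)
      data.frame(chrom = "c1", start = c(s, mid), end = c(mid, e))
    }))
    expect_identical(classify_cpg_context(iv, frags), whole)
  }
})

test_that("gene context applies the precedence rules on 1 bp overlap", {
  gm <- data.frame(
    gene_id = "g1",
    feature = c("promoter", "five_prime_utr", "exon", "intron", "exon",
                "three_prime_utr"),
    chrom = "c1",
    start = c(0, 10000, 10200, 10500, 11000, 11500),
    end = c(10000, 10200, 10500, 11000, 11500, 12000),
    stringsAsFactors = FALSE)
  classify <- function(s, e)
    classify_gene_context(data.frame(chrom = "c1", start = s, end = e), gm)
  expect_equal(classify(9900, 10600), "promoter")   # promoter beats all
  expect_equal(classify(10300, 10400), "exon")
  expect_equal(classify(10600, 10700), "intron")
  expect_equal(classify(10400, 10600), "exon")      # exon beats intron
  expect_equal(classify(20000, 20100), "intergenic")
  expect_equal(classify(11600, 11700), "three_prime_utr")
})

test_that("malformed gene models are rejected", {
  genes <- data.frame(gene_id = "g1", start = 1000, end = 2000)
  gm <- data.frame(gene_id = "g1", feature = "exon", chrom = "c1",
                   start = 2500, end = 2600, stringsAsFactors = FALSE)
  expect_error(
    classify_gene_context(data.frame(chrom = "c1", start = 0, end = 10),
                          gm, genes = genes),
    "outside the gene span")
  gm2 <- data.frame(gene_id = "g1", feature = "enhancer", chrom = "c1",
                    start = 1100, end = 1200, stringsAsFactors = FALSE)
  expect_error(
    classify_gene_context(data.frame(chrom = "c1", start = 0, end = 10),
                          gm2),
    "unknown gene-model feature")
})

test_that("every interval gets exactly one label per context axis", {
  cfg <- small_config(seed = 31, dmr_fraction = 0.2)
  st <- simulate_study(cfg)
  dmrs <- truth_regions(st, "neuron", "dmr")
  cx <- classify_cpg_context(dmrs, st$annotation$cpg_islands)
  gx <- classify_gene_context(dmrs, st$annotation$gene_models,
                              genes = st$annotation$genes)
  expect_length(cx, nrow(dmrs)); expect_length(gx, nrow(dmrs))
  expect_true(all(cx %in% c("island", "shore", "shelf", "open_sea")))
  expect_true(all(gx %in% c("promoter", "five_prime_utr", "exon", "intron",
                            "three_prime_utr", "intergenic")))
})

test_that("context composition tests reduce to the expected Fisher results", {
  # identical composition: all P = 1
  la <- rep(c("island", "shore"), c(5, 5))
  same <- context_composition_test(la, la)
  expect_true(all(same$p == 1))
  # fully separated composition: the enumerated two-sided P
  res <- context_composition_test(rep("island", 5), rep("shore", 5))
  expect_equal(res$p[res$context == "island"], 2 / 252)
  # swapping the sets inverts odds ratios and preserves P
  lb <- rep(c("island", "shore"), c(2, 8))
  ab <- context_composition_test(la, lb)
  ba <- context_composition_test(lb, la)
  expect_equal(ab$p, ba$p)
  i <- ab$context == "island"
  expect_equal(ab$odds_ratio[i], 1 / ba$odds_ratio[i])
  expect_error(context_composition_test(character(0), la), "non-empty")
})

test_that("term enrichment matches the hypergeometric tail and partitions strata", {
  background <- sprintf("g%02d", 1:10)
  query <- c("g01", "g02", "g03")
  # a term equal to the query: P = 1 / C(10,3)
  sets <- list(hit = query, miss = c("g08", "g09", "g10"))
  res <- term_enrichment(query, background, sets)
  expect_equal(res$p[res$term == "hit"], 1 / choose(10, 3))
  expect_equal(res$p[res$term == "miss"], 1)
  # stratum partition sums to 100%
  strata <- list(neuron = c("g01", "g02"), nonneuron = c("g02", "g03"))
  res2 <- term_enrichment(query, background, sets["hit"], strata = strata)
  pct <- res2[, grep("^pct_", names(res2))]
  expect_equal(sum(unlist(pct)), 100)
  expect_equal(res2$n_common, 1)  # g02 in both strata
  expect_error(term_enrichment(c(query, "gZZ"), background, sets),
               "missing from the background: gZZ")
})

test_that("stratified results sort by ascending first-stratum percentage", {
  background <- sprintf("g%02d", 1:20)
  sets <- list(t_mostly_nonneuron = c("g03", "g04"),
               t_mostly_neuron = c("g01", "g02"))
  strata <- list(neuron = c("g01", "g02"), nonneuron = c("g03", "g04"))
  res <- term_enrichment(c("g01", "g02", "g03", "g04"), background, sets,
                         strata = strata)
  expect_equal(res$term, c("t_mostly_nonneuron", "t_mostly_neuron"))
  expect_equal(res$pct_neuron, c(0, 100))
})
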