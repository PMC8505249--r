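# Synthetic-data generator: geometry, determinism, planted-structure
# calibration, and fixture round-trips.

test_that("promoter tiles have the forced width and stay on the genome", {
  cfg <- small_config(n_genes = 40)
  ann <- generate_annotation(cfg)
  w <- ann$promoters$end - ann$promoters$start
  expect_true(all(w == 10000))
  len <- setNames(ann$chromosomes$length, ann$chromosomes$chrom)
  expect_true(all(ann$promoters$start >= 0))
  expect_true(all(ann$promoters$end <= len[ann$promoters$chrom]))
  # non-overlapping tiles: merged track has the same total width
  expect_equal(sum(bed_merge(ann$promoters)$end -
                     bed_merge(ann$promoters)$start), sum(w))
  # one tile per gene, mirrored around the TSS by strand
  expect_equal(nrow(ann$promoters), nrow(ann$genes))
  plus <- ann$genes$strand == "+"
  expect_true(all(ann$genes$tss[plus] - ann$genes$tile_start[plus] == 7500))
  expect_true(all(ann$genes$tss[!plus] - ann$genes$tile_start[!plus] == 2500))
})

test_that("annotation generation is deterministic and fails on infeasible packing", {
  cfg <- small_config(seed = 7)
  expect_identical(generate_annotation(cfg), generate_annotation(cfg))
  cfg2 <- sim_config(n_genes = 10000, chromosomes = c(chr1 = 1000000L))
  expect_error(generate_annotation(cfg2), "capacity")
})

test_that("probe layout follows the floor(width/spacing) convention", {
  cfg <- small_config(n_genes = 5)
  ann <- generate_annotation(cfg)
  lay35 <- generate_probe_layout(ann, 35)
  expect_true(all(table(lay35$promoter_id) == 285))  # floor(10000 / 35)
  lay5k <- generate_probe_layout(ann, 5000)
  expect_true(all(table(lay5k$promoter_id) == 2))
  expect_error(generate_probe_layout(ann, 10), "probe length")
  # probes sit inside their tile at the right spacing
  prom <- ann$promoters
  g <- prom$gene_id[1]
  p <- lay35[lay35$promoter_id == g, ]
  expect_true(all(diff(sort(p$start)) == 35))
  expect_true(all(p$start >= prom$start[prom$gene_id == g] &
                    p$end <= prom$end[prom$gene_id == g]))
})

test_that("planted direction mix matches the configured hypo fraction", {
  n_hypo <- 0; n_tot <- 0
  for (seed in 1:40) {
    cfg <- small_config(seed = seed, n_genes = 100,
                        chromosomes = c(chrA = 700000L, chrB = 700000L),
                        dmr_fraction = 0.2, frac_hypo = 0.9)
    ann <- generate_annotation(cfg)
    tr <- simulate_truth(ann, cfg)
    d <- tr$regions$direction[tr$regions$is_dmr]
    n_hypo <- n_hypo + sum(d == "hypo"); n_tot <- n_tot + length(d)
  }
  phat <- n_hypo / n_tot
  ci <- 1.96 * sqrt(0.9 * 0.1 / n_tot)
  expect_gt(phat, 0.9 - ci - 0.01)
  expect_lt(phat, 0.9 + ci + 0.01)
})

test_that("zero drug concordance yields no drug/disease overlap", {
  cfg <- small_config(drug_concordance = 0, drug_background_rate = 0.2)
  ann <- generate_annotation(cfg)
  tr <- simulate_truth(ann, cfg)
  dmr_genes <- unique(tr$regions$gene_id[tr$regions$is_dmr])
  expect_length(intersect(tr$drug$gene_id, dmr_genes), 0)
  dmr_bed <- tr$regions[tr$regions$is_dmr, ]
  dmr_bed <- data.frame(chrom = ann$genes$chrom[match(dmr_bed$gene_id,
                                                      ann$genes$gene_id)],
                        start = dmr_bed$dmr_start, end = dmr_bed$dmr_end)
  expect_false(any(bed_overlaps_any(tr$drug, dmr_bed)))
})

test_that("enrichment odds 1 leaves DMR status independent of GWAS loci", {
  tab <- matrix(0, 2, 2)
  for (seed in 1:60) {
    cfg <- small_config(seed = seed, gwas_enrichment_odds = 1,
                        n_gwas_loci = 15)
    ann <- generate_annotation(cfg)
    tr <- simulate_truth(ann, cfg)
    gp <- tr$gwas_promoters
    tab <- tab + table(factor(gp$is_dmr_gene, c(FALSE, TRUE)),
                       factor(gp$in_locus, c(FALSE, TRUE)))
  }
  expect_gt(suppressWarnings(chisq.test(tab, correct = FALSE))$p.value, 0.01)
})

test_that("infeasible truth configurations raise sizing errors", {
  cfg <- small_config(n_gwas_loci = 1000)
  ann <- generate_annotation(small_config())
  expect_error(simulate_truth(ann, cfg), "infeasible")
  cfg2 <- small_config(dmr_fraction = 0, drug_concordance = 0.5)
  expect_error(simulate_truth(ann, cfg2), "infeasible")
})

test_that("signal construction honours the planted means", {
  # no noise, no effect: case and control probe means identical
  cfg <- small_config(n_genes = 10, chromosomes = c(chrA = 200000L),
                      noise_sd = 0, sample_effect_sd = 0,
                      dmr_fraction = 0, drug_concordance = 0,
                      n_gwas_loci = 5, n_cases = 3, n_controls = 3)
  st <- simulate_study(cfg)
  sheet <- st$signals$sample_sheet
  case_cols <- sheet$column_id[sheet$group == "case" &
                                 sheet$cell_type == "neuron"]
  ctrl_cols <- sheet$column_id[sheet$group == "control" &
                                 sheet$cell_type == "neuron"]
  expect_equal(rowMeans(st$signals$signals[, case_cols]),
               rowMeans(st$signals$signals[, ctrl_cols]))
  # planted hypo DMR at effect 2: case - control = -2 at covered probes
  cfg2 <- small_config(n_genes = 10, chromosomes = c(chrA = 200000L),
                       noise_sd = 0, sample_effect_sd = 0,
                       dmr_fraction = 0.5, frac_hypo = 1, n_gwas_loci = 5,
                       effect_sizes = 2, n_cases = 3, n_controls = 3)
  st2 <- simulate_study(cfg2)
  sheet2 <- st2$signals$sample_sheet
  cc <- sheet2$column_id[sheet2$group == "case" & sheet2$cell_type == "neuron"]
  kk <- sheet2$column_id[sheet2$group == "control" &
                           sheet2$cell_type == "neuron"]
  diff <- rowMeans(st2$signals$signals[, cc]) -
    rowMeans(st2$signals$signals[, kk])
  tr <- st2$truth$regions[st2$truth$regions$cell_type == "neuron" &
                            st2$truth$regions$is_dmr, ]
  gi <- match(st2$layout$promoter_id, tr$gene_id)
  covered <- !is.na(gi) & st2$layout$start >= tr$dmr_start[gi] &
    st2$layout$start < tr$dmr_end[gi]
  expect_true(any(covered))
  expect_true(all(diff[covered] == -2))
  expect_true(all(diff[!covered] == 0))
})

test_that("the full generator is deterministic given the seed", {
  cfg <- small_config(seed = 42, n_genes = 20,
                      chromosomes = c(chrA = 300000L))
  expect_identical(simulate_study(cfg)$signals$signals,
                   simulate_study(cfg)$signals$signals)
})

test_that("fixtures round-trip through the writers and readers", {
  cfg <- small_config(n_genes = 20, chromosomes = c(chrA = 300000L),
                      n_cases = 3, n_controls = 3)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_fixture(st, dir)
  fx <- read_fixture(dir)
  expect_equal(fx$annotation$promoters, st$annotation$promoters)
  expect_equal(fx$annotation$genes, st$annotation$genes)
  expect_equal(fx$layout, st$layout, ignore_attr = TRUE)
  expect_equal(fx$signals$signals, st$signals$signals, tolerance = 1e-9)
  expect_equal(fx$signals$sample_sheet, st$signals$sample_sheet)
  expect_equal(fx$truth$regions, st$truth$regions)
  expect_equal(fx$truth$gwas_loci, st$truth$gwas_loci)
  # manifest records the seed; BED files are sorted
  expect_equal(as.integer(fx$manifest$seed), cfg$seed)
  isl <- read_bed(file.path(dir, "cpg_islands.bed"))
  expect_false(is.unsorted(order(isl$chrom, isl$start)))
  gmt <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_true(length(gmt) > 0)
  expect_identical(gmt, lapply(fixture_gene_sets(st), as.character)[names(gmt)])
})

test_that("CpG count tables reflect the planted truth", {
  cfg <- small_config(n_genes = 30, chromosomes = c(chrA = 400000L),
                      dmr_fraction = 0.3)
  st <- simulate_study(cfg)
  cpg <- simulate_cpg_table(st, "neuron", depth = 200, delta = 0.3)
  expect_true(all(cpg$meth_cases + cpg$unmeth_cases == 200))
  tdmr <- truth_regions(st, "neuron", "dmr")
  hypo <- tdmr[tdmr$direction == "hypo", ]
  cpg_bed <- data.frame(chrom = cpg$chrom, start = cpg$pos,
                        end = cpg$pos + 1L)
  inside <- bed_overlaps_any(cpg_bed, hypo)
  lev_diff <- cpg$meth_cases / 200 - cpg$meth_controls / 200
  expect_lt(mean(lev_diff[inside]), -0.2)
})
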