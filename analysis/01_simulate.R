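#!/usr/bin/env Rscript
# Generate the synthetic promoter-array study and write it as a plain-text
# fixture under results/fixture/. The configuration mirrors the emulated
# design (two NeuN-sorted cell fractions, duplicate experiments, planted
# hypomethylation-dominant DMRs, drug tracks with opposite-direction
# concordance, GWAS loci with planted promoter-level enrichment) at a
# desk-scale genome of 500 promoters.

library(celldmr)

cfg <- sim_config(
  n_genes = 500,
  chromosomes = c(chr1 = 3300000L, chr2 = 3300000L),
  n_cases = 12, n_controls = 12,       # scaled from the 34/35 cohort
  dmr_fraction = 0.10, frac_hypo = 0.7,
  effect_sizes = c(2, 3, 4),
  drug_concordance = 0.35, drug_flip_prob = 0.9,
  n_gwas_loci = 50, gwas_enrichment_odds = 2,
  seed = 2026)

st <- simulate_study(cfg)
dir.create("results", showWarnings = FALSE)
write_fixture(st, "results/fixture")

tr <- st$truth$regions
cat("Simulated", nrow(st$annotation$genes), "promoters,",
    nrow(st$layout), "probes,", ncol(st$signals$signals), "array columns\n")
cat("Planted DMRs per cell type:",
    paste(tapply(tr$is_dmr, tr$cell_type, sum), collapse = " / "),
    sprintf("(%.0f%% hypomethylated)",
            100 * mean(tr$direction[tr$is_dmr] == "hypo")), "\n")
cat("Fixture written to results/fixture/\n")
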