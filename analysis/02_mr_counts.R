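#!/usr/bin/env Rscript
# Call methylated regions (MRs) per sample against the whole-genome-amplified
# reference, count them, and run the sample-level statistics: Mann-Whitney
# comparisons between cell types and diagnosis groups, and Spearman
# correlations of MR counts with covariates.

library(celldmr)

fx <- read_fixture("results/fixture")
mr <- call_study_mrs(fx$signals, fx$layout)

write.table(mr$counts, "results/mr_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (key in names(mr$mrsets)) {
  df <- mr$mrsets[[key]]
  df$name <- key
  write_bed(df[, c("chrom", "start", "end", "name", "score", "n_probes")],
            file.path("results", paste0("mr_", key, ".bed")),
            "columns: chrom start end sample score n_probes")
}

stats <- mr_count_stats(mr$counts, fx$signals$covariates)
writeLines(jsonlite::toJSON(stats, digits = NA, auto_unbox = TRUE,
                            pretty = TRUE), "results/mr_stats.json")

agg <- tapply(mr$counts$n_mr, list(mr$counts$cell_type, mr$counts$group),
              mean)
cat("Mean MR counts per sample:\n"); print(round(agg, 1))
cat("\nGroup comparisons (two-sided Mann-Whitney):\n")
print(stats$comparisons[, c("comparison", "U", "p", "method")],
      row.names = FALSE)
cat("\nNote: at the default z = 2 threshold the caller is liberal, so MR",
    "counts carry a\nnoise-floor component on top of the truly methylated",
    "promoters; within-cell-type\ngroup comparisons are unaffected (same",
    "threshold behaviour in both groups), but\nbetween cell types the",
    "adaptive threshold couples to the enrichment landscape\n(see the",
    "methods vignette).\n")
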