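#!/usr/bin/env Rscript
# Characterise the DMRs: CpG-island and gene-structure context per DMR,
# Fisher tests of context composition between hyper- and hypomethylated
# sets, and gene-set enrichment over the fixture's GMT collection,
# stratified by cell type.

library(celldmr)

fx <- read_fixture("results/fixture", c("annotation", "truth"))
gene_sets <- read_gmt("results/fixture/gene_sets.gmt")

dmr <- lapply(c(neuron = "neuron", nonneuron = "nonneuron"), function(ct)
  read_bed(file.path("results", sprintf("dmr_%s.bed", ct)),
           c("chrom", "start", "end", "direction", "score_exp1",
             "score_exp2", "gene_ids")))

ann_rows <- list()
for (ct in names(dmr)) {
  d <- dmr[[ct]]
  d$cpg_context <- classify_cpg_context(d, fx$annotation$cpg_islands)
  d$gene_context <- classify_gene_context(d, fx$annotation$gene_models,
                                          genes = fx$annotation$genes)
  d$cell_type <- ct
  ann_rows[[ct]] <- d
}
lab <- do.call(rbind, ann_rows)
write.table(lab, "results/dmr_context.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("CpG context by direction (pooled cell types):\n")
print(table(lab$direction, lab$cpg_context))

comp <- context_composition_test(lab$cpg_context[lab$direction == "hyper"],
                                 lab$cpg_context[lab$direction == "hypo"])
write.table(comp, "results/context_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nHyper vs hypo context composition (Fisher, two-sided):\n")
print(comp[, c("context", "n_a", "n_b", "odds_ratio", "p", "significant")],
      row.names = FALSE)

# gene-set enrichment of all DMR-associated genes, stratified by cell type
genes_of <- function(d) {
  g <- unlist(strsplit(d$gene_ids, ","))
  sort(unique(g[nzchar(g)]))
}
strata <- lapply(dmr, genes_of)
query <- sort(unique(unlist(strata)))
background <- sort(fx$annotation$genes$gene_id)
enr <- term_enrichment(query, background, gene_sets, strata = strata)
write.table(enr, "results/term_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nTop gene-set enrichments (sorted by ascending % neuronal genes):\n")
print(head(enr[order(enr$p), c("term", "hits", "set_size", "p",
                               "pct_neuron", "pct_nonneuron",
                               "pct_common")], 8), row.names = FALSE)
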