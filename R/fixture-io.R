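# Plain-text serialization of a synthetic study: BED for interval tracks,
# TSV for matrices and tables, GMT for gene sets, and a key: value manifest.

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits the genome tables, probe layout, signal matrix, sample sheet,
#' truth tracks (DMR/HMR/drug/GWAS), CpG islands, gene sets derived from the
#' truth labels, and a manifest recording the configuration and seed.
#' Every interval file is sorted and carries a coordinate-convention header.
#'
#' @param study output of [simulate_study()]
#' @param outdir output directory (created if absent)
#' @return `outdir`, invisibly
#' @export
write_fixture <- function(study, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  ann <- study$annotation; truth <- study$truth
  p <- function(f) file.path(outdir, f)
  .write_tsv(ann$chromosomes, p("genome.tsv"))
  .write_tsv(ann$genes, p("genes.tsv"))
  .write_tsv(ann$gene_models, p("gene_models.tsv"))
  write_bed(ann$promoters, p("promoters.bed"), "columns: chrom start end gene_id")
  write_bed(ann$cpg_islands, p("cpg_islands.bed"))
  .write_tsv(study$layout, p("probe_layout.tsv"))
  for (ct in study$config$cell_types) {
    dmr <- truth_regions(study, ct, "dmr")
    dmr$score <- dmr$effect_size
    write_bed(dmr[, c("chrom", "start", "end", "direction", "score",
                      "gene_id")],
              p(sprintf("truth_dmr_%s.bed", ct)),
              "columns: chrom start end direction effect_size gene_id")
    hmr <- truth_regions(study, ct, "hmr")
    write_bed(hmr[, c("chrom", "start", "end", "gene_id")],
              p(sprintf("hmr_%s.bed", ct)),
              "columns: chrom start end gene_id")
  }
  for (cond in study$config$drug_conditions) {
    d <- truth$drug[truth$drug$condition == cond, , drop = FALSE]
    write_bed(d[, c("chrom", "start", "end", "direction", "gene_id")],
              p(sprintf("drug_%s.bed", cond)),
              "columns: chrom start end direction gene_id")
  }
  write_bed(truth$gwas_loci, p("gwas_loci.bed"),
            "columns: chrom start end locus_id")
  .write_tsv(truth$regions, p("truth_table.tsv"))
  .write_tsv(truth$drug, p("drug_truth.tsv"))
  .write_tsv(truth$gwas_promoters, p("gwas_promoters.tsv"))
  sig <- data.frame(probe_id = rownames(study$signals$signals),
                    study$signals$signals, check.names = FALSE,
                    stringsAsFactors = FALSE)
  .write_tsv(sig, p("signals.tsv"))
  .write_tsv(study$signals$sample_sheet, p("sample_sheet.tsv"))
  .write_tsv(study$signals$covariates, p("covariates.tsv"))
  write_gmt(fixture_gene_sets(study), p("gene_sets.gmt"))
  .write_manifest(study$config, study$signals$ref_columns, p("manifest.txt"))
  invisible(outdir)
}

# Gene sets built from the truth labels (DMR / HMR / drug-responsive genes
# per stratum) plus deterministic tiled background sets.
#' @rdname write_fixture
#' @export
fixture_gene_sets <- function(study) {
  truth <- study$truth
  sets <- list()
  for (ct in study$config$cell_types) {
    for (dir in c("hyper", "hypo")) {
      r <- truth$regions[truth$regions$cell_type == ct &
                           truth$regions$is_dmr &
                           !is.na(truth$regions$direction) &
                           truth$regions$direction == dir, ]
      sets[[sprintf("dmr_%s_%s", ct, dir)]] <- sort(r$gene_id)
    }
    h <- truth$regions[truth$regions$cell_type == ct & truth$regions$is_hmr, ]
    sets[[sprintf("hmr_%s", ct)]] <- sort(h$gene_id)
  }
  if (nrow(truth$drug))
    sets[["drug_responsive"]] <- sort(unique(truth$drug$gene_id))
  ids <- sort(unique(truth$regions$gene_id))
  chunk <- max(10L, length(ids) %/% 10L)
  splits <- split(ids, (seq_along(ids) - 1L) %/% chunk)
  for (i in seq_along(splits))
    sets[[sprintf("background_block_%02d", i)]] <- splits[[i]]
  Filter(length, sets)
}

.write_manifest <- function(config, ref_columns, path) {
  fmt <- function(x) paste(x, collapse = ",")
  keys <- names(config)
  lines <- c("# celldmr synthetic-study manifest",
             "# coordinates: 0-based, half-open (BED)",
             vapply(keys, function(k) {
               v <- config[[k]]
               if (is.null(v)) v <- "NULL"
               if (!is.null(names(v)) && length(names(v)) == length(v) &&
                   all(nzchar(names(v))))
                 v <- paste0(names(v), "=", v)
               paste0(k, ": ", fmt(v))
             }, character(1)),
             paste0("ref_columns: ", fmt(ref_columns)))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a study fixture written by [write_fixture()]
#'
#' @param dir fixture directory
#' @param components which parts to load; the signal matrix dominates the
#'   read time, so interval-only analyses can drop `"signals"`
#' @return list with `annotation`, `layout`, `signals`, `truth`, `manifest`
#'   (named character list), mirroring the in-memory study objects
#' @export
read_fixture <- function(dir, components = c("annotation", "layout",
                                             "signals", "truth")) {
  components <- match.arg(components, several.ok = TRUE)
  p <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("missing fixture file: ", fp, call. = FALSE)
    fp
  }
  manifest <- .read_manifest(p("manifest.txt"))
  annotation <- layout <- signals <- truth <- NULL
  if ("annotation" %in% components) {
    annotation <- list(
      chromosomes = .read_tsv(p("genome.tsv")),
      genes = .read_tsv(p("genes.tsv")),
      promoters = read_bed(p("promoters.bed"),
                           c("chrom", "start", "end", "gene_id")),
      gene_models = .read_tsv(p("gene_models.tsv")),
      cpg_islands = read_bed(p("cpg_islands.bed")))
    class(annotation) <- "celldmr_annotation"
  }
  if ("layout" %in% components) layout <- .read_tsv(p("probe_layout.tsv"))
  if ("signals" %in% components) {
    sig <- .read_tsv(p("signals.tsv"))
    m <- as.matrix(sig[, -1, drop = FALSE])
    rownames(m) <- sig$probe_id
    signals <- list(
      signals = m,
      sample_sheet = .read_tsv(p("sample_sheet.tsv")),
      covariates = .read_tsv(p("covariates.tsv")),
      ref_columns = strsplit(manifest[["ref_columns"]], ",",
                             fixed = TRUE)[[1]],
      seed = as.integer(manifest[["seed"]]))
    class(signals) <- "celldmr_signals"
  }
  if ("truth" %in% components) {
    truth <- list(
      regions = .read_tsv(p("truth_table.tsv")),
      drug = .read_tsv(p("drug_truth.tsv")),
      gwas_promoters = .read_tsv(p("gwas_promoters.tsv")),
      gwas_loci = read_bed(p("gwas_loci.bed"),
                           c("chrom", "start", "end", "locus_id")),
      seed = as.integer(manifest[["seed"]]))
    class(truth) <- "celldmr_truth"
  }
  list(annotation = annotation, layout = layout, signals = signals,
       truth = truth, manifest = manifest)
}

.read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- regmatches(lines, regexpr(": ", lines, fixed = TRUE),
                   invert = TRUE)
  out <- lapply(kv, `[`, 2)
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors
#' @param path output file
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
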