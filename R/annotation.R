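# Genomic-context classification of DMRs (CpG island / shore / shelf /
# open sea; promoter / UTR / exon / intron / intergenic), context
# composition tests, and gene-set enrichment over GMT collections.

#' Classify intervals by CpG-island context
#'
#' Labels each interval `island` if it overlaps a (merged) CpG island by at
#' least 1 bp; else `shore` if it overlaps the +/- `shore_bp` island flanks;
#' else `shelf` if it overlaps the next +/- `shelf_bp`; else `open_sea`.
#' Distances are measured from island boundaries. Precedence
#' island > shore > shelf.
#'
#' @param intervals BED-style data.frame
#' @param cpg_islands BED-style island table (merged internally)
#' @param shore_bp,shelf_bp flank widths in bp
#' @param mode overlap of the full interval (`"interval"`) or of its
#'   midpoint (`"midpoint"`)
#' @return character vector of labels along rows of `intervals`
#' @export
classify_cpg_context <- function(intervals, cpg_islands, shore_bp = 2000,
                                 shelf_bp = 2000,
                                 mode = c("interval", "midpoint")) {
  mode <- match.arg(mode)
  .assert_bed(intervals, "intervals")
  islands <- bed_merge(cpg_islands)
  if (mode == "midpoint") {
    mid <- (intervals$start + intervals$end) %/% 2
    intervals <- data.frame(chrom = intervals$chrom, start = mid,
                            end = mid + 1L, stringsAsFactors = FALSE)
  }
  flank <- function(df, inner, outer) {
    up <- data.frame(chrom = df$chrom,
                     start = pmax(0, df$start - outer),
                     end = pmax(0, df$start - inner),
                     stringsAsFactors = FALSE)
    dn <- data.frame(chrom = df$chrom, start = df$end + inner,
                     end = df$end + outer, stringsAsFactors = FALSE)
    out <- rbind(up, dn)
    out[out$end > out$start, , drop = FALSE]
  }
  shores <- .bed_setdiff(flank(islands, 0, shore_bp), islands)
  shelves <- .bed_setdiff(flank(islands, shore_bp, shore_bp + shelf_bp),
                          rbind(islands, shores))
  lab <- rep("open_sea", nrow(intervals))
  lab[bed_overlaps_any(intervals, shelves)] <- "shelf"
  lab[bed_overlaps_any(intervals, shores)] <- "shore"
  lab[bed_overlaps_any(intervals, islands)] <- "island"
  lab
}

.gene_context_precedence <- c("promoter", "five_prime_utr", "exon",
                              "intron", "three_prime_utr")

#' Classify intervals by gene-structure context
#'
#' Single label per interval by precedence promoter > 5'UTR > exon >
#' intron > 3'UTR > intergenic, on >= 1 bp overlap with the feature track.
#'
#' @param intervals BED-style data.frame
#' @param gene_models feature table (gene_id, feature, chrom, start, end)
#'   with features among promoter / five_prime_utr / exon / intron /
#'   three_prime_utr
#' @param genes optional gene table (gene_id, start, end) used to validate
#'   that non-promoter features lie within their gene span
#' @param mode see [classify_cpg_context()]
#' @return character vector of labels
#' @export
classify_gene_context <- function(intervals, gene_models, genes = NULL,
                                  mode = c("interval", "midpoint")) {
  mode <- match.arg(mode)
  .assert_bed(intervals, "intervals")
  .assert_bed(gene_models, "gene_models")
  bad_feat <- setdiff(unique(gene_models$feature), .gene_context_precedence)
  if (length(bad_feat))
    stop("unknown gene-model feature(s): ", paste(bad_feat, collapse = ", "),
         call. = FALSE)
  if (!is.null(genes)) {
    body <- gene_models[gene_models$feature != "promoter", ]
    gi <- match(body$gene_id, genes$gene_id)
    if (anyNA(gi))
      stop("gene model references unknown gene(s)", call. = FALSE)
    bad <- body$start < genes$start[gi] | body$end > genes$end[gi]
    if (any(bad))
      stop("malformed gene model: feature(s) outside the gene span for ",
           paste(unique(body$gene_id[bad]), collapse = ", "), call. = FALSE)
  }
  if (mode == "midpoint") {
    mid <- (intervals$start + intervals$end) %/% 2
    intervals <- data.frame(chrom = intervals$chrom, start = mid,
                            end = mid + 1L, stringsAsFactors = FALSE)
  }
  lab <- rep("intergenic", nrow(intervals))
  for (feat in rev(.gene_context_precedence)) {
    track <- gene_models[gene_models$feature == feat, , drop = FALSE]
    if (nrow(track)) lab[bed_overlaps_any(intervals, track)] <- feat
  }
  lab
}

#' Fisher tests of context composition between two DMR sets
#'
#' For each context label, a 2x2 table of (in-context vs not) x (set A vs
#' set B) is tested two-sided with [fisher_2x2()]. No multiplicity
#' correction by default; Benjamini-Hochberg available.
#'
#' @param labels_a,labels_b context label vectors of the two sets
#' @param alpha significance flag threshold
#' @param p_adjust "none" or "BH"
#' @return data.frame per context: counts, odds ratio, P, significance flag
#' @export
context_composition_test <- function(labels_a, labels_b, alpha = 0.05,
                                     p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!length(labels_a) || !length(labels_b))
    stop("both DMR sets must be non-empty", call. = FALSE)
  contexts <- sort(unique(c(labels_a, labels_b)))
  rows <- lapply(contexts, function(cx) {
    a <- sum(labels_a == cx); b <- sum(labels_a != cx)
    c_ <- sum(labels_b == cx); d <- sum(labels_b != cx)
    ft <- fisher_2x2(a, b, c_, d)
    data.frame(context = cx, n_a = a, n_b = c_,
               total_a = length(labels_a), total_b = length(labels_b),
               odds_ratio = ft$odds_ratio, p = ft$p,
               degenerate = ft$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (p_adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$p_adjust <- p_adjust
  out$significant <- out$p_adj < alpha
  out
}

#' Gene-set (GO-style) enrichment by one-sided Fisher test
#'
#' One-sided hypergeometric enrichment of the query genes in each gene set,
#' after intersecting sets with the background. When `strata` is given
#' (named list of gene vectors partitioning the query by, e.g., cell type),
#' each term's query hits are partitioned into stratum-exclusive and
#' `common` genes with percentages, and results are sorted by ascending
#' percentage of the first stratum.
#'
#' @param query_genes character vector (must be a subset of the background)
#' @param background_genes character vector
#' @param gene_sets named list of character vectors (see [read_gmt()])
#' @param strata optional named list of gene vectors
#' @param min_set_size smallest post-intersection set tested
#' @return data.frame of per-term results
#' @export
term_enrichment <- function(query_genes, background_genes, gene_sets,
                            strata = NULL, min_set_size = 1L) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  offenders <- setdiff(query_genes, background_genes)
  if (length(offenders))
    stop("query genes missing from the background: ",
         paste(head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ..." else "", call. = FALSE)
  N <- length(background_genes)
  q <- length(query_genes)
  rows <- list()
  for (term in names(gene_sets)) {
    set <- intersect(unique(gene_sets[[term]]), background_genes)
    if (length(set) < min_set_size) next
    hit_genes <- intersect(set, query_genes)
    h <- length(hit_genes)
    p <- .hyper_enrichment_p(h, length(set), N, q)
    or <- (h * (N - length(set) - q + h)) /
      ((length(set) - h) * (q - h))
    row <- data.frame(term = term, hits = h, set_size = length(set),
                      query_size = q, background_size = N,
                      odds_ratio = or, p = p,
                      member_genes = paste(sort(hit_genes), collapse = ","),
                      stringsAsFactors = FALSE)
    if (!is.null(strata)) {
      part <- .partition_by_strata(hit_genes, strata)
      for (nm in names(part$counts)) {
        row[[paste0("n_", nm)]] <- part$counts[[nm]]
        row[[paste0("pct_", nm)]] <- part$pct[[nm]]
      }
    }
    rows[[term]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  rownames(out) <- NULL
  if (!is.null(strata)) {
    key <- paste0("pct_", names(strata)[1])
    out <- out[order(out[[key]], out$term), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Partition hit genes into stratum-exclusive classes plus "common" (genes in
# more than one stratum); percentages over all hits sum to 100.
.partition_by_strata <- function(hit_genes, strata) {
  member <- vapply(strata, function(s) hit_genes %in% s, logical(length(hit_genes)))
  if (length(hit_genes) == 1L) member <- matrix(member, nrow = 1)
  if (length(hit_genes) == 0L)
    member <- matrix(logical(0), ncol = length(strata))
  n_in <- rowSums(member)
  classes <- c(names(strata), "common", "unassigned")
  counts <- setNames(vector("list", length(classes)), classes)
  for (i in seq_along(strata))
    counts[[names(strata)[i]]] <- sum(member[, i] & n_in == 1)
  counts[["common"]] <- sum(n_in > 1)
  counts[["unassigned"]] <- sum(n_in == 0)
  tot <- length(hit_genes)
  pct <- lapply(counts, function(k) if (tot) 100 * k / tot else NA_real_)
  list(counts = counts, pct = pct)
}
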