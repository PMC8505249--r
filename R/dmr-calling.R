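# Differential methylation: per-replicate candidate DMRs from a per-probe
# Welch t statistic on window scores, replicate intersection with direction
# checking, and gene association.

.row_welch_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se <- sqrt(va / na + vb / nb)
  t <- (ma - mb) / se
  t[se == 0] <- 0
  t
}

#' Call candidate DMRs for one cell type and replicate experiment
#'
#' Per probe, window scores (sample minus reference, smoothed) are computed
#' for every sample of the given cell type and replicate; a Welch t
#' statistic compares cases against controls; probes with |t| >= `t_threshold`
#' are merged into regions with the same run/gap/min-probe logic as
#' [call_mrs()]. A region is labeled `hyper` if the patient mean exceeds the
#' control mean over its probes, else `hypo`; its score is the mean probe t.
#'
#' @param signals a `celldmr_signals`
#' @param layout probe layout
#' @param cell_type cell-type label
#' @param replicate replicate experiment (1 or 2)
#' @param t_threshold absolute Welch-t threshold per probe
#' @param min_probes,max_gap region merging parameters
#' @param bandwidth,trim window parameters
#' @return data.frame chrom, start, end, direction, score, n_probes with
#'   attributes `cell_type` and `replicate`
#' @export
call_candidate_dmrs <- function(signals, layout, cell_type, replicate,
                                t_threshold = 3, min_probes = 4L,
                                max_gap = 110L, bandwidth = 300, trim = 0.1) {
  sheet <- signals$sample_sheet
  sub <- sheet[sheet$cell_type == cell_type & sheet$replicate == replicate, ]
  case_cols <- sub$column_id[sub$group == "case"]
  ctrl_cols <- sub$column_id[sub$group == "control"]
  if (length(case_cols) < 3 || length(ctrl_cols) < 3)
    stop("need >= 3 samples per group for cell type '", cell_type,
         "', replicate ", replicate, " (have ", length(case_cols), " cases, ",
         length(ctrl_cols), " controls)", call. = FALSE)
  ref <- rowMeans(signals$signals[, signals$ref_columns, drop = FALSE])
  diff <- signals$signals[, c(case_cols, ctrl_cols), drop = FALSE] - ref
  ws <- window_scores(diff, layout, bandwidth = bandwidth, trim = trim)
  # median-centre each sample's scores: a per-sample global offset (array
  # intensity / enrichment efficiency) must not masquerade as a group
  # difference in the probe-wise t statistic
  ws <- sweep(ws, 2, apply(ws, 2, stats::median))
  t <- .row_welch_t(ws[, case_cols, drop = FALSE],
                    ws[, ctrl_cols, drop = FALSE])
  runs <- .threshold_runs(abs(t) >= t_threshold, layout, min_probes, max_gap)
  if (!length(runs)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      score = numeric(0), n_probes = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    score <- vapply(runs, function(g) mean(t[g]), numeric(1))
    out <- data.frame(
      chrom = vapply(runs, function(g) layout$chrom[g[1]], character(1)),
      start = vapply(runs, function(g) layout$start[g[1]], numeric(1)),
      end = vapply(runs, function(g) layout$end[g[length(g)]], numeric(1)),
      direction = ifelse(score > 0, "hyper", "hypo"),
      score = score,
      n_probes = vapply(runs, length, integer(1)),
      stringsAsFactors = FALSE)
    out <- bed_sort(out)
  }
  attr(out, "cell_type") <- cell_type
  attr(out, "replicate") <- replicate
  out
}

#' Intersect candidate DMRs from the two replicate experiments
#'
#' Output regions are the base-pair intersections of overlapping
#' same-direction candidate pairs, merged within direction; overlaps between
#' opposite-direction candidates are dropped and counted in the
#' `n_discordant` attribute.
#'
#' @param dmrs_exp1,dmrs_exp2 candidate sets from [call_candidate_dmrs()]
#'   (same cell type)
#' @return data.frame chrom, start, end, direction, score_exp1, score_exp2
#'   with attributes `cell_type` and `n_discordant`
#' @export
intersect_replicates <- function(dmrs_exp1, dmrs_exp2) {
  ct1 <- attr(dmrs_exp1, "cell_type"); ct2 <- attr(dmrs_exp2, "cell_type")
  if (!is.null(ct1) && !is.null(ct2) && !identical(ct1, ct2))
    stop("cell-type mismatch: '", ct1, "' vs '", ct2, "'", call. = FALSE)
  n_discordant <- 0L
  for (d in c("hyper", "hypo")) {
    opp <- setdiff(c("hyper", "hypo"), d)
    px <- .bed_intersect_pairs(
      dmrs_exp1[dmrs_exp1$direction == d, , drop = FALSE],
      dmrs_exp2[dmrs_exp2$direction == opp, , drop = FALSE])
    n_discordant <- n_discordant + nrow(px)
  }
  if (n_discordant)
    message(n_discordant,
            " discordant-direction replicate overlap(s) dropped")
  pieces <- list()
  for (d in c("hyper", "hypo")) {
    a <- dmrs_exp1[dmrs_exp1$direction == d, , drop = FALSE]
    b <- dmrs_exp2[dmrs_exp2$direction == d, , drop = FALSE]
    px <- .bed_intersect_pairs(a, b)
    if (!nrow(px)) next
    px$direction <- d
    px$score_exp1 <- a$score[px$idx_a]
    px$score_exp2 <- b$score[px$idx_b]
    merged <- bed_merge(px)
    hit <- .bed_intersect_pairs(merged, px)
    merged$direction <- d
    merged$score_exp1 <- vapply(seq_len(nrow(merged)), function(i)
      mean(px$score_exp1[hit$idx_b[hit$idx_a == i]]), numeric(1))
    merged$score_exp2 <- vapply(seq_len(nrow(merged)), function(i)
      mean(px$score_exp2[hit$idx_b[hit$idx_a == i]]), numeric(1))
    pieces[[d]] <- merged
  }
  out <- if (length(pieces)) bed_sort(do.call(rbind, pieces)) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               direction = character(0), score_exp1 = numeric(0),
               score_exp2 = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cell_type") <- ct1
  attr(out, "n_discordant") <- n_discordant
  out
}

#' Associate DMRs with genes by promoter-tile overlap
#'
#' A DMR is associated with every gene whose promoter tile it overlaps by at
#' least 1 bp. Gene identifiers are attached comma-separated per DMR and the
#' distinct associated genes are returned.
#'
#' @param dmrs BED-style DMR table
#' @param annotation a `celldmr_annotation` (or any list with a `promoters`
#'   table carrying chrom/start/end/gene_id)
#' @return `dmrs` with a `gene_ids` column plus attribute `genes`
#'   (character vector of associated genes)
#' @export
associate_genes <- function(dmrs, annotation) {
  prom <- annotation$promoters
  hits <- .bed_intersect_pairs(dmrs, prom)
  gene_ids <- vapply(seq_len(nrow(dmrs)), function(i) {
    g <- prom$gene_id[hits$idx_b[hits$idx_a == i]]
    paste(sort(unique(g)), collapse = ",")
  }, character(1))
  dmrs$gene_ids <- gene_ids
  attr(dmrs, "genes") <- sort(unique(prom$gene_id[hits$idx_b]))
  dmrs
}

#' Pairwise overlap summary of gene sets
#'
#' Overlap percentage uses the smaller set as denominator (recorded in the
#' `denominator` column); Venn counts are emitted per pair.
#'
#' @param sets named list of character vectors
#' @return data.frame with one row per unordered pair
#' @export
gene_overlap_summary <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  nms <- names(sets)
  rows <- list()
  for (i in seq_len(length(sets) - 1)) {
    for (j in seq((i + 1), length(sets))) {
      a <- unique(sets[[i]]); b <- unique(sets[[j]])
      common <- length(intersect(a, b))
      denom <- min(length(a), length(b))
      rows[[length(rows) + 1L]] <- data.frame(
        set_a = nms[i], set_b = nms[j], n_a = length(a), n_b = length(b),
        n_only_a = length(a) - common, n_only_b = length(b) - common,
        n_common = common,
        overlap_pct = if (denom > 0) 100 * common / denom else NA_real_,
        denominator = "smaller_set", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Replicate-intersected DMRs per cell type, with gene association
#'
#' @param signals a `celldmr_signals`
#' @param layout probe layout
#' @param annotation a `celldmr_annotation`
#' @param cell_types cell types to process (default: all in the sheet)
#' @param ... parameters passed to [call_candidate_dmrs()]
#' @return named list per cell type: `candidates` (list of the two
#'   per-replicate sets) and `dmrs` (intersected, gene-associated)
#' @export
call_study_dmrs <- function(signals, layout, annotation,
                            cell_types = NULL, ...) {
  sheet <- signals$sample_sheet
  if (is.null(cell_types)) cell_types <- unique(sheet$cell_type)
  out <- list()
  for (ct in cell_types) {
    reps <- sort(unique(sheet$replicate[sheet$cell_type == ct]))
    cand <- lapply(reps[1:2], function(r)
      call_candidate_dmrs(signals, layout, ct, r, ...))
    dmrs <- intersect_replicates(cand[[1]], cand[[2]])
    dmrs <- associate_genes(dmrs, annotation)
    out[[ct]] <- list(candidates = cand, dmrs = dmrs)
  }
  out
}
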