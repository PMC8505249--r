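# Methylated-region (MR) calling: per-probe sliding-window scores of sample
# minus whole-genome-amplified reference, thresholding into regions, and the
# sample-level MR-count statistics.

# Window index bounds per probe: probes within +/- bandwidth bp of the probe
# start, restricted to the same promoter tile. Layout rows must be sorted by
# (chrom, start); within a tile probes are then position-ordered.
.window_bounds <- function(layout, bandwidth) {
  P <- nrow(layout)
  lo <- integer(P); hi <- integer(P)
  idx_by_tile <- split(seq_len(P), layout$promoter_id)
  for (idx in idx_by_tile) {
    pos <- layout$start[idx]
    lo[idx] <- idx[findInterval(pos - bandwidth - 0.5, pos) + 1L]
    hi[idx] <- idx[findInterval(pos + bandwidth + 0.5, pos)]
  }
  list(lo = lo, hi = hi)
}

#' Sliding-window trimmed-mean scores for a matrix of probe values
#'
#' For each probe, the trimmed mean of the values at probes whose start lies
#' within `bandwidth` bp of the probe's start on the same promoter tile
#' (windows truncate at tile edges).
#'
#' @param values numeric matrix (probes x columns) or vector, rows aligned
#'   with `layout`
#' @param layout probe layout ([generate_probe_layout()]), sorted by
#'   (chrom, start)
#' @param bandwidth window half-width in bp
#' @param trim fraction trimmed from each tail of the window
#' @return matrix (or vector) of window scores, same shape as `values`
#' @export
window_scores <- function(values, layout, bandwidth = 300, trim = 0.1) {
  vec <- is.null(dim(values))
  if (vec) values <- matrix(values, ncol = 1)
  if (nrow(values) != nrow(layout))
    stop("values rows must align with the probe layout", call. = FALSE)
  if (bandwidth < 0) stop("bandwidth must be >= 0", call. = FALSE)
  if (!nrow(layout)) stop("empty probe layout", call. = FALSE)
  wb <- .window_bounds(layout, bandwidth)
  out <- .window_trimmed_mean_cpp(values, wb$lo, wb$hi, trim)
  dimnames(out) <- dimnames(values)
  if (vec) out[, 1] else out
}

#' Per-probe window scores for one sample versus the reference
#'
#' The sample's replicate experiment columns are averaged against the mean
#' of the reference (whole-genome-amplified) columns probe-wise, and the
#' difference is smoothed with [window_scores()].
#'
#' @param signals a `celldmr_signals` object
#' @param layout probe layout
#' @param sample_id sample identifier in the sample sheet
#' @param cell_type cell-type label
#' @param bandwidth,trim see [window_scores()]
#' @return numeric vector of per-probe window scores
#' @export
score_windows <- function(signals, layout, sample_id, cell_type,
                          bandwidth = 300, trim = 0.1) {
  sheet <- signals$sample_sheet
  cols <- sheet$column_id[sheet$sample_id == sample_id &
                            sheet$cell_type == cell_type]
  if (!length(cols))
    stop("unknown sample/cell type: ", sample_id, " / ", cell_type,
         call. = FALSE)
  diff <- rowMeans(signals$signals[, cols, drop = FALSE]) -
    rowMeans(signals$signals[, signals$ref_columns, drop = FALSE])
  window_scores(diff, layout, bandwidth = bandwidth, trim = trim)
}

# Run/gap/min-probe merging shared by MR and candidate-DMR calling.
# above: logical per probe; gaps measured as start[next] - end[prev] between
# consecutive selected probes on the same tile. Returns a list of integer
# index vectors (the selected probes of each retained run).
.threshold_runs <- function(above, layout, min_probes, max_gap) {
  runs <- list()
  idx_by_tile <- split(seq_len(nrow(layout)), layout$promoter_id)
  for (idx in idx_by_tile) {
    sel <- idx[above[idx]]
    if (!length(sel)) next
    if (length(sel) == 1L) {
      grp <- 0L
    } else {
      gap <- layout$start[sel[-1]] - layout$end[sel[-length(sel)]]
      grp <- cumsum(c(0L, as.integer(gap > max_gap)))
    }
    for (g in split(sel, grp))
      if (length(g) >= min_probes) runs[[length(runs) + 1L]] <- g
  }
  runs
}

#' Call methylated regions from per-probe window scores
#'
#' Maximal runs of probes with score >= `threshold`, allowing sub-threshold
#' gaps of at most `max_gap` bp (measured between the end of one selected
#' probe and the start of the next), are merged into regions spanning the
#' first probe's start to the last probe's end; runs with fewer than
#' `min_probes` selected probes are discarded.
#'
#' @param scores per-probe window scores aligned with `layout`
#' @param layout probe layout
#' @param threshold score threshold (see [mr_threshold()] for the z-score
#'   default used by the pipeline)
#' @param min_probes minimum selected probes per region
#' @param max_gap maximum sub-threshold gap in bp
#' @return data.frame with chrom, start, end, score (mean window score of
#'   the selected probes), n_probes
#' @export
call_mrs <- function(scores, layout, threshold, min_probes = 4L,
                     max_gap = 110L) {
  stopifnot(length(scores) == nrow(layout))
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (min_probes < 1L) stop("min_probes must be >= 1", call. = FALSE)
  if (max_gap < 0L) stop("max_gap must be >= 0", call. = FALSE)
  runs <- .threshold_runs(scores >= threshold, layout, min_probes, max_gap)
  if (!length(runs))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      n_probes = integer(0), stringsAsFactors = FALSE))
  out <- data.frame(
    chrom = vapply(runs, function(g) layout$chrom[g[1]], character(1)),
    start = vapply(runs, function(g) layout$start[g[1]], numeric(1)),
    end = vapply(runs, function(g) layout$end[g[length(g)]], numeric(1)),
    score = vapply(runs, function(g) mean(scores[g]), numeric(1)),
    n_probes = vapply(runs, length, integer(1)),
    stringsAsFactors = FALSE)
  bed_sort(out)
}

#' Score threshold as a z-score of the per-sample score distribution
#'
#' By default the centre and spread are estimated robustly (median and MAD),
#' so the threshold is anchored to the unmethylated bulk of the zero-inflated
#' enrichment-score distribution rather than pulled upwards by the
#' methylated mode; `robust = FALSE` gives the plain mean + z * SD rule.
#'
#' @param scores per-probe window scores for one sample
#' @param z number of (robust) SDs above the centre
#' @param robust use median/MAD instead of mean/SD
#' @return numeric threshold
#' @export
mr_threshold <- function(scores, z = 2, robust = TRUE) {
  if (robust) median(scores) + z * stats::mad(scores)
  else mean(scores) + z * sd(scores)
}

#' Call MRs for every (sample, cell type) in a study
#'
#' @param signals a `celldmr_signals`
#' @param layout probe layout
#' @param bandwidth,trim window parameters ([window_scores()])
#' @param z per-sample z-score threshold ([mr_threshold()])
#' @param min_probes,max_gap region merging parameters ([call_mrs()])
#' @return list with `mrsets` (named list of MR data.frames, names
#'   "sample.celltype") and `counts` (sample_id, cell_type, group, n_mr)
#' @export
call_study_mrs <- function(signals, layout, bandwidth = 300, z = 2,
                           min_probes = 4L, max_gap = 110L, trim = 0.1) {
  sheet <- signals$sample_sheet
  ref <- rowMeans(signals$signals[, signals$ref_columns, drop = FALSE])
  mrsets <- list()
  counts <- list()
  for (ct in unique(sheet$cell_type)) {
    sub <- sheet[sheet$cell_type == ct, ]
    ids <- unique(sub$sample_id)
    diff <- vapply(ids, function(sid) {
      cols <- sub$column_id[sub$sample_id == sid]
      rowMeans(signals$signals[, cols, drop = FALSE]) - ref
    }, numeric(nrow(layout)))
    ws <- window_scores(diff, layout, bandwidth = bandwidth, trim = trim)
    for (sid in ids) {
      s <- ws[, sid]
      mrs <- call_mrs(s, layout, mr_threshold(s, z), min_probes, max_gap)
      key <- paste(sid, ct, sep = ".")
      mrsets[[key]] <- mrs
      counts[[key]] <- data.frame(
        sample_id = sid, cell_type = ct,
        group = sub$group[match(sid, sub$sample_id)],
        n_mr = nrow(mrs), stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  list(mrsets = mrsets, counts = counts)
}

#' Mann-Whitney U test (exact permutation for small samples)
#'
#' Exact conditional permutation distribution of U (all rank splits, ties
#' kept) when the combined sample size is at most `exact_max`; otherwise the
#' normal approximation with tie correction and continuity correction.
#' Two-sided P by doubling the smaller tail, capped at 1.
#'
#' @param x,y numeric vectors
#' @param exact_max largest combined n for the exact branch
#' @param exact force (TRUE/FALSE) or choose automatically (NA)
#' @return list with `U`, `p`, `method`, `degenerate`
#' @export
mann_whitney <- function(x, y, exact_max = 12L, exact = NA) {
  m <- length(x); n <- length(y)
  stopifnot(m >= 1, n >= 1)
  comb <- c(x, y)
  r <- rank(comb)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (all(comb == comb[1]))
    return(list(U = m * n / 2, p = 1, method = "degenerate",
                degenerate = TRUE))
  if (is.na(exact)) exact <- (m + n) <= exact_max
  if (exact) {
    splits <- combn(m + n, m)
    u_null <- colSums(matrix(r[splits], nrow = m)) - m * (m + 1) / 2
    p_lo <- mean(u_null <= U); p_hi <- mean(u_null >= U)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    N <- m + n
    ties <- table(comb)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    mu <- m * n / 2
    if (sigma2 <= 0)
      return(list(U = U, p = 1, method = "degenerate", degenerate = TRUE))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(U = U, p = p, method = method, degenerate = FALSE)
}

#' Sample-level MR-count statistics
#'
#' The study's group comparisons of per-sample MR counts (neurons vs
#' nonneurons within each group; cases vs controls within each cell type)
#' by the Mann-Whitney test, and Spearman correlations of MR counts with
#' covariates per cell type.
#'
#' @param counts counts table from [call_study_mrs()]
#' @param covariates per-subject covariate table (`sample_id` plus numeric
#'   columns); covariates that are NA for a subject are dropped pairwise
#' @return list with `comparisons` (data.frame) and `covariate_cor`
#'   (data.frame with rho and P per cell type x covariate)
#' @export
mr_count_stats <- function(counts, covariates = NULL) {
  get_counts <- function(ct, grp)
    counts$n_mr[counts$cell_type == ct & counts$group == grp]
  cts <- unique(counts$cell_type)
  grps <- unique(counts$group)
  comp <- list()
  if (length(cts) == 2) {
    for (grp in grps) {
      a <- get_counts(cts[1], grp); b <- get_counts(cts[2], grp)
      if (length(a) >= 2 && length(b) >= 2) {
        mw <- mann_whitney(a, b)
        comp[[length(comp) + 1L]] <- data.frame(
          comparison = sprintf("%s_vs_%s_within_%s", cts[1], cts[2], grp),
          group_a = cts[1], group_b = cts[2], n_a = length(a),
          n_b = length(b), U = mw$U, p = mw$p, method = mw$method,
          sidedness = "two-sided", degenerate = mw$degenerate,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (all(c("case", "control") %in% grps)) {
    for (ct in cts) {
      a <- get_counts(ct, "case"); b <- get_counts(ct, "control")
      if (length(a) >= 2 && length(b) >= 2) {
        mw <- mann_whitney(a, b)
        comp[[length(comp) + 1L]] <- data.frame(
          comparison = sprintf("case_vs_control_within_%s", ct),
          group_a = "case", group_b = "control", n_a = length(a),
          n_b = length(b), U = mw$U, p = mw$p, method = mw$method,
          sidedness = "two-sided", degenerate = mw$degenerate,
          stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else
    data.frame(comparison = character(0))
  covariate_cor <- NULL
  if (!is.null(covariates)) {
    cov_cols <- setdiff(names(covariates),
                        c("sample_id", "group"))
    cov_cols <- cov_cols[vapply(covariates[cov_cols], is.numeric,
                                logical(1))]
    rows <- list()
    for (ct in cts) {
      sub <- counts[counts$cell_type == ct, ]
      cv <- covariates[match(sub$sample_id, covariates$sample_id), ]
      for (cc in cov_cols) {
        ok <- !is.na(cv[[cc]])
        if (sum(ok) < 3) next
        sp <- spearman_cor(sub$n_mr[ok], cv[[cc]][ok])
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = ct, covariate = cc, n = sum(ok), rho = sp$rho,
          p = sp$p, stringsAsFactors = FALSE)
      }
    }
    covariate_cor <- if (length(rows)) do.call(rbind, rows) else
      data.frame(cell_type = character(0))
  }
  list(comparisons = comparisons, covariate_cor = covariate_cor)
}

#' Spearman rank correlation (average ranks for ties)
#' @param x,y numeric vectors of equal length
#' @return list with `rho` and `p` (two-sided, t approximation; clamped to
#'   the open unit interval)
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate),
       p = min(1, max(ct$p.value, .Machine$double.xmin)))
}
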