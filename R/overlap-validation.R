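# Overlap of DMRs with auxiliary interval tracks (drug-induced DMRs, HMRs),
# directional concordance testing, and per-CpG validation against bisulfite
# count tables.

#' Fraction of DMRs overlapping an auxiliary track
#'
#' A DMR counts as overlapped on >= 1 bp intersection. With a named list of
#' per-condition tracks, `any_condition` mode takes the union of the
#' condition tracks first; `per_condition` reports each condition.
#'
#' @param dmrs BED-style DMR table (non-empty)
#' @param track BED-style table, or a named list of them (one per condition)
#' @param mode `"any_condition"` or `"per_condition"`
#' @return list with `percent` (named numeric), `flags` (logical data.frame,
#'   one column per reported track, rows along `dmrs`), `n_dmrs`
#' @export
overlap_fraction <- function(dmrs, track,
                             mode = c("any_condition", "per_condition")) {
  mode <- match.arg(mode)
  .assert_bed(dmrs, "dmrs")
  if (!nrow(dmrs))
    stop("empty DMR set: overlap percentage undefined", call. = FALSE)
  tracks <- if (is.data.frame(track)) list(track = track) else track
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (mode == "any_condition") {
    u <- bed_merge(do.call(rbind, lapply(tracks, function(t)
      t[, c("chrom", "start", "end")])))
    tracks <- list(any_condition = u)
  }
  flags <- as.data.frame(lapply(tracks, function(t)
    bed_overlaps_any(dmrs, t)), optional = TRUE)
  names(flags) <- names(tracks)
  percent <- vapply(flags, function(f) 100 * mean(f), numeric(1))
  list(percent = percent, flags = flags, n_dmrs = nrow(dmrs))
}

#' Directional concordance between disease DMRs and a directional track
#'
#' For each track direction (hyper/hypo), builds the 2x2 table of disease-DMR
#' direction (rows: hyper, hypo) against overlap with track regions of that
#' direction (columns: yes, no) and tests it two-sided with [fisher_2x2()].
#' Opposite-direction concordance shows as odds ratios on opposite sides
#' of 1 for the two track directions. DMRs overlapping both track directions
#' are counted in both tables and flagged ambiguous.
#'
#' @param dmrs BED-style table with a `direction` column (hyper/hypo)
#' @param track BED-style table with a `direction` column; an optional
#'   `condition` column adds a per-condition overlap breakdown
#' @return list with `tests` (per track direction: odds ratio of the
#'   hyper-vs-hypo disease rows, Fisher P, the 2x2 counts), `breakdown`,
#'   `ambiguous` (logical along `dmrs`)
#' @export
directional_concordance <- function(dmrs, track) {
  for (nm in c("dmrs", "track")) {
    obj <- get(nm)
    .assert_bed(obj, nm)
    if (is.null(obj$direction) || anyNA(obj$direction))
      stop("`", nm, "` must carry a complete `direction` column",
           call. = FALSE)
  }
  dirs <- c("hyper", "hypo")
  ov <- sapply(dirs, function(td)
    bed_overlaps_any(dmrs, track[track$direction == td, , drop = FALSE]))
  if (nrow(dmrs) == 1L) ov <- matrix(ov, nrow = 1, dimnames = list(NULL, dirs))
  ambiguous <- ov[, "hyper"] & ov[, "hypo"]
  tests <- lapply(dirs, function(td) {
    hit <- ov[, td]
    a <- sum(dmrs$direction == "hyper" & hit)
    b <- sum(dmrs$direction == "hyper" & !hit)
    c_ <- sum(dmrs$direction == "hypo" & hit)
    d <- sum(dmrs$direction == "hypo" & !hit)
    ft <- fisher_2x2(a, b, c_, d)
    data.frame(track_direction = td, n_hyper_overlap = a, n_hyper_total = a + b,
               n_hypo_overlap = c_, n_hypo_total = c_ + d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               degenerate = ft$degenerate, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  breakdown <- NULL
  conds <- if (!is.null(track$condition)) unique(track$condition) else NULL
  rows <- list()
  for (bd in dirs) for (td in dirs) {
    sel <- dmrs$direction == bd
    rows[[length(rows) + 1L]] <- data.frame(
      bd_direction = bd, track_direction = td, condition = "all",
      n_overlap = sum(ov[sel, td]), n_total = sum(sel),
      pct = if (sum(sel)) 100 * mean(ov[sel, td]) else NA_real_,
      stringsAsFactors = FALSE)
    for (cond in conds) {
      sub <- track[track$direction == td & track$condition == cond, ,
                   drop = FALSE]
      f <- bed_overlaps_any(dmrs, sub)
      rows[[length(rows) + 1L]] <- data.frame(
        bd_direction = bd, track_direction = td, condition = cond,
        n_overlap = sum(f[sel]), n_total = sum(sel),
        pct = if (sum(sel)) 100 * mean(f[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  breakdown <- do.call(rbind, rows)
  list(tests = tests, breakdown = breakdown, ambiguous = ambiguous)
}

#' Validate DMRs against a per-CpG bisulfite count table
#'
#' Each CpG inside a DMR is tested two-sided with [fisher_2x2()] on pooled
#' (methylated, unmethylated) x (patients, controls) counts. A DMR is
#' validated when at least one contained CpG has P < `alpha` AND the sign of
#' its methylation-level difference (patients minus controls) matches the
#' DMR direction; significant CpGs of the opposite sign are flagged
#' discordant. DMRs with no covered CpG are excluded from the denominator
#' and counted separately.
#'
#' @param dmrs BED-style table with a `direction` column
#' @param cpg_table data.frame: chrom, pos, meth_cases, unmeth_cases,
#'   meth_controls, unmeth_controls (single-base positions)
#' @param alpha per-CpG significance threshold
#' @return list with `summary` (per direction: totals, covered, validated,
#'   validation rate %, mean absolute methylation difference % among
#'   validated DMRs), `per_dmr` (flags per DMR)
#' @export
cpg_validation <- function(dmrs, cpg_table, alpha = 0.05) {
  .assert_bed(dmrs, "dmrs")
  need <- c("chrom", "pos", "meth_cases", "unmeth_cases", "meth_controls",
            "unmeth_controls")
  miss <- setdiff(need, names(cpg_table))
  if (length(miss))
    stop("cpg_table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(cpg_table[, need[-(1:2)]] < 0))
    stop("CpG counts must be non-negative", call. = FALSE)
  if (is.null(dmrs$direction) || anyNA(dmrs$direction))
    stop("`dmrs` must carry a complete `direction` column", call. = FALSE)
  cpg_bed <- data.frame(chrom = cpg_table$chrom, start = cpg_table$pos,
                        end = cpg_table$pos + 1L, stringsAsFactors = FALSE)
  hits <- .bed_intersect_pairs(dmrs, cpg_bed)
  n <- nrow(dmrs)
  covered <- validated <- discordant <- logical(n)
  mean_diff <- rep(NA_real_, n)
  for (i in unique(hits$idx_a)) {
    js <- hits$idx_b[hits$idx_a == i]
    covered[i] <- TRUE
    ps <- numeric(length(js)); diffs <- numeric(length(js))
    for (k in seq_along(js)) {
      r <- cpg_table[js[k], ]
      ps[k] <- fisher_2x2(r$meth_cases, r$unmeth_cases,
                          r$meth_controls, r$unmeth_controls)$p
      diffs[k] <- r$meth_cases / (r$meth_cases + r$unmeth_cases) -
        r$meth_controls / (r$meth_controls + r$unmeth_controls)
    }
    want <- if (dmrs$direction[i] == "hypo") diffs < 0 else diffs > 0
    sig <- ps < alpha & !is.na(diffs)
    if (any(sig & want)) {
      validated[i] <- TRUE
      mean_diff[i] <- mean(abs(diffs[sig & want]))
    }
    if (any(sig & !want)) discordant[i] <- TRUE
  }
  per_dmr <- data.frame(dmrs[, c("chrom", "start", "end", "direction")],
                        covered = covered, validated = validated,
                        discordant = discordant,
                        mean_abs_diff = mean_diff, stringsAsFactors = FALSE)
  dirs <- sort(unique(dmrs$direction))
  summary <- do.call(rbind, lapply(dirs, function(d) {
    sel <- dmrs$direction == d
    n_cov <- sum(covered[sel]); n_val <- sum(validated[sel])
    data.frame(direction = d, n_total = sum(sel), n_covered = n_cov,
               n_uncovered = sum(sel) - n_cov, n_validated = n_val,
               validation_rate_pct = if (n_cov) 100 * n_val / n_cov else
                 NA_real_,
               mean_abs_diff_pct = if (n_val)
                 100 * mean(mean_diff[sel & validated]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, per_dmr = per_dmr)
}
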