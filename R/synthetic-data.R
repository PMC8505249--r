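# Synthetic study generator: toy genome, promoter tiling layout, planted
# methylation truth, and probe-level enrichment signal. All coordinates are
# 0-based half-open.

.rtrunc_norm <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

#' Generate the toy genome annotation
#'
#' Places non-overlapping promoter tiles (TSS-upstream .. TSS+downstream,
#' mirrored on the minus strand) on the configured chromosomes, together with
#' simple gene models (5'UTR, exons, introns, 3'UTR downstream of the TSS)
#' and CpG islands centred on a configurable fraction of TSSs.
#'
#' @param config a [sim_config()] object
#' @return a list of class `celldmr_annotation` with elements `chromosomes`,
#'   `genes`, `promoters`, `gene_models`, `cpg_islands`
#' @export
generate_annotation <- function(config) {
  validate_config(config)
  tile_w <- .tile_width(config)
  pitch <- tile_w + config$promoter_gap
  slots <- pmax(0L, (as.integer(config$chromosomes) - tile_w) %/% pitch + 1L)
  if (sum(slots) < config$n_genes)
    stop("cannot place ", config$n_genes, " promoter tiles of ", tile_w,
         " bp (plus ", config$promoter_gap, " bp gaps) on a genome of ",
         sum(config$chromosomes), " bp: capacity is ", sum(slots),
         " tiles; enlarge `chromosomes` or reduce `n_genes`", call. = FALSE)
  with_seed(config$seed, {
    # allocate genes to chromosomes proportionally to capacity
    alloc <- floor(slots / sum(slots) * config$n_genes)
    while (sum(alloc) < config$n_genes) {
      i <- which.max(slots - alloc)
      alloc[i] <- alloc[i] + 1L
    }
    genes_list <- vector("list", length(config$chromosomes))
    for (i in seq_along(config$chromosomes)) {
      n_i <- alloc[i]
      if (!n_i) next
      chrom <- names(config$chromosomes)[i]
      use <- sort(sample.int(slots[i], n_i))
      tile_start <- as.integer((use - 1L) * pitch +
        sample.int(config$promoter_gap, n_i, replace = TRUE) - 1L)
      strand <- sample(c("+", "-"), n_i, replace = TRUE)
      tss <- ifelse(strand == "+",
                    tile_start + config$promoter_upstream,
                    tile_start + config$promoter_downstream)
      genes_list[[i]] <- data.frame(
        chrom = chrom, strand = strand, tss = as.integer(tss),
        tile_start = tile_start, tile_end = tile_start + tile_w,
        stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes_list)
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    # gene body extends downstream of the TSS along the strand
    body_len <- as.integer(round(runif(nrow(genes), 2000, 8000)))
    genes$start <- ifelse(genes$strand == "+", genes$tss,
                          pmax(0L, genes$tss - body_len))
    genes$end <- ifelse(genes$strand == "+",
                        pmin(config$chromosomes[genes$chrom], genes$tss + body_len),
                        genes$tss)
    genes <- genes[, c("gene_id", "chrom", "strand", "tss",
                       "start", "end", "tile_start", "tile_end")]
    promoters <- data.frame(
      chrom = genes$chrom, start = genes$tile_start, end = genes$tile_end,
      gene_id = genes$gene_id, stringsAsFactors = FALSE)
    gene_models <- .build_gene_models(genes, promoters)
    has_island <- runif(nrow(genes)) < config$cpg_island_fraction
    islands <- data.frame(
      chrom = genes$chrom[has_island],
      start = pmax(0L, genes$tss[has_island] - config$island_halfwidth),
      end = pmin(as.integer(config$chromosomes[genes$chrom[has_island]]),
                 genes$tss[has_island] + config$island_halfwidth),
      stringsAsFactors = FALSE)
    ann <- list(
      chromosomes = data.frame(chrom = names(config$chromosomes),
                               length = as.integer(config$chromosomes),
                               stringsAsFactors = FALSE),
      genes = genes,
      promoters = bed_sort(promoters),
      gene_models = gene_models,
      cpg_islands = bed_merge(islands))
    class(ann) <- "celldmr_annotation"
    ann
  })
}

# Simple transcript structure: along the strand, the gene body is split into
# 5'UTR, exon1, intron1, exon2, intron2, exon3, 3'UTR at fixed proportions.
.build_gene_models <- function(genes, promoters) {
  prop <- c(five_prime_utr = 0.10, exon = 0.10, intron = 0.20,
            exon = 0.10, intron = 0.30, exon = 0.10, three_prime_utr = 0.10)
  prop <- prop / sum(prop)
  n <- nrow(genes)
  len <- genes$end - genes$start
  # cuts: (length(prop)+1) x n matrix of rounded segment boundaries
  cuts <- round(outer(cumsum(c(0, prop)), len))
  seg_start <- rep(genes$start, each = length(prop)) + as.vector(cuts[-nrow(cuts), ])
  seg_end <- rep(genes$start, each = length(prop)) + as.vector(cuts[-1, ])
  feat_plus <- names(prop); feat_minus <- rev(feat_plus)
  feat <- as.vector(vapply(seq_len(n), function(i)
    if (genes$strand[i] == "+") feat_plus else feat_minus,
    character(length(prop))))
  keep <- seg_end > seg_start
  body <- data.frame(
    gene_id = rep(genes$gene_id, each = length(prop))[keep],
    feature = feat[keep], chrom = rep(genes$chrom, each = length(prop))[keep],
    start = as.integer(seg_start[keep]), end = as.integer(seg_end[keep]),
    stringsAsFactors = FALSE)
  prom <- data.frame(gene_id = promoters$gene_id, feature = "promoter",
                     chrom = promoters$chrom, start = promoters$start,
                     end = promoters$end, stringsAsFactors = FALSE)
  out <- rbind(prom, body)
  bed_sort(out)
}

#' Generate the promoter tiling probe layout
#'
#' Probes of `config$probe_length` bp tile each promoter from its start at
#' `spacing` bp start-to-start intervals; a tile of width W holds
#' floor(W / spacing) probes (the trailing remainder is left uncovered).
#'
#' @param annotation a `celldmr_annotation`
#' @param spacing probe spacing in bp (>= probe length)
#' @param probe_length probe length in bp
#' @return data.frame with probe_id, chrom, start, end, promoter_id
#' @export
generate_probe_layout <- function(annotation, spacing = 35L,
                                  probe_length = 25L) {
  stopifnot(inherits(annotation, "celldmr_annotation"))
  spacing <- as.integer(spacing)
  if (spacing < probe_length)
    stop("probe spacing (", spacing, " bp) must be >= probe length (",
         probe_length, " bp)", call. = FALSE)
  prom <- annotation$promoters
  n_per <- (prom$end - prom$start) %/% spacing
  if (any(n_per < 1L))
    stop("promoter tile narrower than probe spacing", call. = FALSE)
  idx <- rep.int(seq_len(nrow(prom)), n_per)
  offs <- unlist(lapply(n_per, function(n) seq_len(n) - 1L),
                 use.names = FALSE)
  start <- prom$start[idx] + offs * spacing
  layout <- data.frame(
    probe_id = sprintf("%s_p%04d", prom$gene_id[idx], offs + 1L),
    chrom = prom$chrom[idx],
    start = as.integer(start),
    end = as.integer(start + probe_length),
    promoter_id = prom$gene_id[idx],
    stringsAsFactors = FALSE)
  layout[order(layout$chrom, layout$start), , drop = FALSE]
}

#' Plant the ground-truth methylation structure
#'
#' Draws, per cell type, baseline promoter methylation states, a set of DMR
#' promoters with direction (hyper/hypo in patients) and effect size, HMR
#' regions, drug-responsive regions overlapping the disease DMRs at the
#' configured concordance fraction (flipping direction with the configured
#' probability), and GWAS-locus membership with a planted promoter-level
#' enrichment odds ratio.
#'
#' GWAS placement: promoter membership is Bernoulli with success odds
#' `gwas_enrichment_odds` times higher for DMR promoters; the base rate is
#' solved so the expected number of locus promoters equals `n_gwas_loci`,
#' and each selected promoter tile becomes one locus interval.
#'
#' @param annotation a `celldmr_annotation`
#' @param config the [sim_config()] used for the annotation
#' @return a list of class `celldmr_truth` with elements `regions` (per
#'   gene x cell type), `drug` (per responsive gene x condition),
#'   `gwas_promoters`, `gwas_loci`, `seed`
#' @export
simulate_truth <- function(annotation, config) {
  stopifnot(inherits(annotation, "celldmr_annotation"))
  validate_config(config)
  genes <- annotation$genes
  n <- nrow(genes)
  n_dmr <- round(config$dmr_fraction * n)
  if (config$drug_concordance > 0 && n_dmr == 0)
    stop("infeasible truth: drug_concordance > 0 requires planted DMRs ",
         "(dmr_fraction yields none)", call. = FALSE)
  if (config$n_gwas_loci > n)
    stop("infeasible truth: n_gwas_loci (", config$n_gwas_loci,
         ") exceeds the number of promoters (", n, ")", call. = FALSE)
  with_seed(config$seed + 1L, {
    regions <- do.call(rbind, lapply(config$cell_types, function(ct) {
      baseline <- runif(n) < config$meth_fraction[[ct]]
      is_dmr <- rep(FALSE, n)
      direction <- rep(NA_character_, n)
      effect <- rep(NA_real_, n)
      if (n_dmr > 0) {
        # a hypomethylated DMR needs a methylated control baseline and a
        # hypermethylated one an unmethylated baseline; drawing each
        # direction from its matching baseline pool keeps the marginal
        # methylated fraction at its configured value. If a pool runs dry
        # the remainder is drawn from the other pool and its baseline
        # flipped.
        n_hypo <- sum(runif(n_dmr) < config$frac_hypo)
        n_hyper <- n_dmr - n_hypo
        pool_m <- sample(which(baseline))
        pool_u <- sample(which(!baseline))
        take_m <- min(n_hypo, length(pool_m))
        take_u <- min(n_hyper, length(pool_u))
        hypo_idx <- c(pool_m[seq_len(take_m)],
                      pool_u[take_u + seq_len(n_hypo - take_m)])
        hyper_idx <- c(pool_u[seq_len(take_u)],
                       pool_m[take_m + seq_len(n_hyper - take_u)])
        if (anyNA(hypo_idx) || anyNA(hyper_idx) ||
            length(hypo_idx) < n_hypo || length(hyper_idx) < n_hyper)
          stop("infeasible truth: dmr_fraction exceeds the promoter count",
               call. = FALSE)
        is_dmr[c(hypo_idx, hyper_idx)] <- TRUE
        direction[hypo_idx] <- "hypo"; direction[hyper_idx] <- "hyper"
        baseline[hypo_idx] <- TRUE; baseline[hyper_idx] <- FALSE
        effect[is_dmr] <- config$effect_sizes[
          sample.int(length(config$effect_sizes), sum(is_dmr),
                     replace = TRUE)]
      }
      wdmr <- .rand_subinterval(genes, is_dmr, config$dmr_width_range)
      is_hmr <- runif(n) < config$hmr_fraction
      whmr <- .rand_subinterval(genes, is_hmr, config$hmr_width_range)
      data.frame(
        gene_id = genes$gene_id, cell_type = ct,
        baseline_methylated = baseline,
        is_dmr = is_dmr, direction = direction, effect_size = effect,
        dmr_start = wdmr$start, dmr_end = wdmr$end,
        is_hmr = is_hmr, hmr_start = whmr$start, hmr_end = whmr$end,
        stringsAsFactors = FALSE)
    }))
    drug <- .simulate_drug_truth(genes, regions, config)
    gw <- .simulate_gwas_truth(genes, regions, config)
    truth <- list(regions = regions, drug = drug,
                  gwas_promoters = gw$promoters, gwas_loci = gw$loci,
                  seed = config$seed)
    class(truth) <- "celldmr_truth"
    truth
  })
}

# Random subinterval of each flagged gene's promoter tile with width drawn
# from width_range; NA rows where flag is FALSE.
.rand_subinterval <- function(genes, flag, width_range) {
  n <- nrow(genes)
  start <- rep(NA_integer_, n); end <- rep(NA_integer_, n)
  k <- sum(flag)
  if (k) {
    w <- as.integer(round(runif(k, width_range[1], width_range[2])))
    tw <- genes$tile_end[flag] - genes$tile_start[flag]
    w <- pmin(w, tw)
    off <- as.integer(floor(runif(k) * (tw - w + 1L)))
    start[flag] <- genes$tile_start[flag] + off
    end[flag] <- start[flag] + w
  }
  list(start = start, end = end)
}

.simulate_drug_truth <- function(genes, regions, config) {
  empty <- data.frame(gene_id = character(0), condition = character(0),
                      direction = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  conds <- config$drug_conditions
  # disease direction of a DMR gene: the direction in a cell type carrying
  # the DMR (first listed cell type wins if both do)
  dmr_rows <- regions[regions$is_dmr, ]
  dmr_rows <- dmr_rows[!duplicated(dmr_rows$gene_id), ]
  out <- list()
  if (nrow(dmr_rows) && config$drug_concordance > 0) {
    resp <- runif(nrow(dmr_rows)) < config$drug_concordance
    for (i in which(resp)) {
      g <- dmr_rows[i, ]
      flip <- runif(1) < config$drug_flip_prob
      dir <- if (flip) {
        if (g$direction == "hypo") "hyper" else "hypo"
      } else g$direction
      in_cond <- runif(length(conds)) < 0.5
      if (!any(in_cond)) in_cond[sample.int(length(conds), 1L)] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, condition = conds[in_cond], direction = dir,
        chrom = genes$chrom[match(g$gene_id, genes$gene_id)],
        start = g$dmr_start, end = g$dmr_end, stringsAsFactors = FALSE)
    }
  }
  # background drug responses on non-DMR promoters only, random direction
  non_dmr <- setdiff(genes$gene_id, dmr_rows$gene_id)
  if (length(non_dmr) && config$drug_background_rate > 0) {
    for (cond in conds) {
      hit <- non_dmr[runif(length(non_dmr)) < config$drug_background_rate]
      if (!length(hit)) next
      gi <- match(hit, genes$gene_id)
      sub <- .rand_subinterval(genes[gi, , drop = FALSE],
                               rep(TRUE, length(gi)), config$dmr_width_range)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = hit, condition = cond,
        direction = sample(c("hyper", "hypo"), length(hit), replace = TRUE),
        chrom = genes$chrom[gi], start = sub$start, end = sub$end,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  drug <- do.call(rbind, out)
  drug[order(drug$condition, drug$chrom, drug$start), , drop = FALSE]
}

.simulate_gwas_truth <- function(genes, regions, config) {
  n <- nrow(genes)
  is_dmr_gene <- genes$gene_id %in% regions$gene_id[regions$is_dmr]
  omega <- config$gwas_enrichment_odds
  target <- config$n_gwas_loci
  n1 <- sum(is_dmr_gene); n0 <- n - n1
  p1_of <- function(p0) {
    o <- omega * p0 / (1 - p0)
    o / (1 + o)
  }
  f <- function(p0) n0 * p0 + n1 * p1_of(p0) - target
  if (f(1 - 1e-9) < 0)
    stop("infeasible truth: cannot reach ", target,
         " expected GWAS-locus promoters", call. = FALSE)
  p0 <- uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  p <- ifelse(is_dmr_gene, p1_of(p0), p0)
  in_locus <- runif(n) < p
  promoters <- data.frame(gene_id = genes$gene_id, in_locus = in_locus,
                          is_dmr_gene = is_dmr_gene,
                          stringsAsFactors = FALSE)
  loci <- data.frame(chrom = genes$chrom[in_locus],
                     start = genes$tile_start[in_locus],
                     end = genes$tile_end[in_locus],
                     locus_id = sprintf("locus_%03d", seq_len(sum(in_locus))),
                     stringsAsFactors = FALSE)
  list(promoters = promoters, loci = bed_sort(loci))
}

#' Simulate probe-level enrichment signal and the sample sheet
#'
#' Signal model per probe and array column:
#' baseline (methylation amplitude if the promoter's baseline state is
#' methylated in that cell type) + planted DMR shift (for case samples at
#' probes inside the planted region; sign by direction, magnitude
#' effect x noise SD) + per-(sample, cell type) random intercept shared by
#' the two replicate experiments + independent probe noise. Reference
#' columns emulate the whole-genome-amplified unmethylated baseline.
#'
#' @param annotation a `celldmr_annotation`
#' @param layout probe layout from [generate_probe_layout()]
#' @param truth a `celldmr_truth`
#' @param config the [sim_config()]
#' @return list of class `celldmr_signals`: `signals` (probe x column
#'   matrix), `sample_sheet` (one row per column), `covariates` (one row per
#'   subject), `ref_columns`
#' @export
simulate_signals <- function(annotation, layout, truth, config) {
  stopifnot(inherits(annotation, "celldmr_annotation"),
            inherits(truth, "celldmr_truth"))
  validate_config(config)
  genes <- annotation$genes
  with_seed(config$seed + 2L, {
    n_sub <- config$n_cases + config$n_controls
    group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
    sample_id <- sprintf("s%03d", seq_len(n_sub))
    covariates <- .simulate_covariates(sample_id, group)
    sheet <- expand.grid(replicate = seq_len(config$n_replicates),
                         sample_id = sample_id,
                         cell_type = config$cell_types,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sheet$group <- group[match(sheet$sample_id, sample_id)]
    sheet$column_id <- paste(sheet$sample_id, sheet$cell_type,
                             paste0("rep", sheet$replicate), sep = ".")
    sheet <- sheet[, c("column_id", "sample_id", "group", "cell_type",
                       "replicate")]
    sheet <- cbind(sheet, covariates[match(sheet$sample_id,
                                           covariates$sample_id),
                                     -(1:2), drop = FALSE])
    rownames(sheet) <- NULL
    P <- nrow(layout)
    gi <- match(layout$promoter_id, genes$gene_id)
    effect_unit <- if (config$noise_sd > 0) config$noise_sd else 1
    # per cell type: baseline mean vector and case-shift vector over probes
    mu_ct <- list(); delta_ct <- list()
    for (ct in config$cell_types) {
      reg <- truth$regions[truth$regions$cell_type == ct, ]
      reg <- reg[match(genes$gene_id, reg$gene_id), ]
      mu_ct[[ct]] <- config$meth_amplitude *
        as.numeric(reg$baseline_methylated[gi])
      d <- numeric(P)
      in_dmr <- !is.na(reg$dmr_start[gi]) & reg$is_dmr[gi] &
        layout$start >= reg$dmr_start[gi] & layout$start < reg$dmr_end[gi]
      sign <- ifelse(reg$direction[gi] == "hypo", -1, 1)
      d[in_dmr] <- (sign * reg$effect_size[gi] * effect_unit)[in_dmr]
      delta_ct[[ct]] <- d
    }
    # optional confounder: global shift proportional to a covariate z-score
    shift <- setNames(numeric(n_sub), sample_id)
    if (!is.null(config$confound_covariate) && config$confound_strength != 0) {
      cv <- covariates[[config$confound_covariate]]
      z <- (cv - mean(cv, na.rm = TRUE)) / sd(cv, na.rm = TRUE)
      z[is.na(z)] <- 0
      shift <- setNames(config$confound_strength * effect_unit * z, sample_id)
    }
    u <- matrix(rnorm(n_sub * length(config$cell_types),
                      sd = config$sample_effect_sd),
                nrow = n_sub,
                dimnames = list(sample_id, config$cell_types))
    C <- nrow(sheet)
    M <- matrix(rnorm(P * C, sd = config$noise_sd), nrow = P, ncol = C,
                dimnames = list(layout$probe_id, sheet$column_id))
    for (j in seq_len(C)) {
      ct <- sheet$cell_type[j]; sid <- sheet$sample_id[j]
      mu <- mu_ct[[ct]] + u[sid, ct] + shift[sid]
      if (sheet$group[j] == "case") mu <- mu + delta_ct[[ct]]
      M[, j] <- M[, j] + mu
    }
    ref <- matrix(rnorm(P * config$n_ref, sd = config$noise_sd), nrow = P,
                  dimnames = list(layout$probe_id,
                                  paste0("ref.", seq_len(config$n_ref))))
    out <- list(signals = cbind(M, ref), sample_sheet = sheet,
                covariates = covariates,
                ref_columns = colnames(ref), seed = config$seed)
    class(out) <- "celldmr_signals"
    out
  })
}

# Cohort covariates; distributions are arbitrary fixtures, not estimates of
# any real cohort. Illness covariates are NA for controls.
.simulate_covariates <- function(sample_id, group) {
  n <- length(sample_id)
  age <- round(.rtrunc_norm(n, 45, 10, 18), 1)
  pmi <- round(.rtrunc_norm(n, 30, 10, 1), 1)
  ph <- round(rnorm(n, 6.5, 0.25), 2)
  onset <- round(pmin(age - 1, .rtrunc_norm(n, 30, 8, 15)), 1)
  duration <- round(age - onset, 1)
  antipsychotics <- round(rlnorm(n, meanlog = log(2000), sdlog = 0.8))
  is_ctrl <- group == "control"
  onset[is_ctrl] <- NA; duration[is_ctrl] <- NA
  antipsychotics[is_ctrl] <- NA
  data.frame(sample_id = sample_id, group = group, age = age, pmi = pmi,
             ph = ph, onset = onset, duration = duration,
             antipsychotics = antipsychotics, stringsAsFactors = FALSE)
}

#' Run the whole generator in one call
#' @param config a [sim_config()]
#' @return list with `config`, `annotation`, `layout`, `truth`, `signals`
#' @export
simulate_study <- function(config = sim_config()) {
  annotation <- generate_annotation(config)
  layout <- generate_probe_layout(annotation, config$probe_spacing,
                                  config$probe_length)
  truth <- simulate_truth(annotation, config)
  signals <- simulate_signals(annotation, layout, truth, config)
  list(config = config, annotation = annotation, layout = layout,
       truth = truth, signals = signals)
}

#' Simulate a per-CpG bisulfite count table for DMR validation
#'
#' Places CpG sites inside promoter tiles and draws, per group, methylated /
#' unmethylated read counts whose underlying methylation level reflects the
#' planted truth for the given cell type (baseline level for methylated /
#' unmethylated promoters, shifted by `delta` inside planted DMRs in cases).
#'
#' @param study output of [simulate_study()]
#' @param cell_type cell type to emulate
#' @param sites_per_tile CpG sites per promoter tile
#' @param depth read depth per group at each CpG
#' @param delta true methylation-level difference inside planted DMRs
#'   (fraction, applied in the planted direction)
#' @param seed RNG seed
#' @return data.frame: chrom, pos, meth_cases, unmeth_cases, meth_controls,
#'   unmeth_controls
#' @export
simulate_cpg_table <- function(study, cell_type = "neuron",
                               sites_per_tile = 5L, depth = 40L,
                               delta = 0.15, seed = study$config$seed + 3L) {
  genes <- study$annotation$genes
  reg <- study$truth$regions
  reg <- reg[reg$cell_type == cell_type, ]
  reg <- reg[match(genes$gene_id, reg$gene_id), ]
  with_seed(seed, {
    n <- nrow(genes)
    pos <- unlist(lapply(seq_len(n), function(i) {
      sort(genes$tile_start[i] +
             sample.int(genes$tile_end[i] - genes$tile_start[i],
                        sites_per_tile))
    }))
    gi <- rep(seq_len(n), each = sites_per_tile)
    p_ctrl <- ifelse(reg$baseline_methylated[gi], 0.8, 0.15)
    in_dmr <- reg$is_dmr[gi] & !is.na(reg$dmr_start[gi]) &
      pos >= reg$dmr_start[gi] & pos < reg$dmr_end[gi]
    sign <- ifelse(reg$direction[gi] == "hypo", -1, 1)
    p_case <- p_ctrl + ifelse(in_dmr & !is.na(sign), sign * delta, 0)
    p_case <- pmin(pmax(p_case, 0.01), 0.99)
    meth_cases <- rbinom(length(pos), depth, p_case)
    meth_controls <- rbinom(length(pos), depth, p_ctrl)
    data.frame(chrom = genes$chrom[gi], pos = pos,
               meth_cases = meth_cases, unmeth_cases = depth - meth_cases,
               meth_controls = meth_controls,
               unmeth_controls = depth - meth_controls,
               stringsAsFactors = FALSE)
  })
}

#' Extract planted truth regions as BED-style tables
#' @param study output of [simulate_study()]
#' @param cell_type cell type
#' @param what "dmr" or "hmr"
#' @return data.frame chrom/start/end/gene_id (+ direction, effect for DMRs)
#' @export
truth_regions <- function(study, cell_type, what = c("dmr", "hmr")) {
  what <- match.arg(what)
  reg <- study$truth$regions
  reg <- reg[reg$cell_type == cell_type, ]
  genes <- study$annotation$genes
  if (what == "dmr") {
    r <- reg[reg$is_dmr, ]
    out <- data.frame(chrom = genes$chrom[match(r$gene_id, genes$gene_id)],
                      start = r$dmr_start, end = r$dmr_end,
                      gene_id = r$gene_id, direction = r$direction,
                      effect_size = r$effect_size, stringsAsFactors = FALSE)
  } else {
    r <- reg[reg$is_hmr, ]
    out <- data.frame(chrom = genes$chrom[match(r$gene_id, genes$gene_id)],
                      start = r$hmr_start, end = r$hmr_end,
                      gene_id = r$gene_id, stringsAsFactors = FALSE)
  }
  bed_sort(out)
}
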