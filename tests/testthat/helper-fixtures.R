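# Shared fixture builders. Everything is generated in code at test time.

# Small study configuration used across module tests.
small_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    n_genes = 60L, chromosomes = c(chrA = 450000L, chrB = 450000L),
    n_cases = 6L, n_controls = 6L, dmr_fraction = 0.2,
    effect_sizes = c(3, 4), n_gwas_loci = 12L, seed = seed)
  do.call(sim_config, modifyList(defaults, args))
}

# Hand-built probe layout: one tile per promoter row, probes at `spacing`.
toy_layout <- function(n_probes, spacing = 35L, chrom = "chrT",
                       tile_start = 0L, promoter_id = "gX",
                       probe_length = 25L) {
  start <- tile_start + (seq_len(n_probes) - 1L) * spacing
  data.frame(probe_id = sprintf("%s_p%03d", promoter_id, seq_len(n_probes)),
             chrom = chrom, start = start, end = start + probe_length,
             promoter_id = promoter_id, stringsAsFactors = FALSE)
}

# Random multi-tile layout for property tests.
random_layout <- function(n_tiles = 3, probes_per_tile = 20,
                          spacing = 35L) {
  do.call(rbind, lapply(seq_len(n_tiles), function(i) {
    toy_layout(probes_per_tile, spacing = spacing,
               tile_start = (i - 1L) * 20000L,
               promoter_id = sprintf("g%02d", i))
  }))
}

# Random BED table on a small genome.
random_bed <- function(n, chroms = c("c1", "c2"), genome_len = 2000L,
                       max_width = 200L) {
  start <- sample.int(genome_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width, stringsAsFactors = FALSE)
}

# Per-base occupancy mask of a BED table, as one logical vector per chrom.
base_mask <- function(df, chroms, genome_len) {
  masks <- lapply(chroms, function(ch) logical(genome_len))
  names(masks) <- chroms
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (df$end[i] > df$start[i])
      masks[[ch]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  masks
}

# Independent run-length MR caller: linear scan over probes of each tile.
oracle_call_mrs <- function(scores, layout, threshold, min_probes, max_gap) {
  out <- list()
  for (tile in unique(layout$promoter_id)) {
    idx <- which(layout$promoter_id == tile)
    idx <- idx[order(layout$start[idx])]
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= min_probes)
        out[[length(out) + 1L]] <<- data.frame(
          chrom = layout$chrom[run[1]], start = layout$start[run[1]],
          end = layout$end[run[length(run)]],
          score = mean(scores[run]), n_probes = length(run),
          stringsAsFactors = FALSE)
    }
    for (i in idx) {
      if (scores[i] >= threshold) {
        if (length(run) &&
            layout$start[i] - layout$end[run[length(run)]] > max_gap) {
          flush(run); run <- integer(0)
        }
        run <- c(run, i)
      }
    }
    flush(run)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      n_probes = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# Exhaustive-enumeration two-sided Fisher P via log-binomials (independent
# of dhyper and of fisher_2x2's code path).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[support == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

expect_same_regions <- function(a, b, tol = 1e-8) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    rownames(a) <- rownames(b) <- NULL
    cols <- intersect(c("chrom", "start", "end", "direction"),
                      intersect(names(a), names(b)))
    expect_equal(a[cols], b[cols], tolerance = tol)
  }
}
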