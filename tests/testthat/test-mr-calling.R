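# MR calling: window scores against a sorting/slicing oracle, the
# run/gap/min-probe caller against a linear-scan oracle, threshold
# monotonicity, and the sample-level statistics.

test_that("window scores reduce to known values in simple layouts", {
  lay <- toy_layout(21)
  expect_equal(window_scores(rep(2.5, 21), lay), rep(2.5, 21))
  # bandwidth below the probe spacing: each probe is its own window
  x <- rnorm(21)
  expect_equal(window_scores(x, lay, bandwidth = 10), x)
})

test_that("a spike is trimmed out of neighbouring windows", {
  lay <- toy_layout(11)
  x <- rep(0, 11); x[6] <- 100
  ws <- window_scores(x, lay, bandwidth = 5 * 35, trim = 0.1)
  # probe 1's window is probes 1..6 (truncated): floor(0.1*6)=0 trimmed,
  # spike included; probe 4's window is 1..9: floor(0.9)=0 trimmed as well;
  # an 11-probe window trims floor(1.1)=1 from each end, excluding the spike
  expect_equal(ws[6], 0)  # full window centred on the spike, spike trimmed
  expect_equal(ws[1], 100 / 6)
})

test_that("window scores equal the sort-and-slice trimmed mean oracle", {
  set.seed(101)
  for (rep in 1:30) {
    lay <- random_layout(n_tiles = sample(1:3, 1),
                         probes_per_tile = sample(5:25, 1))
    x <- rnorm(nrow(lay))
    bw <- sample(c(50, 150, 300, 600), 1)
    ws <- window_scores(x, lay, bandwidth = bw, trim = 0.1)
    oracle <- vapply(seq_len(nrow(lay)), function(i) {
      same <- lay$promoter_id == lay$promoter_id[i] &
        abs(lay$start - lay$start[i]) <= bw
      v <- sort(x[same])
      k <- floor(0.1 * length(v))
      mean(v[(k + 1):(length(v) - k)])
    }, numeric(1))
    expect_equal(ws, oracle)
  }
})

test_that("call_mrs handles the threshold/gap/min-probe edge cases", {
  lay <- toy_layout(30)
  expect_equal(nrow(call_mrs(rep(0, 30), lay, threshold = 1)), 0)
  x <- rep(0, 30); x[6:25] <- 5
  mr <- call_mrs(x, lay, threshold = 1)
  expect_equal(nrow(mr), 1)
  expect_equal(mr$start, lay$start[6])
  expect_equal(mr$end, lay$end[25])
  expect_equal(mr$n_probes, 20L)
  # two blocks split by a gap wider than max_gap, merged when allowed
  y <- rep(0, 30); y[1:8] <- 5; y[13:20] <- 5
  # gap: start[13] - end[8] = 12*35 - (7*35+25) = 150 bp
  expect_equal(nrow(call_mrs(y, lay, threshold = 1, max_gap = 110)), 2)
  expect_equal(nrow(call_mrs(y, lay, threshold = 1, max_gap = 150)), 1)
})

test_that("call_mrs matches the linear-scan oracle on random fixtures", {
  set.seed(202)
  for (rep in 1:100) {
    lay <- random_layout(n_tiles = sample(1:3, 1),
                         probes_per_tile = sample(4:30, 1))
    x <- rnorm(nrow(lay))
    thr <- runif(1, -1, 1)
    mp <- sample(1:5, 1); mg <- sample(c(0, 50, 110, 200), 1)
    got <- call_mrs(x, lay, thr, min_probes = mp, max_gap = mg)
    want <- oracle_call_mrs(x, lay, thr, min_probes = mp, max_gap = mg)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("raising the threshold never increases MR base-pair coverage", {
  # region COUNT is not monotone for a gap-merging caller (a raised
  # threshold can split one merged run into two), but the covered bp and
  # the selected probe set shrink monotonically
  set.seed(303)
  for (rep in 1:25) {
    lay <- random_layout(n_tiles = 2, probes_per_tile = 40)
    x <- rnorm(nrow(lay), sd = 2)
    prev_bp <- Inf; prev_probes <- Inf
    for (thr in c(-1, 0, 1, 2)) {
      mr <- call_mrs(x, lay, thr)
      expect_lte(sum(mr$end - mr$start), prev_bp)
      expect_lte(sum(mr$n_probes), prev_probes)
      prev_bp <- sum(mr$end - mr$start); prev_probes <- sum(mr$n_probes)
    }
  }
})

test_that("planted methylated promoters are recovered, null calls are stable", {
  cfg <- small_config(seed = 5, dmr_fraction = 0, drug_concordance = 0,
                      meth_amplitude = 3, noise_sd = 1)
  st <- simulate_study(cfg)
  mr <- call_study_mrs(st$signals, st$layout)
  prom <- st$annotation$promoters
  hit <- 0; tot <- 0
  for (ct in cfg$cell_types) {
    tr <- st$truth$regions[st$truth$regions$cell_type == ct &
                             st$truth$regions$baseline_methylated, ]
    meth <- prom[prom$gene_id %in% tr$gene_id, ]
    for (sid in unique(mr$counts$sample_id)) {
      f <- bed_overlaps_any(meth, mr$mrsets[[paste(sid, ct, sep = ".")]])
      hit <- hit + sum(f); tot <- tot + length(f)
    }
  }
  expect_gte(hit / tot, 0.95)
  # no planted group difference: mean MR counts agree between groups
  agg <- tapply(mr$counts$n_mr, list(mr$counts$cell_type, mr$counts$group),
                mean)
  expect_lt(max(abs(agg[, "case"] - agg[, "control"])), 3)
})

test_that("Mann-Whitney exact branch reproduces enumerated P-values", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$method, "exact")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 / C(6,3)
  # identical groups: degenerate, U at its mid-value
  mw2 <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_true(mw2$degenerate)
  expect_equal(mw2$p, 1)
  expect_equal(mw2$U, 10)  # m*n/2
  # agreement with the reference implementation on random tie-free data
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("normal approximation tracks the exact branch at combined n = 12", {
  set.seed(12)
  for (i in 1:40) {
    x <- rnorm(6); y <- rnorm(6)
    pe <- mann_whitney(x, y, exact = TRUE)$p
    pa <- mann_whitney(x, y, exact = FALSE)$p
    expect_lte(abs(pe - pa), 0.02)
  }
})

test_that("MR-count statistics cover the study comparisons and covariates", {
  counts <- data.frame(
    sample_id = rep(sprintf("s%02d", 1:12), 2),
    cell_type = rep(c("neuron", "nonneuron"), each = 12),
    group = rep(rep(c("case", "control"), each = 6), 2),
    n_mr = c(1:12, 13:24), stringsAsFactors = FALSE)
  cov <- data.frame(sample_id = sprintf("s%02d", 1:12),
                    group = rep(c("case", "control"), each = 6),
                    age = c(1:12), onset = c(1:6, rep(NA, 6)))
  st <- mr_count_stats(counts, cov)
  expect_setequal(
    st$comparisons$comparison,
    c("neuron_vs_nonneuron_within_case", "neuron_vs_nonneuron_within_control",
      "case_vs_control_within_neuron", "case_vs_control_within_nonneuron"))
  # covariate equals the MR count exactly: rho = 1
  rho_age <- st$covariate_cor$rho[st$covariate_cor$cell_type == "neuron" &
                                    st$covariate_cor$covariate == "age"]
  expect_equal(rho_age, 1)
  # case-only covariate uses only the non-missing samples
  n_onset <- st$covariate_cor$n[st$covariate_cor$cell_type == "neuron" &
                                  st$covariate_cor$covariate == "onset"]
  expect_equal(n_onset, 6)
})
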