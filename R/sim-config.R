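#' Simulation configuration for the synthetic promoter-array study
#'
#' Bundles every tunable of the synthetic-data generator with validation.
#' Defaults emulate the study design: a promoter tiling array covering each
#' promoter from 7.5 kb upstream to 2.5 kb downstream of the TSS with 25-mer
#' probes at 35 bp spacing, two cell fractions (neuronal, nonneuronal),
#' 34 patients and 35 controls, and two technical replicate experiments per
#' sample. The genome itself is a toy (default 300 promoters on two
#' chromosomes) so the pipeline runs at desk scale.
#'
#' @param n_genes number of genes / promoter tiles
#' @param chromosomes named integer vector of chromosome lengths (bp)
#' @param n_cases,n_controls samples per group
#' @param probe_spacing probe start-to-start spacing (bp)
#' @param probe_length probe length (bp)
#' @param promoter_upstream,promoter_downstream promoter-tile extent around
#'   the TSS (bp); the tile spans TSS-upstream .. TSS+downstream on the plus
#'   strand and is mirrored on the minus strand
#' @param promoter_gap minimum gap between adjacent promoter tiles (bp)
#' @param cell_types character vector of cell-fraction labels
#' @param meth_fraction named per-cell-type fraction of promoters with a
#'   methylated baseline state
#' @param noise_sd probe-level Gaussian noise SD (signal units)
#' @param sample_effect_sd per (sample, cell type) random-intercept SD,
#'   shared by the two replicate experiments
#' @param meth_amplitude mean enrichment signal of a methylated promoter over
#'   the whole-genome-amplified reference (signal units)
#' @param n_replicates technical replicate experiments per sample
#' @param n_ref reference (whole-genome-amplified) array columns
#' @param dmr_fraction fraction of promoters with a planted DMR (per cell type)
#' @param frac_hypo fraction of planted DMRs hypomethylated in patients
#' @param effect_sizes grid of planted effect sizes, in units of `noise_sd`
#'   (signal units when `noise_sd` is 0)
#' @param dmr_width_range planted DMR width range (bp)
#' @param hmr_fraction fraction of promoters carrying a hydroxymethylated
#'   region (per cell type)
#' @param hmr_width_range planted HMR width range (bp)
#' @param cpg_island_fraction fraction of TSSs with a CpG island
#' @param island_halfwidth CpG-island half-width around the TSS (bp)
#' @param drug_conditions auxiliary drug-track condition labels
#'   (mood stabilizer x min/max therapeutic concentration)
#' @param drug_concordance fraction of DMR promoters that are also
#'   drug-responsive (their drug region coincides with the planted DMR)
#' @param drug_flip_prob probability that a concordant drug region changes in
#'   the direction OPPOSITE to the planted disease DMR
#' @param drug_background_rate per-condition rate of drug-responsive regions
#'   among non-DMR promoters
#' @param n_gwas_loci expected number of GWAS-locus promoters
#' @param gwas_enrichment_odds planted odds ratio that a DMR promoter falls
#'   inside a GWAS locus, relative to a non-DMR promoter (1 = no enrichment)
#' @param confound_covariate optional covariate name ("age", "pmi", "ph",
#'   "onset", "duration", "antipsychotics") correlated with global
#'   methylation burden
#' @param confound_strength global signal shift per covariate SD, in units of
#'   `noise_sd`
#' @param seed RNG seed recorded in all outputs
#' @return a validated list of class `celldmr_config`
#' @export
sim_config <- function(n_genes = 300L,
                       chromosomes = c(chr1 = 2500000L, chr2 = 2500000L),
                       n_cases = 34L,
                       n_controls = 35L,
                       probe_spacing = 35L,
                       probe_length = 25L,
                       promoter_upstream = 7500L,
                       promoter_downstream = 2500L,
                       promoter_gap = 2000L,
                       cell_types = c("neuron", "nonneuron"),
                       meth_fraction = c(neuron = 0.10, nonneuron = 0.15),
                       noise_sd = 1,
                       sample_effect_sd = 0.2,
                       meth_amplitude = 3,
                       n_replicates = 2L,
                       n_ref = 4L,
                       dmr_fraction = 0.05,
                       frac_hypo = 0.7,
                       effect_sizes = c(2, 3, 4),
                       dmr_width_range = c(600L, 1500L),
                       hmr_fraction = 0.10,
                       hmr_width_range = c(400L, 1000L),
                       cpg_island_fraction = 0.6,
                       island_halfwidth = 500L,
                       drug_conditions = c("Li_min", "Li_max", "Val_min",
                                           "Val_max", "Car_min", "Car_max"),
                       drug_concordance = 0.35,
                       drug_flip_prob = 0.9,
                       drug_background_rate = 0.05,
                       n_gwas_loci = 30L,
                       gwas_enrichment_odds = 2,
                       confound_covariate = NULL,
                       confound_strength = 0,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), chromosomes = chromosomes,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    probe_spacing = as.integer(probe_spacing),
    probe_length = as.integer(probe_length),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    promoter_gap = as.integer(promoter_gap),
    cell_types = cell_types, meth_fraction = meth_fraction,
    noise_sd = noise_sd, sample_effect_sd = sample_effect_sd,
    meth_amplitude = meth_amplitude,
    n_replicates = as.integer(n_replicates), n_ref = as.integer(n_ref),
    dmr_fraction = dmr_fraction, frac_hypo = frac_hypo,
    effect_sizes = effect_sizes,
    dmr_width_range = as.integer(dmr_width_range),
    hmr_fraction = hmr_fraction,
    hmr_width_range = as.integer(hmr_width_range),
    cpg_island_fraction = cpg_island_fraction,
    island_halfwidth = as.integer(island_halfwidth),
    drug_conditions = drug_conditions,
    drug_concordance = drug_concordance,
    drug_flip_prob = drug_flip_prob,
    drug_background_rate = drug_background_rate,
    n_gwas_loci = as.integer(n_gwas_loci),
    gwas_enrichment_odds = gwas_enrichment_odds,
    confound_covariate = confound_covariate,
    confound_strength = confound_strength,
    seed = as.integer(seed)
  )
  class(cfg) <- "celldmr_config"
  validate_config(cfg)
}

#' @rdname sim_config
#' @param config a `celldmr_config`
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "celldmr_config"))
  chk_count <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 1L)
      stop("`", nm, "` must be a positive integer", call. = FALSE)
  }
  for (nm in c("n_genes", "n_cases", "n_controls", "probe_spacing",
               "probe_length", "n_replicates", "n_ref", "n_gwas_loci"))
    chk_count(config[[nm]], nm)
  chk_frac <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("meth_fraction", "dmr_fraction", "frac_hypo", "hmr_fraction",
               "cpg_island_fraction", "drug_concordance", "drug_flip_prob",
               "drug_background_rate"))
    chk_frac(config[[nm]], nm)
  if (any(config$effect_sizes < 0))
    stop("`effect_sizes` must be non-negative", call. = FALSE)
  if (config$noise_sd < 0 || config$sample_effect_sd < 0)
    stop("noise and sample-effect SDs must be non-negative", call. = FALSE)
  if (config$gwas_enrichment_odds <= 0)
    stop("`gwas_enrichment_odds` must be positive", call. = FALSE)
  if (is.null(names(config$chromosomes)) || any(config$chromosomes < 1))
    stop("`chromosomes` must be a named vector of positive lengths",
         call. = FALSE)
  if (!all(config$cell_types %in% names(config$meth_fraction)))
    stop("`meth_fraction` must name every cell type", call. = FALSE)
  if (!is.null(config$confound_covariate) &&
      !config$confound_covariate %in%
        c("age", "pmi", "ph", "onset", "duration", "antipsychotics"))
    stop("unknown `confound_covariate`", call. = FALSE)
  config
}

#' @export
print.celldmr_config <- function(x, ...) {
  cat("celldmr simulation config:",
      x$n_genes, "genes on", length(x$chromosomes), "chromosome(s);",
      x$n_cases, "cases /", x$n_controls, "controls;",
      "seed", x$seed, "\n")
  invisible(x)
}

# Width of every promoter tile, forced by the upstream/downstream extents.
.tile_width <- function(config) {
  config$promoter_upstream + config$promoter_downstream
}
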