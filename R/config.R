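#' Simulation configuration for the synthetic multi-cohort study
#'
#' Collects every tunable of the synthetic cohort generator and validates it.
#' Defaults encode the stated world the generator emulates: three cohorts
#' (the smallest structure that exercises meta-analysis), case/control arms,
#' schizophrenia-like volumetric shifts of +0.5 SD for lateral-ventricle (LV)
#' volume and -0.5 SD for corpus-callosum (CC) volumes, and genetic effects
#' concentrated in a designated pathway.
#'
#' @param n_cohorts number of cohorts (sites).
#' @param n_cases,n_controls per-cohort arm sizes (recycled to `n_cohorts`).
#' @param n_snps number of simulated SNPs.
#' @param n_genes number of simulated genes.
#' @param n_chrom number of autosomes the genome is split over.
#' @param genome_length total genome length in bp (split evenly over
#'   `n_chrom` chromosomes).
#' @param maf_range length-2 numeric in (0, 0.5]; SNP minor-allele
#'   frequencies are drawn uniformly from this interval.
#' @param h2_target narrow-sense heritability in `[0,1]` of each volume
#'   phenotype (fraction of non-covariate variance that is genetic).
#' @param case_shift_sd named numeric vector of case-minus-control shifts in
#'   control-SD units per raw volume; defaults to +0.5 for LV and -0.5 for
#'   every CC volume.
#' @param pathway_effect_fraction fraction of discovery effect-variance mass
#'   placed on SNPs inside the designated pathway's gene windows.
#' @param enriched_pathway name of the pathway carrying that mass.
#' @param effect_sd per-SNP baseline standard deviation of true log odds
#'   ratios (the total effect-variance budget is `n_snps * effect_sd^2`).
#' @param discovery_n effective sample size of the simulated discovery GWAS;
#'   controls summary-statistic standard errors and hence p-values.
#' @param window_bp gene window in bp used when placing pathway effect mass.
#' @param ld "none" for independent SNPs or "block" for block-exchangeable
#'   LD (autoregressive latent correlation within blocks).
#' @param ld_rho,ld_block_size AR(1) latent correlation and block size used
#'   when `ld = "block"`.
#' @param ambiguous_fraction fraction of SNPs given strand-ambiguous (A/T or
#'   C/G) allele pairs; default 0 so the default world loses no scoring SNPs.
#' @param ancestry_mode "gaussian" (default) simulates the 4 ancestry
#'   components as standard normals; "pca" derives them from the genotype
#'   matrix by principal components.
#' @param clinical_rho named numeric of target (partial) Spearman
#'   correlations between clinical measures and the CC total : LV ratio.
#' @param seed integer seed recorded in the config; generators reseed from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 3L,
                       n_cases = 200L,
                       n_controls = 200L,
                       n_snps = 2000L,
                       n_genes = 60L,
                       n_chrom = 2L,
                       genome_length = 2e7,
                       maf_range = c(0.01, 0.5),
                       h2_target = 0.3,
                       case_shift_sd = c(LV = 0.5,
                                         CC_anterior = -0.5,
                                         CC_mid_anterior = -0.5,
                                         CC_central = -0.5,
                                         CC_mid_posterior = -0.5,
                                         CC_posterior = -0.5,
                                         CC_total = -0.5),
                       pathway_effect_fraction = 0.5,
                       enriched_pathway = "ephrin",
                       effect_sd = 0.05,
                       discovery_n = 8e4,
                       window_bp = 20000,
                       ld = c("none", "block"),
                       ld_rho = 0.6,
                       ld_block_size = 10L,
                       ambiguous_fraction = 0,
                       ancestry_mode = c("gaussian", "pca"),
                       clinical_rho = c(GAF = 0.3, PANSS = -0.25, IQ = 0.2),
                       seed = 1L) {
  ld <- match.arg(ld)
  ancestry_mode <- match.arg(ancestry_mode)
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    n_cases = rep_len(as.integer(n_cases), n_cohorts),
    n_controls = rep_len(as.integer(n_controls), n_cohorts),
    n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes),
    n_chrom = as.integer(n_chrom),
    genome_length = as.numeric(genome_length),
    maf_range = as.numeric(maf_range),
    h2_target = as.numeric(h2_target),
    case_shift_sd = case_shift_sd,
    pathway_effect_fraction = as.numeric(pathway_effect_fraction),
    enriched_pathway = enriched_pathway,
    effect_sd = as.numeric(effect_sd),
    discovery_n = as.numeric(discovery_n),
    window_bp = as.numeric(window_bp),
    ld = ld,
    ld_rho = as.numeric(ld_rho),
    ld_block_size = as.integer(ld_block_size),
    ambiguous_fraction = as.numeric(ambiguous_fraction),
    ancestry_mode = ancestry_mode,
    clinical_rho = clinical_rho,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cohorts < 1L) stop("n_cohorts must be positive", call. = FALSE)
  if (any(cfg$n_cases < 0L) || any(cfg$n_controls < 0L))
    stop("arm sizes must be non-negative", call. = FALSE)
  if (any(cfg$n_cases + cfg$n_controls < 1L))
    stop("each cohort needs at least one individual", call. = FALSE)
  if (cfg$n_snps < 1L || cfg$n_genes < 1L)
    stop("n_snps and n_genes must be positive", call. = FALSE)
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5] and be ordered", call. = FALSE)
  if (cfg$h2_target < 0 || cfg$h2_target > 1)
    stop("h2_target must be in [0, 1]", call. = FALSE)
  if (cfg$pathway_effect_fraction < 0 || cfg$pathway_effect_fraction > 1)
    stop("pathway_effect_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$discovery_n <= 0) stop("discovery_n must be positive", call. = FALSE)
  if (cfg$ambiguous_fraction < 0 || cfg$ambiguous_fraction > 1)
    stop("ambiguous_fraction must be in [0, 1]", call. = FALSE)
  if (any(abs(cfg$clinical_rho) >= 1))
    stop("clinical target correlations must lie in (-1, 1)", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  cohorts: %d (cases %s / controls %s)\n", x$n_cohorts,
              paste(x$n_cases, collapse = ","),
              paste(x$n_controls, collapse = ",")))
  cat(sprintf("  genome: %d SNPs, %d genes on %d chromosomes (%.0f bp)\n",
              x$n_snps, x$n_genes, x$n_chrom, x$genome_length))
  cat(sprintf("  h2_target %.2f, pathway '%s' carries %.0f%% of effect mass\n",
              x$h2_target, x$enriched_pathway,
              100 * x$pathway_effect_fraction))
  cat(sprintf("  LD: %s, seed %d\n", x$ld, x$seed))
  invisible(x)
}
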