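test_that("config validation rejects out-of-range parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(h2_target = 1.2), "h2_target")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_snps = 0), "positive")
  expect_error(sim_config(pathway_effect_fraction = -0.1), "fraction")
  expect_error(sim_config(clinical_rho = c(GAF = 1, PANSS = 0, IQ = 0)),
               "correlations")
})

test_that("genotypes follow Hardy-Weinberg proportions at the drawn MAF", {
  cfg <- sim_config(n_cohorts = 1L, n_cases = 5000, n_controls = 5000,
                    n_snps = 50, maf_range = c(0.2, 0.2), seed = 4)
  g <- simulate_genotypes(cfg)
  # expected genotype frequencies Binomial(2, 0.2): (0.64, 0.32, 0.04)
  freq <- rowMeans(apply(g$dosages, 2, tabulate, nbins = 3) / 10000)
  p0 <- 1 - colSums(apply(g$dosages, 2, tabulate, nbins = 3)) / 10000
  expect_equal(mean(p0), 0.64, tolerance = 0.02)
  expect_equal(freq[1], 0.32, tolerance = 0.03)
  expect_equal(freq[2], 0.04, tolerance = 0.05)
  expect_equal(mean(g$dosages), 2 * 0.2, tolerance = 0.02)

  cfg5 <- sim_config(n_cohorts = 1L, n_cases = 5000, n_controls = 5000,
                     n_snps = 20, maf_range = c(0.5, 0.5), seed = 4)
  expect_equal(mean(simulate_genotypes(cfg5)$dosages), 1, tolerance = 0.02)
})

test_that("generator is deterministic for a fixed seed", {
  cfg <- sim_config(n_cases = 30, n_controls = 30, n_snps = 100,
                    n_genes = 12, seed = 99)
  a <- suppressWarnings(simulate_cohort_study(cfg))
  b <- suppressWarnings(simulate_cohort_study(cfg))
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$phenotypes, b$phenotypes)
  c2 <- suppressWarnings(simulate_cohort_study(
    sim_config(n_cases = 30, n_controls = 30, n_snps = 100,
               n_genes = 12, seed = 100)))
  expect_false(identical(a$genotypes$dosages, c2$genotypes$dosages))
})

test_that("snp map is coordinate-sorted with unique ids and dosages in range", {
  g <- simulate_genotypes(sim_config(n_snps = 500, n_genes = 20, seed = 2))
  expect_false(anyDuplicated(g$snp_map$id) > 0)
  expect_true(all(g$dosages >= 0 & g$dosages <= 2))
  o <- order(g$snp_map$chrom, g$snp_map$pos)
  expect_identical(o, seq_len(nrow(g$snp_map)))
})

test_that("block LD mode induces within-block correlation, HWE margins intact", {
  cfg <- sim_config(n_cohorts = 1L, n_cases = 2000, n_controls = 2000,
                    n_snps = 40, maf_range = c(0.3, 0.3), ld = "block",
                    ld_rho = 0.7, ld_block_size = 10L, seed = 5)
  g <- simulate_genotypes(cfg)
  r_adj <- mean(sapply(c(1:9, 11:19), function(j)
    cor(g$dosages[, j], g$dosages[, j + 1])))
  expect_gt(r_adj, 0.3)
  expect_equal(mean(g$dosages), 0.6, tolerance = 0.02)
})

test_that("pathway_effect_fraction = 1 puts all effect mass inside the pathway", {
  cfg <- sim_config(n_cases = 40, n_controls = 40, n_snps = 300,
                    n_genes = 30, pathway_effect_fraction = 1, seed = 6)
  ann <- simulate_annotation(cfg)
  g <- simulate_genotypes(cfg)
  ss <- simulate_sumstats(g, ann, cfg)
  genes <- ann$genes[ann$genes$name %in% ann$pathways$ephrin, ]
  inside <- ss$id %in% map_snps_to_pathway(g$snp_map, genes,
                                           window = cfg$window_bp)
  expect_true(all(ss$beta_true[!inside] == 0))
  expect_gt(sd(ss$beta_true[inside]), 0)
})

test_that("null summary statistics have uniform p-values", {
  cfg <- sim_config(n_cases = 30, n_controls = 30, n_snps = 5000,
                    n_genes = 40, effect_sd = 0, seed = 8)
  ann <- simulate_annotation(cfg)
  g <- simulate_genotypes(cfg)
  ss <- simulate_sumstats(g, ann, cfg)
  expect_gt(ks.test(ss$p_value, "punif")$p.value, 0.01)
})

test_that("stored p-value equals the two-sided normal tail of beta/se", {
  # closed form: z = 5 gives p = 5.733e-7
  study <- small_study(seed = 21)
  ss <- study$sumstats
  bh <- log(ss$odds_ratio)
  expect_equal(ss$p_value, 2 * pnorm(-abs(bh / ss$se)), tolerance = 1e-12)
  expect_equal(2 * pnorm(-5), 5.733031e-07, tolerance = 1e-6)
})

test_that("empty enriched pathway is a parameter error", {
  cfg <- sim_config(n_cases = 20, n_controls = 20, n_snps = 100,
                    n_genes = 10, enriched_pathway = "no_such_set",
                    seed = 1)
  ann <- simulate_annotation(cfg)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_sumstats(g, ann, cfg), "empty or unknown")
})

test_that("case shift lands at the configured SD separation after harmonization", {
  cfg <- sim_config(n_cohorts = 2L, n_cases = 500, n_controls = 500,
                    n_snps = 200, n_genes = 20, seed = 31)
  study <- suppressWarnings(simulate_cohort_study(cfg))
  harm <- harmonize_phenotypes(study$phenotypes,
                               phenotypes = c("LV", "CC_total"))
  lv <- harm[harm$phenotype == "LV", ]
  cc <- harm[harm$phenotype == "CC_total", ]
  expect_gt(mean(lv$z[lv$diagnosis == "case"], na.rm = TRUE), 0.4)
  expect_lt(mean(lv$z[lv$diagnosis == "case"], na.rm = TRUE), 0.6)
  expect_lt(mean(cc$z[cc$diagnosis == "case"], na.rm = TRUE), -0.4)
  expect_gt(mean(cc$z[cc$diagnosis == "case"], na.rm = TRUE), -0.6)
})

test_that("null world: no significant case/control difference beyond chance", {
  # case_shift 0, no genetic or covariate-borne diagnosis effects: the
  # case/control mean difference should be null-calibrated
  reps <- 60
  pvals <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_cohorts = 1L, n_cases = 80, n_controls = 80,
                      n_snps = 20, n_genes = 4, h2_target = 0,
                      pathway_effect_fraction = 0, effect_sd = 0,
                      case_shift_sd = c(LV = 0), seed = 1000 + r)
    g <- simulate_genotypes(cfg)
    ann <- simulate_annotation(cfg)
    ss <- simulate_sumstats(g, ann, cfg)
    ph <- simulate_phenotypes(g, ss, ann, cfg)
    h <- harmonize_phenotypes(ph, phenotypes = "LV")
    t.test(z ~ diagnosis, data = h)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("clinical generator recovers the target partial rank correlation", {
  cfg <- sim_config(n_cohorts = 2L, n_cases = 500, n_controls = 500,
                    n_snps = 100, n_genes = 10, seed = 13,
                    clinical_rho = c(GAF = 0.3, PANSS = -0.25, IQ = 0))
  study <- suppressWarnings(simulate_cohort_study(cfg))
  harm <- harmonized_wide(
    harmonize_phenotypes(study$phenotypes,
                         phenotypes = "ratio_CC_total_LV"))
  ph <- study$phenotypes
  j <- match(harm$sample_id, ph$sample_id)
  cov <- data.frame(age = ph$age[j], sex = ph$sex[j])
  gaf <- spearman_partial(harm$ratio_CC_total_LV, ph$GAF[j], cov)
  expect_gt(gaf$rho, 0.22)
  expect_lt(gaf$rho, 0.38)
  iq <- spearman_partial(harm$ratio_CC_total_LV, ph$IQ[j], cov)
  expect_lt(abs(iq$rho), 0.07)
  # bounded scales
  expect_true(all(ph$GAF >= 1 & ph$GAF <= 100))
  expect_true(all(is.na(ph$PANSS) | (ph$PANSS >= 30 & ph$PANSS <= 120)))
  expect_true(all(ph$PANSS[ph$diagnosis != "case"] %in% NA))
})

test_that("monotone transform of the clinical measure leaves rho unchanged", {
  study <- small_study(seed = 17)
  harm <- harmonized_wide(
    harmonize_phenotypes(study$phenotypes,
                         phenotypes = "ratio_CC_total_LV"))
  ph <- study$phenotypes
  j <- match(harm$sample_id, ph$sample_id)
  cov <- data.frame(age = ph$age[j], sex = ph$sex[j])
  a <- spearman_partial(harm$ratio_CC_total_LV, ph$GAF[j], cov)
  b <- spearman_partial(harm$ratio_CC_total_LV, exp(ph$GAF[j] / 20), cov)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})
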