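#!/usr/bin/env Rscript
# Stage 4: per-cohort linear models of each harmonized phenotype on each
# standardized PRS (with the full covariate set), inverse-variance
# fixed-effects meta-analysis, and multiple-testing correction under both
# the declared (7 scores x 7 volume phenotypes) and the eigenvalue-based
# effective-count rule.

suppressMessages(library(endopgs))
pheno <- read_phenotypes("results/data/phenotypes.tsv")
harm <- endopgs:::read_tsv_meta("results/harmonized.tsv")
prs <- endopgs:::read_tsv_meta("results/prs.tsv")

assoc <- suppressWarnings(run_associations(harm, prs, pheno))
endopgs:::write_tsv_meta(assoc, "results/associations.tsv")
meta <- meta_analyze_all(assoc)
endopgs:::write_tsv_meta(meta, "results/meta.tsv")

hw <- harmonized_wide(harm)
m_eff_ph <- effective_tests(endopgs:::safe_cor(
  as.matrix(hw[, setdiff(names(hw), "sample_id")])))
m_eff_prs <- effective_tests(endopgs:::safe_cor(
  endopgs:::prs_to_matrix(prs)))
eff <- correct_pvalues(meta, mode = "effective",
                       m_eff_prs = m_eff_prs,
                       m_eff_phenotypes = m_eff_ph)
dec <- correct_pvalues(meta, mode = "declared")
flags <- eff$flags
flags$significant_declared <- dec$flags$significant
endopgs:::write_tsv_meta(flags, "results/significance.tsv")

cat(sprintf("fitted %d cohort cells; pooled %d meta cells\n",
            nrow(assoc), nrow(meta)))
cat(sprintf("effective tests: %.2f phenotypes x %.2f scores -> p < %.2e\n",
            m_eff_ph, m_eff_prs, eff$threshold))
cat(sprintf("declared rule threshold: p < %.2e\n", dec$threshold))
best <- meta[order(meta$p), ][1:5, c("phenotype", "pathway", "threshold",
                                     "beta", "se", "p", "r2_mean")]
cat("strongest pooled associations:\n")
print(best, digits = 3, row.names = FALSE)
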