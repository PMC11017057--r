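#!/usr/bin/env Rscript
# Stage 6: Spearman partial correlations (adjusted for age and sex)
# between clinical/cognitive measures and the harmonized brain phenotypes,
# BH-FDR corrected as one family, plus Table-1-style group descriptives.

suppressMessages(library(endopgs))
pheno <- read_phenotypes("results/data/phenotypes.tsv")
harm <- endopgs:::read_tsv_meta("results/harmonized.tsv")
hw <- harmonized_wide(harm)

clin <- clinical_correlations(hw, pheno)
endopgs:::write_tsv_meta(clin, "results/clinical.tsv")
gaf <- clin[clin$clinical == "GAF", ]
gaf <- gaf[order(-abs(gaf$rho)), ]
cat("strongest GAF correlations (partial Spearman, age/sex adjusted):\n")
print(gaf[1:5, c("phenotype", "rho", "p", "p_fdr", "significant")],
      digits = 2, row.names = FALSE)

desc <- describe_groups(pheno)
endopgs:::write_tsv_meta(desc, "results/descriptives.tsv")
cat("\ngroup descriptives (cases vs controls):\n")
print(desc[, c("variable", "n_case", "n_control", "statistic", "p",
               "test")], digits = 3, row.names = FALSE)
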