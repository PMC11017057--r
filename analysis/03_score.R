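#!/usr/bin/env Rscript
# Stage 3: pathway-restricted polygenic scores. SNPs within 20 kb of each
# gene set are weighted by discovery log odds ratios and summed per
# individual at six discovery p-value thresholds.

suppressMessages(library(endopgs))
geno <- read_dosage_tsv("results/data/genotypes.tsv")
sumstats <- read_sumstats("results/data/sumstats.tsv")
genes <- read_genes_bed("results/data/genes.bed")
sets <- read_gmt("results/data/pathways.gmt")
annotation <- resolve_gene_sets(sets, genes)

prs <- score_pathways(geno, sumstats, annotation)
endopgs:::write_tsv_meta(prs, "results/prs.tsv")

used <- unique(prs[, c("pathway", "threshold", "n_snps")])
cat("SNPs entering each score (per pathway, by threshold):\n")
print(reshape(used, idvar = "pathway", timevar = "threshold",
              direction = "wide"), row.names = FALSE)
cat("scores written to results/prs.tsv\n")
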