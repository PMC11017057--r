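#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-cohort study (3 cohorts x 400,
# schizophrenia-like volumetric shifts, pathway-concentrated genetics)
# and write every interchange file under results/data/.

suppressMessages(library(endopgs))
seed <- 20260918L
cfg <- sim_config(seed = seed)
print(cfg)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
study <- simulate_cohort_study(cfg)

write_dosage_tsv(study$genotypes, file.path(out, "genotypes.tsv"), seed)
write_vcf(study$genotypes, file.path(out, "genotypes.vcf"))
write_sumstats(study$sumstats, file.path(out, "sumstats.tsv"), seed)
write_genes_bed(study$annotation$genes, file.path(out, "genes.bed"))
write_gmt(study$annotation$pathways, file.path(out, "pathways.gmt"))
write_phenotypes(study$phenotypes, file.path(out, "phenotypes.tsv"), seed)

cat(sprintf("simulated %d individuals x %d SNPs across %d cohorts\n",
            nrow(study$genotypes$dosages), ncol(study$genotypes$dosages),
            cfg$n_cohorts))
cat(sprintf("discovery stats: %d SNPs, %d with p < 1e-4\n",
            nrow(study$sumstats), sum(study$sumstats$p_value < 1e-4)))
cat("files written to", out, "\n")
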