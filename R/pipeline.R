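#' Run the full analysis pipeline on a simulated study
#'
#' Executes simulate -> harmonize -> score -> associate -> meta-analyze ->
#' multiple-testing correction -> heritability -> clinical correlation and
#' writes every stage's table under `out_dir` as TSV with metadata
#' headers. Deterministic: the same config and seed produce byte-identical
#' output files.
#'
#' @param config a [sim_config()] object, or a path to a JSON file of
#'   [sim_config()] arguments.
#' @param out_dir output directory (created if absent).
#' @param thresholds discovery p-value grid (default
#'   [default_thresholds()]).
#' @param n_perm heritability permutations (default 0: skip permutation
#'   p-values, which dominate runtime).
#' @param alpha significance level for correction (default 0.05).
#' @return invisible list of the in-memory stage results; side effect: the
#'   output files listed in the `files` element.
#' @export
run_pipeline <- function(config, out_dir,
                         thresholds = default_thresholds(),
                         n_perm = 0L, alpha = 0.05) {
  if (is.character(config)) config <- load_config(config)
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  fp <- function(f) file.path(out_dir, f)

  study <- simulate_cohort_study(config)
  write_dosage_tsv(study$genotypes, fp("genotypes.tsv"), seed)
  write_vcf(study$genotypes, fp("genotypes.vcf"))
  write_sumstats(study$sumstats, fp("sumstats.tsv"), seed)
  write_genes_bed(study$annotation$genes, fp("genes.bed"))
  write_gmt(study$annotation$pathways, fp("pathways.gmt"))
  write_phenotypes(study$phenotypes, fp("phenotypes.tsv"), seed)

  harmonized <- harmonize_phenotypes(study$phenotypes)
  write_tsv_meta(harmonized, fp("harmonized.tsv"), seed)

  prs <- score_pathways(study$genotypes, study$sumstats, study$annotation,
                        window = config$window_bp, thresholds = thresholds)
  write_tsv_meta(prs, fp("prs.tsv"), seed)

  assoc <- run_associations(harmonized, prs, study$phenotypes)
  write_tsv_meta(assoc, fp("associations.tsv"), seed)

  meta <- meta_analyze_all(assoc)
  write_tsv_meta(meta, fp("meta.tsv"), seed)

  harm_wide <- harmonized_wide(harmonized)
  pheno_z <- as.matrix(harm_wide[, intersect(analysis_phenotypes(),
                                             names(harm_wide)),
                                 drop = FALSE])
  prs_wide <- prs_to_matrix(prs)
  corr <- correct_pvalues(
    meta, alpha = alpha, mode = "effective",
    m_eff_prs = effective_tests(safe_cor(prs_wide)),
    m_eff_phenotypes = effective_tests(safe_cor(pheno_z)))
  corr_declared <- correct_pvalues(meta, alpha = alpha, mode = "declared")
  flags <- corr$flags
  flags$threshold_effective <- corr$threshold
  flags$threshold_declared <- corr_declared$threshold
  flags$significant_declared <- corr_declared$flags$significant
  write_tsv_meta(flags, fp("significance.tsv"), seed)

  grm <- compute_grm(study$genotypes)
  h2 <- estimate_h2_all(grm, study$phenotypes, n_perm = n_perm,
                        seed = seed)
  write_tsv_meta(h2, fp("heritability.tsv"), seed)

  clin <- clinical_correlations(harm_wide, study$phenotypes, alpha = alpha)
  write_tsv_meta(clin, fp("clinical.tsv"), seed)

  desc <- describe_groups(study$phenotypes)
  write_tsv_meta(desc, fp("descriptives.tsv"), seed)

  files <- list.files(out_dir, full.names = TRUE)
  invisible(list(study = study, harmonized = harmonized, prs = prs,
                 associations = assoc, meta = meta, significance = flags,
                 heritability = h2, clinical = clin, descriptives = desc,
                 files = files))
}

# correlation matrix over complete pairwise observations, with unit
# diagonal restored for columns that were constant
safe_cor <- function(m) {
  keep <- apply(m, 2, function(x) sd(x, na.rm = TRUE) > 0 &&
                  sum(!is.na(x)) > 2)
  r <- cor(m[, keep, drop = FALSE], use = "pairwise.complete.obs")
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

# individuals x (pathway, threshold) score matrix, standardized columns
prs_to_matrix <- function(prs) {
  ids <- unique(prs$sample_id)
  cells <- unique(prs[, c("pathway", "threshold")])
  out <- matrix(NA_real_, length(ids), nrow(cells))
  colnames(out) <- paste(cells$pathway, cells$threshold, sep = "@")
  for (r in seq_len(nrow(cells))) {
    sub <- prs[prs$pathway == cells$pathway[r] &
                 prs$threshold == cells$threshold[r], ]
    if (all(sub$n_snps == 0L)) next
    out[, r] <- sub$score[match(ids, sub$sample_id)]
  }
  out[, colSums(!is.na(out)) > 0, drop = FALSE]
}

#' Load a simulation config from JSON
#'
#' @param path JSON file whose top-level keys are [sim_config()] argument
#'   names.
#' @return a validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(args), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, args)
}
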