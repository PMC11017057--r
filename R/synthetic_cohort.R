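#' Simulate a gene map and pathway collection
#'
#' Places `n_genes` non-overlapping genes uniformly over the simulated
#' autosomes and partitions them into the named gene sets the pipeline
#' analyses: four signalling pathways (ephrin, axon guidance, long-term
#' potentiation, PKA), a microRNA target set, the single-gene MIR137 set, and
#' the genome-wide set containing every gene.
#'
#' @param config a [sim_config()] object.
#' @return a list with `genes` (data.frame: name, chrom, start, end; 1-based
#'   inclusive coordinates) and `pathways` (named list of gene-name vectors),
#'   of class `pathway_collection`.
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 11L)
  chrom_len <- config$genome_length / config$n_chrom
  n <- config$n_genes
  chrom <- sort(sample.int(config$n_chrom, n, replace = TRUE))
  genes <- do.call(rbind, lapply(seq_len(config$n_chrom), function(ch) {
    k <- sum(chrom == ch)
    if (k == 0L) return(NULL)
    # carve the chromosome into k slots; a gene occupies a random interval
    # well inside its slot so genes never overlap
    slot <- chrom_len / k
    start <- floor((seq_len(k) - 1) * slot +
                     runif(k, 0.1, 0.4) * slot) + 1
    end <- floor(start + runif(k, 0.1, 0.4) * slot)
    data.frame(chrom = ch, start = start, end = end)
  }))
  genes$name <- sprintf("gene%04d", seq_len(n))
  genes <- genes[, c("name", "chrom", "start", "end")]

  # partition: one MIR137 gene, disjoint pathway sets over the rest,
  # a target set that overlaps the pathways (as real target lists do)
  idx <- sample.int(n)
  genes$name[idx[1]] <- "MIR137"
  pool <- genes$name[idx[-1]]
  k <- max(1L, floor(length(pool) / 6))
  take <- function(i) {
    got <- pool[((i - 1) * k + 1):(i * k)]
    got[!is.na(got)]
  }
  pathways <- list(
    ephrin = take(1),
    axon_guidance = take(2),
    LTP = take(3),
    PKA = take(4),
    mir137_targets = unique(c(take(5), take(1)[seq_len(ceiling(k / 2))])),
    mir137_gene = "MIR137",
    genome_wide = genes$name
  )
  structure(list(genes = genes, pathways = pathways),
            class = "pathway_collection")
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws per-SNP minor-allele frequencies uniformly from the configured
#' range and genotypes as the sum of two binomial allele draws, i.e.
#' Binomial(2, maf) counts of the effect (ALT) allele. SNPs are independent
#' by default; with `config$ld = "block"` the two latent gametes are drawn
#' from an AR(1) Gaussian copula within blocks, giving block-exchangeable LD.
#'
#' @param config a [sim_config()] object.
#' @return a `genotype_matrix`: list with `dosages` (individuals x SNPs
#'   matrix, values in `{0,1,2}`), `snp_map` (data.frame: id, chrom, pos,
#'   allele1 = counted/ALT allele, allele2 = REF, maf), `sample_ids`.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 17L)
  m <- config$n_snps
  n <- sum(config$n_cases) + sum(config$n_controls)
  chrom_len <- config$genome_length / config$n_chrom

  chrom <- sort(sample.int(config$n_chrom, m, replace = TRUE))
  pos <- unlist(lapply(seq_len(config$n_chrom), function(ch) {
    k <- sum(chrom == ch)
    sort(sample.int(chrom_len, k))
  }), use.names = FALSE)
  maf <- runif(m, config$maf_range[1], config$maf_range[2])

  unamb <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  amb <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_amb <- runif(m) < config$ambiguous_fraction
  pair <- matrix("", m, 2)
  pair[!is_amb, ] <- unamb[sample.int(nrow(unamb), sum(!is_amb), TRUE), ]
  if (any(is_amb))
    pair[is_amb, ] <- amb[sample.int(nrow(amb), sum(is_amb), TRUE), ]

  if (config$ld == "none") {
    dos <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  } else {
    # two latent gametes per individual; AR(1) correlation within blocks of
    # ld_block_size SNPs; allele = 1 when the latent normal falls below the
    # maf quantile, so marginals stay Binomial(2, maf)
    dos <- matrix(0L, n, m)
    thr <- qnorm(maf)
    blocks <- split(seq_len(m), ceiling(seq_len(m) / config$ld_block_size))
    for (b in blocks) {
      k <- length(b)
      for (g in 1:2) {
        z <- matrix(rnorm(n * k), n, k)
        if (k > 1) {
          for (j in 2:k)
            z[, j] <- config$ld_rho * z[, j - 1] +
              sqrt(1 - config$ld_rho^2) * z[, j]
        }
        dos[, b] <- dos[, b] + (z < rep(thr[b], each = n))
      }
    }
  }

  snp_map <- data.frame(
    id = sprintf("snp%06d", seq_len(m)),
    chrom = chrom,
    pos = pos,
    allele1 = pair[, 1],
    allele2 = pair[, 2],
    maf = maf,
    stringsAsFactors = FALSE
  )
  sample_ids <- sprintf("ind%05d", seq_len(n))
  dimnames(dos) <- list(sample_ids, snp_map$id)
  structure(list(dosages = dos, snp_map = snp_map, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' Simulate discovery GWAS summary statistics
#'
#' Stands in for a large case-control discovery GWAS. True log odds ratios
#' are zero-mean normal, with a configurable fraction of the total
#' effect-variance budget placed on SNPs inside the designated pathway's
#' gene windows. The reported odds ratio is the *observed* (noisy) effect at
#' the discovery sample size, and the p-value is the matching two-sided
#' normal test, so null SNPs yield uniform p-values.
#'
#' @param genotypes a `genotype_matrix`.
#' @param annotation a `pathway_collection` from [simulate_annotation()].
#' @param config a [sim_config()] object.
#' @return a `summary_stats` data.frame: id, chrom, pos, effect_allele,
#'   other_allele, odds_ratio, p_value, plus simulation-truth columns
#'   `beta_true` and `se` (kept in memory, not written by
#'   [write_sumstats()]).
#' @export
simulate_sumstats <- function(genotypes, annotation, config) {
  validate_sim_config(config)
  set.seed(config$seed + 23L)
  map <- genotypes$snp_map
  genes <- annotation$genes
  path_genes <- annotation$pathways[[config$enriched_pathway]]
  if (is.null(path_genes) || length(path_genes) == 0L)
    stop("enriched pathway is empty or unknown: ", config$enriched_pathway,
         call. = FALSE)
  in_path <- map$id %in% map_snps_to_pathway(
    map, genes[genes$name %in% path_genes, ], window = config$window_bp)
  if (all(!in_path) && config$pathway_effect_fraction > 0)
    stop("no SNPs fall inside the enriched pathway's gene windows",
         call. = FALSE)

  m <- nrow(map)
  budget <- m * config$effect_sd^2
  f <- config$pathway_effect_fraction
  sd_in <- if (any(in_path)) sqrt(f * budget / sum(in_path)) else 0
  sd_out <- if (any(!in_path)) sqrt((1 - f) * budget / sum(!in_path)) else 0
  beta_true <- numeric(m)
  beta_true[in_path] <- rnorm(sum(in_path), 0, sd_in)
  beta_true[!in_path] <- rnorm(sum(!in_path), 0, sd_out)

  # SE of a log-OR for a balanced case-control study of discovery_n samples
  se <- 1 / sqrt(2 * map$maf * (1 - map$maf) * 0.25 * config$discovery_n)
  beta_hat <- beta_true + rnorm(m, 0, se)
  p <- 2 * pnorm(-abs(beta_hat) / se)

  out <- data.frame(
    id = map$id, chrom = map$chrom, pos = map$pos,
    effect_allele = map$allele1, other_allele = map$allele2,
    odds_ratio = exp(beta_hat),
    p_value = pmax(p, .Machine$double.xmin),
    beta_true = beta_true, se = se,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Simulate multi-cohort volumetric phenotypes with covariates
#'
#' Builds raw lateral-ventricle and corpus-callosum volumes as
#' cohort baseline + scanner offset + covariate effects + genetic component
#' + diagnosis shift + Gaussian noise. The genetic component is the true-
#' effect weighted dosage score, rescaled so it explains `h2_target` of the
#' non-covariate variance. The case shift is applied in units of the
#' within-cohort *control* standard deviation of the shift-free raw volume,
#' so the post-harmonization case mean lands at the configured shift
#' (schizophrenia-like: LV up ~0.5 SD, CC volumes down ~0.5 SD).
#'
#' @param genotypes a `genotype_matrix`.
#' @param sumstats a `summary_stats` table carrying `beta_true` (falls back
#'   to `log(odds_ratio)` when absent).
#' @param annotation a `pathway_collection`.
#' @param config a [sim_config()] object.
#' @return a `phenotype_table` data.frame: sample_id, cohort, scanner,
#'   diagnosis ("case"/"control"), age, sex, tbv, anc1..anc4, the 7 raw
#'   volumes (mm^3), and the 6 CC:LV ratios added by [compute_ratios()].
#' @export
simulate_phenotypes <- function(genotypes, sumstats, annotation, config) {
  validate_sim_config(config)
  set.seed(config$seed + 31L)
  n <- length(genotypes$sample_ids)
  cohort <- rep(sprintf("cohort%02d", seq_len(config$n_cohorts)),
                times = config$n_cases + config$n_controls)
  diagnosis <- unlist(lapply(seq_len(config$n_cohorts), function(k) {
    c(rep("case", config$n_cases[k]), rep("control", config$n_controls[k]))
  }), use.names = FALSE)

  age <- pmin(pmax(rnorm(n, 35, 12), 16), 80)
  sex <- rbinom(n, 1L, 0.5)                      # 1 = male
  tbv <- rnorm(n, 1.2e6, 1.1e5) + sex * 6e4
  if (config$ancestry_mode == "pca") {
    x <- scale(genotypes$dosages)
    x[is.na(x)] <- 0
    pc <- prcomp(x, rank. = 4L)$x
    anc <- scale(pc)
  } else {
    anc <- matrix(rnorm(n * 4), n, 4)
  }
  colnames(anc) <- paste0("anc", 1:4)

  # one or two scanners per cohort with additive offsets
  scanner <- character(n)
  scanner_offset <- numeric(n)
  for (k in seq_len(config$n_cohorts)) {
    co <- sprintf("cohort%02d", k)
    i <- which(cohort == co)
    n_sc <- 1L + (k %% 2L)
    lab <- sprintf("%s_sc%d", co, sample.int(n_sc, length(i), replace = TRUE))
    scanner[i] <- lab
    off <- rnorm(n_sc, 0, 0.2)
    scanner_offset[i] <- off[as.integer(sub(".*_sc", "", lab))]
  }

  beta <- if ("beta_true" %in% names(sumstats)) sumstats$beta_true
          else log(sumstats$odds_ratio)
  g_raw <- as.vector(genotypes$dosages %*% beta)
  g_std <- if (sd(g_raw) > 0) as.vector(scale(g_raw)) else rep(0, n)

  vols <- c(LV = 8000, CC_anterior = 900, CC_mid_anterior = 700,
            CC_central = 650, CC_mid_posterior = 680, CC_posterior = 950)
  rel_sd <- 0.25   # phenotype SD as a fraction of the baseline volume
  pheno <- data.frame(sample_id = genotypes$sample_ids, cohort = cohort,
                      scanner = scanner, diagnosis = diagnosis,
                      age = age, sex = sex, tbv = tbv, anc,
                      stringsAsFactors = FALSE)
  h2 <- config$h2_target
  cohort_base <- matrix(rnorm(config$n_cohorts * length(vols), 0, 0.3),
                        config$n_cohorts, length(vols))
  age_z <- as.vector(scale(age))
  tbv_z <- as.vector(scale(tbv))

  # diagnosis shift in units of the within-cohort control SD of the
  # shift-free volume, so the post-harmonization case mean lands at the
  # configured value
  apply_shift <- function(x, shift) {
    if (is.null(shift) || is.na(shift) || shift == 0) return(x)
    for (co in unique(cohort)) {
      i <- cohort == co
      s_hc <- sd(x[i & diagnosis == "control"])
      x[i & diagnosis == "case"] <- x[i & diagnosis == "case"] +
        shift * s_hc
    }
    x
  }
  raw0 <- matrix(NA_real_, n, length(vols),
                 dimnames = list(NULL, names(vols)))
  for (j in seq_along(vols)) {
    v <- names(vols)[j]
    core <- sqrt(h2) * g_std * (if (v == "LV") 1 else -1) +
      sqrt(1 - h2) * rnorm(n)
    zvol <- core + scanner_offset +
      cohort_base[as.integer(factor(cohort)), j] +
      0.15 * age_z * (if (v == "LV") 1 else -0.5) +
      0.1 * sex + 0.35 * tbv_z
    raw0[, j] <- vols[j] * (1 + rel_sd * zvol)
  }
  # total CC from the shift-free subregions; each volume (including the
  # total) then gets its own configured diagnosis shift, so every
  # phenotype is calibrated to its case_shift_sd entry
  cc_cols <- setdiff(names(vols), "LV")
  total0 <- rowSums(raw0[, cc_cols, drop = FALSE])
  raw <- raw0
  for (v in names(vols))
    raw[, v] <- pmax(apply_shift(raw0[, v], config$case_shift_sd[v]), 1)
  pheno <- cbind(pheno, as.data.frame(raw))
  pheno$CC_total <- pmax(apply_shift(total0, config$case_shift_sd["CC_total"]), 1)
  class(pheno) <- c("phenotype_table", "data.frame")
  compute_ratios(pheno)
}

#' Simulate clinical and cognitive measures
#'
#' Adds a GAF-like global-functioning score, a PANSS-like symptom total
#' (cases only) and an IQ-like cognitive score, each built on a Gaussian
#' latent with the configured correlation to the standardized CC total : LV
#' ratio plus age/sex confounding, then mapped monotonically to its
#' conventional bounded scale.
#'
#' @param phenotypes a `phenotype_table` with ratio columns.
#' @param config a [sim_config()] object; `config$clinical_rho` holds the
#'   target latent correlations (GAF, PANSS, IQ).
#' @return the phenotype table with `GAF`, `PANSS`, `IQ` columns appended.
#' @export
simulate_clinical <- function(phenotypes, config) {
  validate_sim_config(config)
  if (any(abs(config$clinical_rho) >= 1))
    stop("clinical target correlations must lie in (-1, 1)", call. = FALSE)
  set.seed(config$seed + 41L)
  n <- nrow(phenotypes)
  ratio <- phenotypes$ratio_CC_total_LV
  # standardize within cohort: the analyzed phenotype is the within-cohort
  # harmonized ratio, so the target correlation must be built on that scale
  r_z <- ratio
  for (co in unique(phenotypes$cohort)) {
    i <- phenotypes$cohort == co
    r_z[i] <- (ratio[i] - mean(ratio[i], na.rm = TRUE)) /
      sd(ratio[i], na.rm = TRUE)
  }
  age_z <- as.vector(scale(phenotypes$age))
  sex <- phenotypes$sex

  latent <- function(rho) {
    rho * r_z + sqrt(1 - rho^2) * rnorm(n) - 0.2 * age_z + 0.1 * sex
  }
  rho <- config$clinical_rho
  gaf <- pmin(100, pmax(1, 55 + 15 * latent(rho[["GAF"]])))
  iq <- pmin(160, pmax(55, 100 + 15 * latent(rho[["IQ"]])))
  panss <- pmin(120, pmax(30, 60 + 12 * latent(rho[["PANSS"]])))
  panss[phenotypes$diagnosis != "case"] <- NA_real_

  phenotypes$GAF <- gaf
  phenotypes$PANSS <- panss
  phenotypes$IQ <- iq
  phenotypes
}

#' Simulate a complete multi-cohort study
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_genotypes()], [simulate_sumstats()], [simulate_phenotypes()]
#' and [simulate_clinical()] in order under one configuration.
#'
#' @param config a [sim_config()] object.
#' @return list with `config`, `annotation`, `genotypes`, `sumstats`,
#'   `phenotypes`.
#' @export
simulate_cohort_study <- function(config) {
  annotation <- simulate_annotation(config)
  genotypes <- simulate_genotypes(config)
  sumstats <- simulate_sumstats(genotypes, annotation, config)
  phenotypes <- simulate_phenotypes(genotypes, sumstats, annotation, config)
  phenotypes <- simulate_clinical(phenotypes, config)
  list(config = config, annotation = annotation, genotypes = genotypes,
       sumstats = sumstats, phenotypes = phenotypes)
}
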