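# Independent oracles used across the suite. Each is a deliberately naive
# implementation (loops, normal equations, grid search) kept separate from
# the package's computational path.

# brute-force polygenic score: explicit double loop over (individual, SNP)
oracle_prs <- function(dosages, weights, flip, snp_ids, use_ids) {
  n <- nrow(dosages)
  score <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_along(snp_ids)) {
      if (!(snp_ids[k] %in% use_ids)) next
      d <- dosages[i, snp_ids[k]]
      if (flip[k]) d <- 2 - d
      s <- s + weights[k] * d
    }
    score[i] <- s
  }
  score
}

# OLS via explicit normal equations
oracle_ols <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  list(coef = as.vector(b), resid = as.vector(y - X %*% b))
}

# inverse-variance fixed-effects pooling by direct summation
oracle_ivw <- function(beta, se) {
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  list(beta = b, se = sqrt(1 / sum(w)))
}

# exact Gaussian ML grid search for h2 under y ~ N(0, s2 * (h2 K + (1-h2) I)),
# s2 profiled out; eigen-decomposition of K done once
oracle_h2_grid <- function(K, y, grid = seq(0, 1, by = 0.01)) {
  eig <- eigen(K, symmetric = TRUE)
  z <- as.vector(t(eig$vectors) %*% y)
  n <- length(y)
  ll <- vapply(grid, function(h2) {
    lam <- h2 * eig$values + (1 - h2)
    if (any(lam <= 0)) return(-Inf)
    s2 <- mean(z^2 / lam)
    -0.5 * (sum(log(lam)) + n * log(s2) + n)
  }, numeric(1))
  grid[which.max(ll)]
}

# genotypes with family structure: members copy most founder dosages, so
# the GRM has strong blocks and h2 is identifiable at small n
related_genotypes <- function(n_fam, fam_size, m, copy_p, maf = 0.3) {
  founders <- matrix(rbinom(n_fam * m, 2, maf), n_fam, m)
  d <- matrix(0L, n_fam * fam_size, m)
  for (f in seq_len(n_fam)) {
    for (k in seq_len(fam_size)) {
      keep <- runif(m) < copy_p
      d[(f - 1) * fam_size + k, ] <- ifelse(keep, founders[f, ],
                                            rbinom(m, 2, maf))
    }
  }
  d
}

# small genotype_matrix fixture with controllable dosages
toy_genotypes <- function(dosages, chrom = 1L, pos = NULL,
                          allele1 = NULL, allele2 = NULL, maf = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(allele1)) allele1 <- rep("A", m)
  if (is.null(allele2)) allele2 <- rep("G", m)
  if (is.null(maf)) maf <- colMeans(dosages) / 2
  ids <- sprintf("snp%03d", seq_len(m))
  colnames(dosages) <- ids
  rownames(dosages) <- sprintf("ind%03d", seq_len(nrow(dosages)))
  structure(list(
    dosages = dosages,
    snp_map = data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos,
                         allele1 = allele1, allele2 = allele2, maf = maf,
                         stringsAsFactors = FALSE),
    sample_ids = rownames(dosages)), class = "genotype_matrix")
}

# small summary_stats fixture aligned with a snp_map
toy_sumstats <- function(snp_map, odds_ratio, p_value = NULL,
                         effect_allele = snp_map$allele1,
                         other_allele = snp_map$allele2) {
  if (is.null(p_value)) p_value <- rep(0.5, nrow(snp_map))
  out <- data.frame(id = snp_map$id, chrom = snp_map$chrom,
                    pos = snp_map$pos, effect_allele = effect_allele,
                    other_allele = other_allele, odds_ratio = odds_ratio,
                    p_value = p_value, stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

# a small complete simulated study shared by several files
small_study <- function(seed = 11L, ...) {
  cfg <- sim_config(n_cases = 50, n_controls = 50, n_snps = 200,
                    n_genes = 24, seed = seed, ...)
  suppressWarnings(simulate_cohort_study(cfg))
}
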