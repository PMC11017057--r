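#' Genetic relationship matrix from dosages
#'
#' `K = X X' / M` where column `j` of `X` is the dosage vector of SNP `j`
#' centered at twice its sample allele frequency and scaled by
#' `sqrt(2 p (1 - p))`. Monomorphic SNPs and SNPs below the MAF floor are
#' excluded. Because columns are centered at the sample mean, rows of `K`
#' sum to (numerically) zero, and the diagonal averages ~1 for unrelated
#' samples in Hardy-Weinberg proportions.
#'
#' @param genotypes a `genotype_matrix`, or a plain dosage matrix
#'   (individuals x SNPs).
#' @param maf_min minor-allele-frequency floor (default 0.01).
#' @return list of class `grm`: `K` (n x n symmetric), `n_snps`,
#'   `sample_ids`.
#' @export
compute_grm <- function(genotypes, maf_min = 0.01) {
  d <- if (is.list(genotypes)) genotypes$dosages else genotypes
  ids <- if (is.list(genotypes)) genotypes$sample_ids else rownames(d)
  if (nrow(d) < 2L) stop("need at least 2 individuals", call. = FALSE)
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- is.finite(maf) & maf >= maf_min & maf > 0
  if (!any(keep))
    stop("no polymorphic SNPs above the MAF floor", call. = FALSE)
  x <- d[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(x, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  if (anyNA(x)) x[is.na(x)] <- 0
  K <- tcrossprod(x) / ncol(x)
  structure(list(K = K, n_snps = ncol(x), sample_ids = ids), class = "grm")
}

#' Project a phenotype onto the orthogonal complement of the covariates
#'
#' Least-squares residuals of the phenotype on the covariate design (an
#' intercept is always included), standardized to unit variance —
#' heritability is a variance fraction, so the scale is immaterial but a
#' unit-variance working phenotype makes the Haseman-Elston slope directly
#' interpretable as h^2.
#'
#' @param pheno numeric phenotype vector.
#' @param covariates data.frame/matrix of covariates, or NULL for
#'   intercept-only (centering).
#' @return list: `resid` (standardized residuals, NA where inputs missing),
#'   `rank` (projection rank).
#' @export
project_covariates <- function(pheno, covariates = NULL) {
  n <- length(pheno)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1)
    cc <- !is.na(pheno)
  } else {
    df <- as.data.frame(covariates)
    X <- model.matrix(~ ., data = df)
    cc <- !is.na(pheno) & complete.cases(df)
  }
  qrX <- qr(X[cc, , drop = FALSE])
  if (qrX$rank < ncol(X))
    warning("rank-deficient covariate design; collinear column(s) ignored",
            call. = FALSE)
  r <- qr.resid(qrX, pheno[cc])
  s <- sd(r)
  if (!is.finite(s) || s < 1e-10)
    stop("phenotype lies in the covariate span; nothing to estimate",
         call. = FALSE)
  out <- rep(NA_real_, n)
  out[cc] <- r / s
  list(resid = out, rank = qrX$rank)
}

# Haseman-Elston slope from the pairwise regression of phenotype
# cross-products y_i y_j on kinship K_ij over i < j, in closed form via
# matrix identities (sums over ordered pairs; duplication cancels).
he_slope <- function(K, y, diag_K = diag(K), fro2 = sum(K^2),
                     sum_K = sum(K)) {
  n <- length(y)
  N <- n * (n - 1)                       # ordered off-diagonal pairs
  s_k <- sum_K - sum(diag_K)
  s_kk <- fro2 - sum(diag_K^2)
  sy <- sum(y); sy2 <- sum(y^2)
  s_q <- sy^2 - sy2
  s_qq <- (sy2)^2 - sum(y^4)
  s_kq <- as.vector(crossprod(y, K %*% y)) - sum(diag_K * y^2)
  sxx <- s_kk - s_k^2 / N
  sxy <- s_kq - s_k * s_q / N
  syy <- s_qq - s_q^2 / N
  slope <- sxy / sxx
  list(slope = slope, sxx = sxx, sxy = sxy, syy = syy, N = N)
}

#' SNP heritability by Haseman-Elston regression on the GRM
#'
#' Moment estimator of the variance fraction attributable to common SNPs
#' under the linear mixed model `y = g + e`, `cov(g) = h^2 K`: the slope of
#' the regression of phenotypic cross-products `y_i y_j` on kinship `K_ij`
#' over all pairs `i < j`, computed in closed form. With a unit-variance
#' working phenotype the slope estimates `h^2` directly. The standard error
#' is the OLS sampling formula of that pairwise regression (under
#' independence of individuals the cross-product pairs are uncorrelated, so
#' the formula is exact at h^2 = 0 and approximate otherwise). The point
#' estimate is clipped to `[0, 1]`; the unclipped value and a normal 95% CI
#' (from the unclipped estimate) are retained.
#'
#' @param grm a `grm` object (or bare n x n matrix).
#' @param pheno residualized, standardized phenotype (see
#'   [project_covariates()]); NAs excluded pairwise-consistently by
#'   dropping those individuals.
#' @return data.frame of class `h2_estimate`: h2, h2_unclipped, se, ci_lo,
#'   ci_hi (unclipped normal CI), n, n_snps.
#' @export
estimate_h2 <- function(grm, pheno) {
  K <- if (is.list(grm)) grm$K else grm
  n_snps <- if (is.list(grm)) grm$n_snps else NA_integer_
  ok <- !is.na(pheno)
  y <- pheno[ok]
  K <- K[ok, ok, drop = FALSE]
  n <- length(y)
  if (n < 10L) stop("too few individuals for heritability", call. = FALSE)
  offd <- K[upper.tri(K)]
  if (sd(offd) < 1e-12) {
    warning("GRM off-diagonals nearly constant; estimate unstable",
            call. = FALSE)
    return(data.frame(h2 = NA_real_, h2_unclipped = NA_real_, se = Inf,
                      ci_lo = -Inf, ci_hi = Inf, n = n, n_snps = n_snps))
  }
  he <- he_slope(K, y)
  m <- he$N / 2                          # unordered pairs
  rss <- (he$syy - he$slope * he$sxy) / 2
  sigma2 <- rss / (m - 2)
  se <- sqrt(sigma2 / (he$sxx / 2))
  h2u <- he$slope
  data.frame(h2 = min(1, max(0, h2u)), h2_unclipped = h2u, se = se,
             ci_lo = h2u - 1.96 * se, ci_hi = h2u + 1.96 * se,
             n = n, n_snps = n_snps)
}

#' Permutation p-value for a heritability estimate
#'
#' Permutes the residualized phenotype across individuals (breaking the
#' phenotype-kinship link while preserving the phenotype distribution),
#' re-estimates the Haseman-Elston slope for each permutation, and returns
#' the add-one permutation p-value
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)`.
#'
#' @param grm a `grm` object (or bare matrix).
#' @param pheno residualized standardized phenotype.
#' @param n_perm number of permutations (>= 100; default 500).
#' @param seed RNG seed.
#' @return list: `p`, `observed` (unclipped slope), `perm` (permutation
#'   slopes).
#' @export
permutation_pvalue <- function(grm, pheno, n_perm = 500L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  K <- if (is.list(grm)) grm$K else grm
  ok <- !is.na(pheno)
  y <- pheno[ok]
  K <- K[ok, ok, drop = FALSE]
  diag_K <- diag(K); fro2 <- sum(K^2); sum_K <- sum(K)
  obs <- he_slope(K, y, diag_K, fro2, sum_K)$slope
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    he_slope(K, y[sample.int(length(y))], diag_K, fro2, sum_K)$slope
  }, numeric(1))
  list(p = (1 + sum(perm >= obs)) / (1 + n_perm), observed = obs,
       perm = perm)
}

#' Heritability of every analysis phenotype
#'
#' Runs [project_covariates()] + [estimate_h2()] (and optionally the
#' permutation test) for each phenotype column, sharing one GRM.
#'
#' @param grm a `grm` object.
#' @param table a `phenotype_table`; rows must align with the GRM's
#'   `sample_ids`.
#' @param phenotypes phenotype columns (default the 13 analysis
#'   phenotypes present).
#' @param covariates covariate data.frame (default [build_covariates()]).
#' @param n_perm permutations for the p-value; 0 disables (default 0).
#' @param seed RNG seed for permutations.
#' @return data.frame: phenotype, h2, h2_unclipped, se, ci_lo, ci_hi,
#'   p_perm, n, n_snps.
#' @export
estimate_h2_all <- function(grm, table,
                            phenotypes = intersect(analysis_phenotypes(),
                                                   names(table)),
                            covariates = build_covariates(table),
                            n_perm = 0L, seed = 1L) {
  stopifnot(identical(as.character(table$sample_id),
                      as.character(grm$sample_ids)))
  out <- lapply(phenotypes, function(ph) {
    pr <- project_covariates(table[[ph]], covariates)
    est <- estimate_h2(grm, pr$resid)
    est$p_perm <- if (n_perm > 0L)
      permutation_pvalue(grm, pr$resid, n_perm, seed)$p else NA_real_
    cbind(data.frame(phenotype = ph, stringsAsFactors = FALSE), est)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
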