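#' Build the standard covariate design for association models
#'
#' Age, sex, age^2, age x sex, age^2 x sex, total brain volume, scanner
#' dummies (for multi-scanner cohorts) and the four ancestry components.
#' Age is centered before powers are formed to tame collinearity.
#'
#' @param table a `phenotype_table` (or any data.frame with age, sex, tbv,
#'   anc1..anc4, scanner).
#' @return data.frame of covariate columns aligned with `table` rows.
#' @export
build_covariates <- function(table) {
  age_c <- table$age - mean(table$age, na.rm = TRUE)
  cov <- data.frame(
    age = age_c,
    sex = table$sex,
    age2 = age_c^2,
    age_sex = age_c * table$sex,
    age2_sex = age_c^2 * table$sex,
    tbv = table$tbv,
    anc1 = table$anc1, anc2 = table$anc2,
    anc3 = table$anc3, anc4 = table$anc4
  )
  if ("scanner" %in% names(table) &&
      length(unique(table$scanner)) > 1L) {
    sc <- model.matrix(~ factor(scanner), data = table)[, -1, drop = FALSE]
    colnames(sc) <- paste0("scanner", seq_len(ncol(sc)))
    cov <- cbind(cov, sc)
  }
  cov
}

#' Per-cohort association of a harmonized phenotype with a polygenic score
#'
#' Ordinary least squares of the harmonized z-score on the PRS plus the
#' full covariate set, on complete cases. The PRS is standardized to mean 0,
#' SD 1 within the cohort first, so betas are comparable across cohorts for
#' pooling. Variance explained is reported as incremental R^2: R^2 of the
#' full model minus R^2 of the covariate-only model on the same cases.
#'
#' @param z numeric harmonized phenotype values for one cohort.
#' @param prs numeric polygenic score, same length.
#' @param covariates data.frame of covariates, same rows.
#' @param min_n minimum complete cases over model parameters (default
#'   parameters + 10).
#' @return one-row data.frame: beta, se, p, r2_inc, r2_full, n — or NULL
#'   (with a warning) when the cohort is skipped.
#' @export
fit_cohort_association <- function(z, prs, covariates, min_n = NULL) {
  cc <- !is.na(z) & !is.na(prs) & complete.cases(covariates)
  X <- model.matrix(~ ., data = as.data.frame(covariates)[cc, , drop = FALSE])
  n <- sum(cc)
  if (is.null(min_n)) min_n <- ncol(X) + 11L
  if (n < min_n || sd(prs[cc]) == 0) {
    warning("cohort skipped: too few complete cases or constant PRS",
            call. = FALSE)
    return(NULL)
  }
  prs_z <- as.vector(scale(prs[cc]))
  # drop collinear covariate columns (keep intercept and PRS)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("collinear covariate column(s) dropped: ",
            paste(colnames(X)[-keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  y <- z[cc]
  fit_full <- lm.fit(cbind(PRS = prs_z, X), y)
  fit_cov <- lm.fit(X, y)
  rss_full <- sum(fit_full$residuals^2)
  rss_cov <- sum(fit_cov$residuals^2)
  tss <- sum((y - mean(y))^2)
  p_full <- fit_full$rank
  sigma2 <- rss_full / (n - p_full)
  XtX_inv <- chol2inv(chol(crossprod(cbind(PRS = prs_z, X))))
  se <- sqrt(sigma2 * XtX_inv[1, 1])
  beta <- fit_full$coefficients["PRS"]
  tval <- beta / se
  data.frame(beta = unname(beta), se = se,
             p = 2 * pt(-abs(tval), df = n - p_full),
             r2_inc = max(0, (rss_cov - rss_full) / tss),
             r2_full = 1 - rss_full / tss,
             n = n)
}

#' Run all per-cohort associations over phenotypes and score profiles
#'
#' Loops over every (cohort, phenotype, pathway, threshold) cell, fitting
#' [fit_cohort_association()] with the standard covariates built per cohort.
#' Cases and controls are analyzed together (the primary configuration);
#' pass `diagnosis_subset` to stratify.
#'
#' @param harmonized output of [harmonize_phenotypes()].
#' @param prs_profile output of [score_pathways()].
#' @param table the `phenotype_table` (covariate source).
#' @param diagnosis_subset optional character vector, e.g. "case".
#' @return data.frame of class `association_results`: cohort, phenotype,
#'   pathway, threshold, beta, se, p, r2_inc, r2_full, n.
#' @export
run_associations <- function(harmonized, prs_profile, table,
                             diagnosis_subset = NULL) {
  if (!is.null(diagnosis_subset))
    table <- table[table$diagnosis %in% diagnosis_subset, , drop = FALSE]
  out <- list()
  cells <- unique(prs_profile[, c("pathway", "threshold")])
  for (co in unique(table$cohort)) {
    tco <- table[table$cohort == co, , drop = FALSE]
    cov <- build_covariates(tco)
    for (ph in unique(harmonized$phenotype)) {
      hsub <- harmonized[harmonized$phenotype == ph, ]
      z <- hsub$z[match(tco$sample_id, hsub$sample_id)]
      for (r in seq_len(nrow(cells))) {
        pw <- cells$pathway[r]; th <- cells$threshold[r]
        psub <- prs_profile[prs_profile$pathway == pw &
                              prs_profile$threshold == th, ]
        if (all(psub$n_snps == 0L)) next
        prs <- psub$score[match(tco$sample_id, psub$sample_id)]
        fit <- withCallingHandlers(
          fit_cohort_association(z, prs, cov),
          warning = function(w) invokeRestart("muffleWarning"))
        if (is.null(fit)) next
        out[[length(out) + 1L]] <- cbind(
          data.frame(cohort = co, phenotype = ph, pathway = pw,
                     threshold = th, stringsAsFactors = FALSE),
          fit)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("association_results", "data.frame")
  res
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Pools per-cohort betas with weights `w_k = 1/SE_k^2`:
#' pooled beta `= sum(w b) / sum(w)`, pooled SE `= 1/sqrt(sum(w))`, p from
#' the normal approximation. Cochran's Q and I^2 quantify heterogeneity;
#' variance explained is summarized as the unweighted mean of the cohort
#' incremental R^2 values. An optional DerSimonian-Laird random-effects
#' mode inflates the weights by the method-of-moments tau^2.
#'
#' @param beta,se numeric vectors of cohort estimates and standard errors.
#' @param r2 optional cohort incremental R^2 values to average.
#' @param method "fixed" (default) or "random" (DerSimonian-Laird).
#' @return one-row data.frame: beta, se, p, q, q_df, i2, r2_mean, tau2,
#'   n_cohorts. Cohorts with non-positive or missing SE are excluded with
#'   a warning.
#' @export
meta_analyze <- function(beta, se, r2 = NULL, method = c("fixed", "random")) {
  method <- match.arg(method)
  ok <- is.finite(beta) & is.finite(se) & se > 0
  if (any(!ok))
    warning(sum(!ok), " cohort(s) excluded from pooling (bad SE)",
            call. = FALSE)
  beta <- beta[ok]; se <- se[ok]
  k <- length(beta)
  if (k == 0L) stop("no cohorts to pool", call. = FALSE)
  w <- 1 / se^2
  b_fe <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - b_fe)^2)
  q_df <- k - 1L
  i2 <- if (q_df > 0) max(0, (q - q_df) / q) else NA_real_
  tau2 <- 0
  if (method == "random" && q_df > 0) {
    tau2 <- max(0, (q - q_df) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (se^2 + tau2)
  }
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  data.frame(beta = b, se = s, p = 2 * pnorm(-abs(b / s)),
             q = q, q_df = q_df, i2 = i2,
             r2_mean = if (is.null(r2)) NA_real_ else mean(r2, na.rm = TRUE),
             tau2 = tau2, n_cohorts = k)
}

#' Meta-analyze every (phenotype, pathway, threshold) cell
#'
#' @param results an `association_results` table.
#' @param method pooling mode, see [meta_analyze()].
#' @return data.frame of class `meta_results` with one row per cell.
#' @export
meta_analyze_all <- function(results, method = "fixed") {
  key <- interaction(results$phenotype, results$pathway, results$threshold,
                     drop = TRUE)
  out <- lapply(split(results, key), function(d) {
    cbind(d[1, c("phenotype", "pathway", "threshold")],
          meta_analyze(d$beta, d$se, d$r2_inc, method = method))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("meta_results", "data.frame")
  res
}

#' Effective number of independent tests (Li & Ji)
#'
#' Eigenvalue-based effective test count for a family of correlated tests:
#' `M_eff = sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`
#' over the eigenvalues of the correlation matrix. Equals M for identity
#' (independent tests) and 1 for a rank-one (perfectly correlated) family.
#'
#' @param correlation_matrix symmetric correlation matrix with unit
#'   diagonal.
#' @return scalar M_eff in `[1, M]`.
#' @export
effective_tests <- function(correlation_matrix) {
  m <- as.matrix(correlation_matrix)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  lambda <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  # epsilon-tolerant floor: an eigenvalue computed as 2.9999999999999996
  # must contribute 1 + 0, not 1 + 0.9999...
  eps <- 1e-10
  m_eff <- sum((lambda >= 1 - eps) + (lambda - floor(lambda + eps)))
  min(max(m_eff, 1), nrow(m))
}

#' Multiple-testing correction across phenotypes and scores
#'
#' Two modes for the per-test significance threshold at family level
#' `alpha`:
#' * `"declared"` — a fixed declared count: `alpha / (n_prs * n_phenotypes)`
#'   with the defaults 7 scores (1 genome-wide PRS + 1 MIR137 gene score +
#'   5 pathway scores) x 7 volume phenotypes (ratios not counted as
#'   independent phenotypes), i.e. `0.05 / 49`.
#' * `"effective"` — `alpha / (M_eff_prs * M_eff_phenotypes)` with
#'   eigenvalue-based effective counts from [effective_tests()].
#'
#' The six thresholds of one score count as a single test: each
#' (phenotype, pathway) cell is flagged on its minimum pooled p.
#'
#' @param meta a `meta_results` table.
#' @param alpha family-wise level in (0, 1), default 0.05.
#' @param mode "declared" or "effective".
#' @param n_prs,n_phenotypes declared counts (defaults 7 and 7).
#' @param m_eff_prs,m_eff_phenotypes effective counts for mode
#'   "effective".
#' @return list with `threshold` (the per-test p threshold) and `flags`
#'   (data.frame phenotype, pathway, min_p, significant).
#' @export
correct_pvalues <- function(meta, alpha = 0.05,
                            mode = c("declared", "effective"),
                            n_prs = 7, n_phenotypes = 7,
                            m_eff_prs = NULL, m_eff_phenotypes = NULL) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  thr <- if (mode == "declared") {
    alpha / (n_prs * n_phenotypes)
  } else {
    stopifnot(!is.null(m_eff_prs), !is.null(m_eff_phenotypes))
    alpha / (m_eff_prs * m_eff_phenotypes)
  }
  key <- interaction(meta$phenotype, meta$pathway, drop = TRUE)
  flags <- do.call(rbind, lapply(split(meta, key), function(d) {
    data.frame(phenotype = d$phenotype[1], pathway = d$pathway[1],
               min_p = min(d$p), significant = min(d$p) < thr,
               stringsAsFactors = FALSE)
  }))
  rownames(flags) <- NULL
  list(threshold = thr, flags = flags)
}
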