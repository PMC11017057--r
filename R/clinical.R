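#' Spearman partial correlation adjusted for covariates
#'
#' Rank-transforms both variables (average ranks for ties), residualizes
#' each on the covariates (default age and sex) by OLS with intercept, and
#' returns the Pearson correlation of the rank residuals — the standard
#' operationalization of a partial Spearman correlation. The p-value uses
#' the t approximation with `n - 2 - k` degrees of freedom (`k` =
#' number of covariate columns).
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of adjustment variables (NULL for
#'   an unadjusted Spearman correlation).
#' @return one-row data.frame: rho, p, n, df. `rho` is NA (with a warning)
#'   when either variable is constant after complete-case filtering.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  cc <- !is.na(x) & !is.na(y)
  k <- 0L
  if (!is.null(covariates)) {
    df <- as.data.frame(covariates)
    cc <- cc & complete.cases(df)
    df <- df[cc, , drop = FALSE]
    k <- ncol(model.matrix(~ ., data = df)) - 1L
  }
  n <- sum(cc)
  if (n < 5L) stop("need at least 5 complete cases", call. = FALSE)
  xr <- rank(x[cc]); yr <- rank(y[cc])
  if (sd(xr) == 0 || sd(yr) == 0) {
    warning("constant variable; correlation undefined", call. = FALSE)
    return(data.frame(rho = NA_real_, p = NA_real_, n = n,
                      df = n - 2L - k))
  }
  if (k > 0L) {
    X <- model.matrix(~ ., data = df)
    qrX <- qr(X)
    xr <- qr.resid(qrX, xr)
    yr <- qr.resid(qrX, yr)
  } else {
    xr <- xr - mean(xr); yr <- yr - mean(yr)
  }
  rho <- sum(xr * yr) / sqrt(sum(xr^2) * sum(yr^2))
  dfree <- n - 2L - k
  tval <- rho * sqrt(dfree / max(1e-300, 1 - rho^2))
  data.frame(rho = rho, p = 2 * pt(-abs(tval), dfree), n = n, df = dfree)
}

#' Correlate clinical measures with harmonized brain phenotypes
#'
#' Spearman partial correlations, adjusted for age and sex, between each
#' clinical/cognitive measure and each harmonized phenotype, with
#' Benjamini-Hochberg FDR over the whole family of pairs.
#'
#' @param harm_wide wide harmonized z table (see [harmonized_wide()]).
#' @param table `phenotype_table` with clinical columns and age/sex.
#' @param clinical clinical column names (default GAF, PANSS, IQ present).
#' @param phenotypes phenotype columns (default all z columns).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return data.frame of class `clinical_correlations`: phenotype,
#'   clinical, rho, p, n, p_fdr, significant.
#' @export
clinical_correlations <- function(harm_wide, table,
                                  clinical = intersect(c("GAF", "PANSS", "IQ"),
                                                       names(table)),
                                  phenotypes = setdiff(names(harm_wide),
                                                       "sample_id"),
                                  alpha = 0.05) {
  j <- match(harm_wide$sample_id, table$sample_id)
  cov <- data.frame(age = table$age[j], sex = table$sex[j])
  out <- list()
  for (cl in clinical) {
    yv <- table[[cl]][j]
    for (ph in phenotypes) {
      res <- tryCatch(
        spearman_partial(harm_wide[[ph]], yv, cov),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(res)) next
      out[[length(out) + 1L]] <- cbind(
        data.frame(phenotype = ph, clinical = cl, stringsAsFactors = FALSE),
        res[, c("rho", "p", "n")])
    }
  }
  res <- do.call(rbind, out)
  fdr <- fdr_correct(res$p, alpha)
  res$p_fdr <- fdr$p_adjusted
  res$significant <- fdr$flag
  rownames(res) <- NULL
  class(res) <- c("clinical_correlations", "data.frame")
  res
}

#' Pearson chi-squared test from a 2x2 count table
#'
#' Without continuity correction, df = 1. Used to reproduce categorical
#' group-difference statistics (e.g. sex by diagnosis) from printed counts.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return one-row data.frame: statistic, df, p.
#' @export
chi2_from_counts <- function(table) {
  m <- as.matrix(table)
  stopifnot(nrow(m) == 2L, ncol(m) == 2L, all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins must be positive", call. = FALSE)
  expd <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expd)^2 / expd)
  data.frame(statistic = stat, df = 1L, p = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Two-group ANOVA F from summary statistics
#'
#' One-way two-group F computed from group sizes, means and SDs — equal to
#' the square of the pooled-variance two-sample t statistic; df = (1,
#' n1 + n2 - 2). Reproduces quantitative group-difference statistics from
#' printed summaries (exact up to rounding of the printed means/SDs).
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 group summaries (n >= 2, sd > 0).
#' @return one-row data.frame: statistic, df1, df2, p.
#' @export
f_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  df2 <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df2
  f <- (mean1 - mean2)^2 / (sp2 * (1 / n1 + 1 / n2))
  data.frame(statistic = f, df1 = 1L, df2 = df2,
             p = pf(f, 1L, df2, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up adjusted p-values over one family; flags where the adjusted p
#' falls below `alpha`.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list: `p_adjusted`, `flag` (logical).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  padj <- p.adjust(p, method = "BH")
  list(p_adjusted = padj, flag = !is.na(padj) & padj < alpha)
}

#' Group descriptives table (Table-1 style)
#'
#' Per-diagnosis n, mean, SD and range for quantitative variables plus the
#' two-group F (from the raw values' summaries) and, for sex, counts and
#' the chi-squared statistic.
#'
#' @param table a `phenotype_table`.
#' @param variables quantitative columns (default age, tbv, clinical
#'   measures present).
#' @return data.frame with one row per variable: group summaries,
#'   statistic, df, p, and `test` ("F" or "chi2").
#' @export
describe_groups <- function(table,
                            variables = intersect(
                              c("age", "tbv", "GAF", "PANSS", "IQ"),
                              names(table))) {
  ca <- table[table$diagnosis == "case", , drop = FALSE]
  co <- table[table$diagnosis == "control", , drop = FALSE]
  rows <- lapply(variables, function(v) {
    x <- ca[[v]][!is.na(ca[[v]])]; y <- co[[v]][!is.na(co[[v]])]
    if (length(x) < 2L || length(y) < 2L || sd(x) == 0 || sd(y) == 0)
      return(data.frame(variable = v, n_case = length(x),
                        mean_case = mean(x), sd_case = sd(x),
                        n_control = length(y), mean_control = mean(y),
                        sd_control = sd(y), statistic = NA_real_,
                        df = NA_real_, p = NA_real_, test = "F",
                        stringsAsFactors = FALSE))
    f <- f_from_summary(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
    data.frame(variable = v, n_case = length(x), mean_case = mean(x),
               sd_case = sd(x), n_control = length(y),
               mean_control = mean(y), sd_control = sd(y),
               statistic = f$statistic, df = f$df2, p = f$p, test = "F",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("sex" %in% names(table)) {
    tab <- rbind(c(sum(ca$sex == 0, na.rm = TRUE), sum(ca$sex == 1, na.rm = TRUE)),
                 c(sum(co$sex == 0, na.rm = TRUE), sum(co$sex == 1, na.rm = TRUE)))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ch <- chi2_from_counts(tab)
      out <- rbind(out, data.frame(
        variable = "sex", n_case = sum(tab[1, ]), mean_case = NA_real_,
        sd_case = NA_real_, n_control = sum(tab[2, ]),
        mean_control = NA_real_, sd_control = NA_real_,
        statistic = ch$statistic, df = ch$df, p = ch$p, test = "chi2",
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
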