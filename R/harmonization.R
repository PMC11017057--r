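#' Names of the 13 analysis phenotypes
#'
#' Seven raw volumes (lateral ventricles, five corpus-callosum subregions,
#' total corpus callosum) and the six CC:LV ratios.
#'
#' @return character vector of column names.
#' @export
analysis_phenotypes <- function() {
  c(volume_phenotypes(), ratio_phenotypes())
}

#' @rdname analysis_phenotypes
#' @export
volume_phenotypes <- function() {
  c("LV", "CC_anterior", "CC_mid_anterior", "CC_central",
    "CC_mid_posterior", "CC_posterior", "CC_total")
}

#' @rdname analysis_phenotypes
#' @export
ratio_phenotypes <- function() {
  paste0("ratio_", c("CC_anterior", "CC_mid_anterior", "CC_central",
                     "CC_mid_posterior", "CC_posterior", "CC_total"), "_LV")
}

#' Compute CC:LV ratio phenotypes on raw volumes
#'
#' For each corpus-callosum subregion and the total, adds the ratio of its
#' raw volume to the raw lateral-ventricle volume. Ratios are computed on
#' raw volumes *before* any standardization. Records with missing,
#' zero or negative LV volume get `NA` ratios and are flagged.
#'
#' @param table a `phenotype_table` with the seven raw volume columns.
#' @return the table with six `ratio_<CC>_LV` columns and a logical
#'   `ratio_invalid` column.
#' @export
compute_ratios <- function(table) {
  stopifnot(is.data.frame(table), "LV" %in% names(table))
  lv <- table$LV
  bad <- is.na(lv) | lv <= 0
  if (any(bad, na.rm = TRUE))
    warning(sum(bad), " record(s) with non-positive or missing LV; ",
            "ratios set to NA", call. = FALSE)
  for (v in setdiff(volume_phenotypes(), "LV")) {
    if (!v %in% names(table)) next
    r <- table[[v]] / lv
    r[bad] <- NA_real_
    table[[paste0("ratio_", v, "_LV")]] <- r
  }
  table$ratio_invalid <- bad
  if (!inherits(table, "phenotype_table"))
    class(table) <- c("phenotype_table", class(table))
  table
}

#' Control-referenced z-scores within one cohort
#'
#' Standardizes a phenotype against the cohort's *control* distribution:
#' `Z_i = (x_i - M_HC) / SD_HC`, where `M_HC` and `SD_HC` are the mean and
#' sample standard deviation (n-1 denominator) of the controls with
#' non-missing values. Controls therefore have mean 0 and SD 1 before any
#' outlier processing.
#'
#' @param values numeric vector of raw phenotype values for one cohort.
#' @param control_mask logical vector: TRUE for controls.
#' @return list with `z`, `m_hc`, `sd_hc`; `z` is all-NA (and the moments
#'   NA) when fewer than two controls have data or the control SD is zero,
#'   with a warning.
#' @export
zscore_within_cohort <- function(values, control_mask) {
  stopifnot(length(values) == length(control_mask))
  hc <- values[control_mask & !is.na(values)]
  if (length(hc) < 2L) {
    warning("fewer than 2 controls with data; cohort-phenotype skipped",
            call. = FALSE)
    return(list(z = rep(NA_real_, length(values)),
                m_hc = NA_real_, sd_hc = NA_real_))
  }
  m <- mean(hc)
  s <- sd(hc)
  if (!is.finite(s) || s == 0) {
    warning("control SD is zero; cohort-phenotype skipped", call. = FALSE)
    return(list(z = rep(NA_real_, length(values)),
                m_hc = m, sd_hc = NA_real_))
  }
  list(z = (values - m) / s, m_hc = m, sd_hc = s)
}

#' Remove extreme outliers and winsorize the remainder
#'
#' Applies the outlier rules on the control-referenced z scale in a single
#' pass: records with `|Z| >= remove_sd` are removed (z set to `NA`,
#' status "removed"); remaining records with `|Z| >= winsorize_sd` are set
#' to `sign(Z) * winsorize_sd` (status "winsorized"); everything else is
#' kept unchanged. Both bounds are inclusive. The operation is idempotent.
#'
#' @param z numeric vector of z-scores (NA allowed).
#' @param remove_sd removal bound in SD units (default 6).
#' @param winsorize_sd winsorization bound in SD units (default 4).
#' @return list with `z` (processed values) and `status` (factor:
#'   kept / winsorized / removed; NA input stays NA with status kept).
#' @export
filter_and_winsorize <- function(z, remove_sd = 6, winsorize_sd = 4) {
  stopifnot(winsorize_sd <= remove_sd)
  status <- rep("kept", length(z))
  rm_i <- !is.na(z) & abs(z) >= remove_sd
  z[rm_i] <- NA_real_
  status[rm_i] <- "removed"
  wi <- !is.na(z) & abs(z) >= winsorize_sd
  z[wi] <- sign(z[wi]) * winsorize_sd
  status[wi] <- "winsorized"
  list(z = z,
       status = factor(status, levels = c("kept", "winsorized", "removed")))
}

#' Harmonize all analysis phenotypes across cohorts
#'
#' Runs, per cohort and per phenotype: control-referenced z-scoring, then
#' outlier removal at `remove_sd`, then winsorization at `winsorize_sd`.
#' Raw volumes are never pooled across cohorts; every moment is within-
#' cohort. Ratios must already be present (see [compute_ratios()]).
#'
#' @param table a `phenotype_table` with volume and ratio columns.
#' @param phenotypes which phenotype columns to harmonize (default the 13
#'   analysis phenotypes present in the table).
#' @param remove_sd,winsorize_sd outlier bounds in SD units (defaults 6, 4).
#' @return a long data.frame of class `harmonized_phenotypes`: sample_id,
#'   cohort, diagnosis, phenotype, z, status, m_hc, sd_hc.
#' @export
harmonize_phenotypes <- function(table,
                                 phenotypes = intersect(analysis_phenotypes(),
                                                        names(table)),
                                 remove_sd = 6, winsorize_sd = 4) {
  stopifnot(all(c("sample_id", "cohort", "diagnosis") %in% names(table)))
  out <- vector("list", length(phenotypes) * length(unique(table$cohort)))
  k <- 0L
  for (ph in phenotypes) {
    for (co in unique(table$cohort)) {
      i <- which(table$cohort == co)
      zs <- zscore_within_cohort(table[[ph]][i],
                                 table$diagnosis[i] == "control")
      fw <- filter_and_winsorize(zs$z, remove_sd, winsorize_sd)
      k <- k + 1L
      out[[k]] <- data.frame(
        sample_id = table$sample_id[i], cohort = co,
        diagnosis = table$diagnosis[i], phenotype = ph,
        z = fw$z, status = fw$status, m_hc = zs$m_hc, sd_hc = zs$sd_hc,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  class(res) <- c("harmonized_phenotypes", "data.frame")
  res
}

#' Harmonized z-scores in wide (individuals x phenotypes) form
#'
#' @param harmonized output of [harmonize_phenotypes()].
#' @return data.frame with sample_id and one z column per phenotype
#'   (removed records are NA).
#' @export
harmonized_wide <- function(harmonized) {
  ids <- unique(harmonized$sample_id)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (ph in unique(harmonized$phenotype)) {
    sub <- harmonized[harmonized$phenotype == ph, ]
    out[[ph]] <- sub$z[match(ids, sub$sample_id)]
  }
  out
}

#' Residualize values on a covariate design
#'
#' Ordinary least-squares residuals of `y` on the covariate columns (an
#' intercept is always included). Used for descriptive covariate-adjusted
#' means and distributions only; association models include covariates in
#' the regression instead. Collinear columns are dropped with a warning.
#'
#' @param y numeric response.
#' @param covariates data.frame or matrix of covariates (factors allowed in
#'   a data.frame).
#' @return numeric vector of residuals (NA where y or a covariate is NA).
#' @export
residualize <- function(y, covariates) {
  df <- as.data.frame(covariates)
  X <- model.matrix(~ ., data = df)
  keep <- !is.na(y) & complete.cases(df)
  res <- rep(NA_real_, length(y))
  qrX <- qr(X[keep, , drop = FALSE])
  if (qrX$rank < ncol(X))
    warning("rank-deficient covariate design; ",
            ncol(X) - qrX$rank, " column(s) dropped", call. = FALSE)
  res[keep] <- qr.resid(qrX, y[keep])
  res
}
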