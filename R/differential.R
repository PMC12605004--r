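#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`
#' using sample variances.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return Cohen's d (positive when `a` has the higher mean).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("degenerate feature: pooled SD is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Covariate-adjusted linear model for one feature
#'
#' Ordinary least squares of a feature's abundance on a phenotype indicator
#' plus confounders; returns the phenotype coefficient and its two-sided
#' t-test p-value. Constant design columns are dropped (e.g. medication
#' flags in a treatment-naive sub-cohort); a genuinely rank-deficient design
#' is an error naming the collinear columns.
#'
#' @param y numeric abundance vector, aligned to `rownames(design)`.
#' @param design numeric design matrix from [encode_design()] (no intercept
#'   column; one is added internally).
#' @param phenotype_column name of the phenotype indicator column in `design`.
#' @return list with `beta`, `p`, `n_used`, and `dropped` (constant columns
#'   removed).
#' @export
fit_adjusted_lm <- function(y, design, phenotype_column) {
  if (!phenotype_column %in% colnames(design)) {
    stop("phenotype column '", phenotype_column, "' not in design")
  }
  keep <- apply(design, 2, function(cl) stats::var(cl) > 0)
  dropped <- colnames(design)[!keep]
  if (phenotype_column %in% dropped) {
    stop("phenotype indicator is constant in this design")
  }
  X <- cbind(`(Intercept)` = 1, design[, keep, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    coll <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(coll, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- length(y) - ncol(X)
  if (df <= 0) stop("not enough samples for the model degrees of freedom")
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(qr.R(qx))  # in pivoted column order
  se <- numeric(ncol(X))
  se[qx$pivot] <- sqrt(sigma2 * diag(XtX_inv))
  names(se) <- colnames(X)
  beta <- fit$coefficients[phenotype_column]
  tval <- beta / se[phenotype_column]
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = unname(beta), p = unname(p), n_used = length(y),
       dropped = dropped)
}

.comparison_groups <- function(comparison) {
  switch(comparison,
         ACPA_NEG_vs_CTRL = c(ra = "ACPA_NEG", ctrl = "CONTROL"),
         ACPA_POS_vs_CTRL = c(ra = "ACPA_POS", ctrl = "CONTROL"),
         stop("unknown comparison: ", comparison))
}

#' Phenotype-associated features by adjusted regression plus effect size
#'
#' For each feature, fits abundance ~ phenotype indicator + confounders
#' (sex, age, BMI, smoking with unknown-smoking samples excluded, and
#' medication flags) on the two groups of the comparison, and computes
#' Cohen's d on the unadjusted abundances of the same retained samples
#' (positive d = higher in the RA subgroup). A feature passes the strict
#' gate iff `p < p_thr` and `|d| > d_thr`; the relaxed gate (used for
#' pathway-level analysis) replaces `p_thr` with `relaxed_p_thr`.
#' Benjamini-Hochberg q-values are reported as an extra column but play no
#' role in the gates.
#'
#' @param data an OmicsMatrix (typically log-transformed proteins merged with
#'   scaled-imputed metabolites); no missing cells.
#' @param meta validated sample metadata covering `sample_ids(data)`.
#' @param comparison "ACPA_NEG_vs_CTRL" or "ACPA_POS_vs_CTRL".
#' @param p_thr,d_thr strict gates on the coefficient p-value and `|d|`.
#' @param relaxed_p_thr p-value gate of the relaxed pass.
#' @param covariates confounder set handed to [encode_design()].
#' @return data.frame with one row per feature: `feature_id`, `comparison`,
#'   `beta`, `p`, `q`, `d`, `direction`, `passes_strict`, `passes_relaxed`,
#'   `n_used`.
#' @export
differential_features <- function(data, meta, comparison,
                                  p_thr = 0.01, d_thr = 0.5,
                                  relaxed_p_thr = 0.05,
                                  covariates = c("sex", "age", "bmi",
                                                 "smoking", "meds")) {
  grp <- .comparison_groups(comparison)
  meta <- meta[meta$group %in% grp, , drop = FALSE]
  design <- encode_design(meta, include = covariates,
                          smoking_mode = "DROP_UNKNOWN")
  kept <- rownames(design)
  meta_k <- meta[match(kept, meta$sample_id), , drop = FALSE]
  if (min(table(factor(meta_k$group, levels = grp))) < 3) {
    stop("fewer than 3 samples per group after exclusions")
  }
  design <- cbind(design, phenotype = as.numeric(meta_k$group == grp[["ra"]]))
  v <- data$values[kept, , drop = FALSE]
  if (anyNA(v)) stop("data contains missing cells; impute first")
  is_ra <- meta_k$group == grp[["ra"]]

  res <- lapply(seq_len(ncol(v)), function(j) {
    fit <- fit_adjusted_lm(v[, j], design, "phenotype")
    d <- cohens_d(v[is_ra, j], v[!is_ra, j])
    data.frame(feature_id = colnames(v)[j], comparison = comparison,
               beta = fit$beta, p = fit$p, d = d,
               direction = if (d >= 0) "up" else "down",
               n_used = fit$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$passes_strict <- out$p < p_thr & abs(out$d) > d_thr
  out$passes_relaxed <- out$p < relaxed_p_thr & abs(out$d) > d_thr
  out[, c("feature_id", "comparison", "beta", "p", "q", "d", "direction",
          "passes_strict", "passes_relaxed", "n_used")]
}

#' Treatment-naive sub-cohort
#'
#' Sample IDs with no methotrexate, prednisone, bDMARD or csDMARD exposure;
#' controls (whose flags are all false) are always included. Rerunning
#' [differential_features()] on this subset drops the then-constant
#' medication covariates automatically.
#'
#' @param meta validated sample metadata.
#' @return character vector of sample IDs.
#' @export
subset_treatment_naive <- function(meta) {
  naive <- !(meta$med_mtx | meta$med_prednisone | meta$med_bdmard |
               meta$med_csdmard)
  meta$sample_id[naive | meta$group == "CONTROL"]
}
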