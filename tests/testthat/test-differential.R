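test_that("cohens_d matches hand calculations and its symmetries", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- stats::rnorm(8); b <- stats::rnorm(11, 1)
      k <- stats::runif(1, 0.1, 10)
      expect_equal(cohens_d(a, b), -cohens_d(b, a))
      expect_equal(cohens_d(k * a, k * b), cohens_d(a, b))
    }
  })
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("adjusted OLS reproduces a brute-force normal-equations solve", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- 40
      X <- cbind(x1 = stats::rnorm(n), x2 = stats::rnorm(n),
                 phenotype = rep(0:1, each = n / 2))
      rownames(X) <- sprintf("s%d", 1:n)
      y <- stats::rnorm(n) + 0.8 * X[, "phenotype"]
      fit <- fit_adjusted_lm(y, X, "phenotype")
      # independent oracle: solve the normal equations directly
      Xi <- cbind(1, X)
      beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
      resid <- y - Xi %*% beta
      s2 <- sum(resid^2) / (n - ncol(Xi))
      se <- unname(sqrt(s2 * diag(solve(t(Xi) %*% Xi)))[4])
      p <- 2 * stats::pt(abs(beta[4] / se), n - ncol(Xi), lower.tail = FALSE)
      expect_equal(fit$beta, beta[4], tolerance = 1e-8)
      expect_equal(fit$p, p, tolerance = 1e-8)
    }
  })
})

test_that("OLS edge cases: perfect separation, collinearity, constant columns", {
  n <- 20
  X <- cbind(phenotype = rep(0:1, each = n / 2))
  rownames(X) <- sprintf("s%d", 1:n)
  y <- X[, "phenotype"] * 1.0
  fit <- fit_adjusted_lm(y, X, "phenotype")
  expect_equal(fit$beta, 1)
  expect_lt(fit$p, 1e-12)
  X2 <- cbind(X, dup = X[, "phenotype"])
  expect_error(fit_adjusted_lm(stats::rnorm(n), X2, "phenotype"),
               "collinear.*dup")
  X3 <- cbind(X, flat = 1)
  fit3 <- fit_adjusted_lm(y + stats::rnorm(n, sd = 0.1), X3, "phenotype")
  expect_identical(fit3$dropped, "flat")
})

test_that("the phenotype coefficient p-value is uniform under the null", {
  withr::with_seed(11, {
    n <- 2000
    meta <- toy_meta(n)
    X <- encode_design(meta, smoking_mode = "DROP_UNKNOWN")
    kept <- rownames(X)
    g <- meta$group[match(kept, meta$sample_id)]
    X <- cbind(X, phenotype = as.numeric(g == "ACPA_NEG"))
    ps <- vapply(1:1000, function(i) {
      fit_adjusted_lm(stats::rnorm(nrow(X)), X, "phenotype")$p
    }, 0)
    frac <- mean(ps < 0.05)
    expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  })
})

test_that("adjustment shrinks a purely BMI-mediated group effect", {
  eff <- data.frame(feature_id = "P0001|SOMA0001", coef = 0.8)
  co <- generate_cohort(synthetic_config(
    n_per_group = 200, n_proteins = 3, n_metabolites = 2,
    covariate_effects = list(bmi = eff),
    confounding = list(bmi = c(ACPA_NEG = 6, ACPA_POS = 0, CONTROL = 0)),
    missing_censor_frac = 0, seed = 21))
  d <- log_transform(co$proteins)
  adj <- differential_features(d, co$meta, "ACPA_NEG_vs_CTRL")
  unadj <- differential_features(d, co$meta, "ACPA_NEG_vs_CTRL",
                                 covariates = "sex")
  f <- "P0001|SOMA0001"
  expect_lt(abs(adj$beta[adj$feature_id == f]),
            abs(unadj$beta[unadj$feature_id == f]))
})

test_that("strict/relaxed gates and direction are internally consistent", {
  co <- make_merged_cohort(5, n_per_group = 30, n_proteins = 40,
                           n_metabolites = 10,
                           planted = plant(10, group = "ACPA_NEG", d = 1.2))
  res <- differential_features(co$data, co$meta, "ACPA_NEG_vs_CTRL")
  expect_equal(nrow(res), 50L)
  expect_identical(res$passes_strict, res$p < 0.01 & abs(res$d) > 0.5)
  expect_identical(res$passes_relaxed, res$p < 0.05 & abs(res$d) > 0.5)
  expect_true(all(res$passes_relaxed[res$passes_strict]))
  expect_identical(res$direction, ifelse(res$d >= 0, "up", "down"))
  expect_true(all(res$n_used <= 60))
  # planted features dominate the strict pass set
  expect_gt(mean(res$passes_strict[res$feature_id %in%
                                     plant(10)$feature_id]), 0.5)
})

test_that("treatment-naive subsetting keeps controls and drops med covariates", {
  meta <- toy_meta(12)
  meta[, c("med_prednisone", "med_bdmard", "med_csdmard", "med_mtx")] <- FALSE
  expect_setequal(subset_treatment_naive(meta), meta$sample_id)
  meta$med_prednisone[meta$group == "ACPA_NEG"][1] <- TRUE
  out <- subset_treatment_naive(meta)
  expect_equal(setdiff(meta$sample_id, out),
               meta$sample_id[meta$med_prednisone])
  expect_true(all(meta$sample_id[meta$group == "CONTROL"] %in% out))

  co <- make_merged_cohort(6, n_per_group = 25, n_proteins = 10,
                           n_metabolites = 5)
  naive <- subset_treatment_naive(co$meta)
  sub_meta <- co$meta[co$meta$sample_id %in% naive, ]
  sub_meta[, c("med_prednisone", "med_bdmard", "med_csdmard", "med_mtx")] <- FALSE
  res <- differential_features(omics_subset(co$data, samples = sub_meta$sample_id),
                               sub_meta, "ACPA_POS_vs_CTRL")
  expect_true(all(is.finite(res$p)))
})

test_that("too few samples per group after exclusions is an error", {
  co <- make_merged_cohort(8, n_per_group = 5, n_proteins = 5, n_metabolites = 3)
  meta <- co$meta
  meta$smoking[meta$group == "ACPA_NEG"][1:3] <- "UNKNOWN"
  expect_error(differential_features(co$data, meta, "ACPA_NEG_vs_CTRL"),
               "fewer than 3")
})
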