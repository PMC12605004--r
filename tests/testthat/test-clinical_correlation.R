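mini_corr_data <- function(x, marker_vals, group = "ACPA_NEG") {
  n <- length(x)
  v <- matrix(x, n, 1, dimnames = list(sprintf("S%04d", 1:n), "f1"))
  meta <- toy_meta(n, groups = group)
  meta$esr <- marker_vals
  list(data = toy_matrix(v), meta = meta)
}

test_that("Spearman correlation matches the rank formula on small cases", {
  d <- mini_corr_data(c(1, 2, 3, 4), c(1, 4, 9, 16))
  r <- spearman_by_subgroup(d$data, d$meta, "esr", subgroups = "ACPA_NEG")
  expect_equal(r$rho, 1)
  d2 <- mini_corr_data(c(1, 2, 3, 4), c(16, 9, 4, 1))
  expect_equal(spearman_by_subgroup(d2$data, d2$meta, "esr",
                                    subgroups = "ACPA_NEG")$rho, -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4
  d3 <- mini_corr_data(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(spearman_by_subgroup(d3$data, d3$meta, "esr",
                                    subgroups = "ACPA_NEG")$rho, 0.6)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(3, {
    x <- stats::rnorm(12); y <- stats::rnorm(12)
    base <- mini_corr_data(x, y)
    r0 <- spearman_by_subgroup(base$data, base$meta, "esr",
                               subgroups = "ACPA_NEG")
    tx <- mini_corr_data(exp(3 * x), y^3 + 5 * y)
    r1 <- spearman_by_subgroup(tx$data, tx$meta, "esr", subgroups = "ACPA_NEG")
    expect_equal(r0$rho, r1$rho)
    expect_equal(r0$p, r1$p)
  })
})

test_that("degenerate features are flagged, not errors", {
  d <- mini_corr_data(rep(2, 5), c(1, 2, 3, 4, 5))
  r <- spearman_by_subgroup(d$data, d$meta, "esr", subgroups = "ACPA_NEG")
  expect_true(r$degenerate)
  expect_true(is.na(r$rho))
  d$meta$esr <- c(1, 2, NA, NA, NA)
  expect_error(spearman_by_subgroup(d$data, d$meta, "esr",
                                    subgroups = "ACPA_NEG"), "fewer than")
})

test_that("concordance categories follow the pass/significance logic", {
  row <- function(rho, p, sub = "A") {
    data.frame(feature_id = "f", marker = "esr", subgroup = sub, rho = rho,
               p = p, n_pairs = 40, degenerate = FALSE)
  }
  expect_equal(classify_concordance(row(0.5, 0.01), row(-0.1, 0.6)),
               "A_specific_pos")
  expect_equal(classify_concordance(row(0.6, 0.01), row(0.6, 0.01)),
               "concordant_pos")
  expect_equal(classify_concordance(row(-0.6, 0.01), row(-0.5, 0.02)),
               "concordant_neg")
  expect_equal(classify_concordance(row(0.45, 0.01), row(-0.45, 0.01)),
               "opposite")
  expect_equal(classify_concordance(row(0.1, 0.9), row(-0.5, 0.01)),
               "B_specific_neg")
  expect_equal(classify_concordance(row(0.1, 0.9), row(0.2, 0.8)), "none")
  # significant in B but below the rho threshold: not B-specific
  expect_equal(classify_concordance(row(0.1, 0.9), row(0.3, 0.01)), "none")
  expect_error(classify_concordance(row(0.5, 0.01),
                                    within(row(0.5, 0.01), marker <- "crp")),
               "same feature and marker")
})

test_that("concordance is symmetric under subgroup swap up to label exchange", {
  withr::with_seed(5, {
    swap <- c(concordant_pos = "concordant_pos", concordant_neg = "concordant_neg",
              A_specific_pos = "B_specific_pos", A_specific_neg = "B_specific_neg",
              B_specific_pos = "A_specific_pos", B_specific_neg = "A_specific_neg",
              opposite = "opposite", none = "none")
    for (i in 1:50) {
      a <- data.frame(feature_id = "f", marker = "esr", subgroup = "A",
                      rho = stats::runif(1, -0.8, 0.8),
                      p = stats::runif(1), n_pairs = 40, degenerate = FALSE)
      b <- within(a, rho <- stats::runif(1, -0.8, 0.8))
      b$p <- stats::runif(1)
      expect_equal(classify_concordance(b, a),
                   unname(swap[classify_concordance(a, b)]))
    }
  })
})

test_that("group mean Z-scores standardize across the group axis", {
  v <- rbind(S0001 = c(f1 = 1, f2 = 5), S0002 = c(2, 5), S0003 = c(3, 5))
  colnames(v) <- c("f1", "f2")
  meta <- toy_meta(3, groups = c("ACPA_NEG", "ACPA_POS", "CONTROL"))
  z <- group_mean_zscores(toy_matrix(v), meta)
  expect_equal(unname(z$z["f1", c("ACPA_NEG", "ACPA_POS", "CONTROL")]),
               c(-1, 0, 1))
  expect_equal(unname(z$z["f2", ]), c(0, 0, 0))
  expect_true(z$degenerate[["f2"]])
  co <- make_merged_cohort(4, n_per_group = 10, n_proteins = 8, n_metabolites = 4)
  zz <- group_mean_zscores(co$data, co$meta)
  expect_true(all(abs(rowMeans(zz$z)) < 1e-12))
})

test_that("the wide concordance table pairs both subgroups per feature", {
  mc <- data.frame(feature_id = c("P0001|SOMA0001", "P0002|SOMA0002"),
                   marker = "esr", coef = c(1.2, -1.2))
  co <- make_merged_cohort(17, n_per_group = 40, n_proteins = 10,
                           n_metabolites = 4, marker_coupling = mc)
  cors <- spearman_by_subgroup(co$data, co$meta, "esr")
  wide <- concordance_table(cors)
  expect_equal(nrow(wide), 14L)
  expect_true(all(wide$category %in%
    c("concordant_pos", "concordant_neg", "A_specific_pos", "A_specific_neg",
      "B_specific_pos", "B_specific_neg", "opposite", "none")))
  # strong symmetric coupling is concordant in both RA subgroups
  expect_equal(wide$category[wide$feature_id == "P0001|SOMA0001"],
               "concordant_pos")
})
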