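test_that("stratified folds balance every group and are seed-deterministic", {
  meta <- toy_meta(120)
  f <- stratified_folds(meta, k = 5, seed = 3)
  for (k in 1:5) {
    tab <- table(meta$group[match(names(f)[f == k], meta$sample_id)])
    expect_true(all(tab == 8))
  }
  expect_identical(f, stratified_folds(meta, k = 5, seed = 3))
  expect_false(identical(f, stratified_folds(meta, k = 5, seed = 4)))
  # 41/40/40: the remainder lands in exactly one fold, sizes differ by <= 1
  meta41 <- rbind(meta, within(meta[1, ], sample_id <- "S9999"))
  f41 <- stratified_folds(meta41, k = 5, seed = 1)
  g1 <- names(f41)[meta41$group[match(names(f41), meta41$sample_id)] ==
                     meta41$group[1]]
  sizes <- table(f41[g1])
  expect_lte(diff(range(sizes)), 1)
  expect_error(stratified_folds(toy_meta(9), k = 5), "smallest group")
})

test_that("the metric panel matches the worked confusion matrix", {
  # TP=7, FN=1, TN=6, FP=2
  y <- c(rep(TRUE, 8), rep(FALSE, 8))
  s <- c(rep(0.9, 7), 0.1, rep(0.8, 2), rep(0.2, 6))
  m <- compute_metrics(y, s)
  expect_equal(m$tp, 7); expect_equal(m$fn, 1)
  expect_equal(m$tn, 6); expect_equal(m$fp, 2)
  expect_equal(m$sensitivity, 0.875)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$ppv, 7 / 9)
  expect_equal(m$npv, 6 / 7)
  expect_equal(m$accuracy, 0.8125)
  expect_equal(m$mcc, 40 / sqrt(4032))
  expect_equal(m$f1, 14 / 17)
})

test_that("AUC is rank-based with tie credit and monotone-invariant", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(compute_metrics(y, c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(compute_metrics(y, c(0.5, 0.5, 0.5, 0.5))$auc, 0.5)
  withr::with_seed(8, {
    for (i in 1:10) {
      yy <- stats::runif(30) < 0.5
      if (length(unique(yy)) < 2) next
      sc <- stats::runif(30)
      a0 <- compute_metrics(yy, sc)$auc
      expect_equal(compute_metrics(yy, stats::plogis(5 * sc - 2))$auc, a0)
    }
  })
  expect_true(is.na(compute_metrics(rep(TRUE, 4), stats::runif(4))$auc))
  # NPV denominator of zero is NA, not an error
  expect_true(is.na(compute_metrics(c(TRUE, FALSE), c(0.9, 0.8))$npv))
})

test_that("run_task produces the full metric grid and a best N by mean AUC", {
  co <- make_merged_cohort(31, n_per_group = 15, n_proteins = 25,
                           n_metabolites = 10,
                           planted = plant(8, group = "BOTH", d = 1.5))
  res <- run_task(co$data, co$meta, "RA_vs_CTRL", selector = "anova_f",
                  n_grid = c(5, 10), k = 3, cv_seed = 2)
  expect_s3_class(res, "cv_result")
  expect_equal(nrow(res$per_fold), 6L)  # 3 folds x 2 Ns
  expect_true(res$best_n %in% c(5, 10))
  expect_setequal(res$summary$metric,
                  c("auc", "accuracy", "sensitivity", "specificity", "ppv",
                    "npv", "f1", "mcc"))
  # RA pooled as positives: each test fold has 10 positives, 5 controls
  expect_true(all(res$per_fold$tp + res$per_fold$fn == 10))
  expect_true(all(res$per_fold$tn + res$per_fold$fp == 5))
})

test_that("selector baselines run on identical folds for paired comparison", {
  co <- make_merged_cohort(32, n_per_group = 10, n_proteins = 20,
                           n_metabolites = 8,
                           planted = plant(5, group = "ACPA_POS", d = 1.5))
  folds <- stratified_folds(co$meta[co$meta$group %in%
                                      c("ACPA_POS", "CONTROL"), ], k = 2,
                            seed = 9)
  out <- lapply(c("anova_f", "mutual_info", "none"), function(sel) {
    suppressWarnings(
      run_task(co$data, co$meta, "ACPA_POS_vs_CTRL", selector = sel,
               n_grid = 5, k = 2, cv_seed = 9, folds = folds))
  })
  expect_identical(out[[1]]$folds, out[[2]]$folds)
  # 'none' ignores the grid and uses all features
  expect_warning(
    all_feat <- run_task(co$data, co$meta, "ACPA_POS_vs_CTRL",
                         selector = "none", n_grid = 5, k = 2, cv_seed = 9),
    "ignored")
  expect_equal(unique(all_feat$per_fold$n), 28)
})

test_that("modality restriction drops the other omic block", {
  co <- make_merged_cohort(33, n_per_group = 10, n_proteins = 12,
                           n_metabolites = 6)
  res <- run_task(co$data, co$meta, "ACPA_NEG_vs_CTRL", modality = "metabolomic",
                  selector = "anova_f", n_grid = 3, k = 2, cv_seed = 1)
  feats <- unique(unlist(res$selected))
  expect_true(all(grepl("^M", feats)))
})

test_that("test-fold corruption cannot change training artifacts (no leakage)", {
  co <- make_merged_cohort(34, n_per_group = 10, n_proteins = 15,
                           n_metabolites = 5,
                           planted = plant(5, group = "BOTH", d = 1.2))
  meta <- co$meta[co$meta$group %in% c("ACPA_NEG", "CONTROL"), ]
  data <- omics_subset(co$data, samples = meta$sample_id)
  folds <- stratified_folds(meta, k = 2, seed = 5)
  base <- run_task(data, meta, "ACPA_NEG_vs_CTRL", selector = "network_rwr",
                   n_grid = c(4, 8), k = 2, cv_seed = 5, folds = folds,
                   return_models = TRUE)
  # corrupt fold 1's held-out values AND labels
  te1 <- names(folds)[folds == 1]
  data2 <- data
  data2$values[te1, ] <- data2$values[te1, ] * 3 + 7
  meta2 <- meta
  g1 <- meta2$group[match(te1, meta2$sample_id)]
  meta2$group[match(te1, meta2$sample_id)] <-
    ifelse(g1 == "ACPA_NEG", "CONTROL", "ACPA_NEG")
  pert <- run_task(data2, meta2, "ACPA_NEG_vs_CTRL", selector = "network_rwr",
                   n_grid = c(4, 8), k = 2, cv_seed = 5, folds = folds,
                   return_models = TRUE)
  expect_identical(base$selected[["1"]], pert$selected[["1"]])
  for (N in c(4, 8)) {
    expect_identical(base$models[[paste0("1:", N)]]$forest,
                     pert$models[[paste0("1:", N)]]$forest)
  }
})
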