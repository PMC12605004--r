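#' Stratified cross-validation fold assignment
#'
#' Each fold's test set has (as near as possible) equal counts per group:
#' with 40 samples per group and k = 5, every test fold is exactly 8+8+8.
#' Remainders are spread so per-group fold sizes differ by at most one.
#'
#' @param meta validated sample metadata (its `group` column stratifies).
#' @param k number of folds; must not exceed the smallest group size.
#' @param seed integer seed; the assignment is deterministic given it.
#' @return named integer vector (sample_id -> fold in 1..k).
#' @export
stratified_folds <- function(meta, k = 5, seed = 1) {
  sizes <- table(meta$group)
  if (k > min(sizes)) {
    stop("k = ", k, " exceeds the smallest group size (", min(sizes), ")")
  }
  withr::with_seed(seed, {
    fold <- stats::setNames(integer(nrow(meta)), meta$sample_id)
    for (g in names(sizes)) {
      ids <- sample(meta$sample_id[meta$group == g])
      fold[ids] <- rep(seq_len(k), length.out = length(ids))
    }
    fold
  })
}

#' Classification metric panel from scores and labels
#'
#' AUC is rank-based (Mann-Whitney) with half credit for score ties, so it is
#' invariant under strictly monotone transforms of the scores. Confusion
#' counts are taken at `threshold`; PPV and NPV are `NA` when their
#' denominator is zero (such folds are omitted from fold averaging), as are
#' F1 and MCC when undefined.
#'
#' @param y_true logical vector (TRUE = positive class).
#' @param scores numeric scores in `[0, 1]` (positive-class probabilities).
#' @param threshold score cut for the confusion counts.
#' @return one-row data.frame: tp, fp, tn, fn, auc, accuracy, sensitivity,
#'   specificity, ppv, npv, f1, mcc.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores))
  n1 <- sum(y_true); n0 <- sum(!y_true)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(scores)  # average ranks give ties half credit
    (sum(r[y_true]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  pred <- scores >= threshold
  tp <- sum(pred & y_true); fp <- sum(pred & !y_true)
  tn <- sum(!pred & !y_true); fn <- sum(!pred & y_true)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn, auc = auc,
             accuracy = (tp + tn) / length(y_true),
             sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
             ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
             f1 = div(2 * tp, 2 * tp + fp + fn),
             mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den)
}

.task_groups <- function(task) {
  switch(task,
         ACPA_NEG_vs_CTRL = list(groups = c("ACPA_NEG", "CONTROL"),
                                 positive = "ACPA_NEG"),
         ACPA_POS_vs_CTRL = list(groups = c("ACPA_POS", "CONTROL"),
                                 positive = "ACPA_POS"),
         RA_vs_CTRL = list(groups = c("ACPA_NEG", "ACPA_POS", "CONTROL"),
                           positive = c("ACPA_NEG", "ACPA_POS")),
         stop("unknown task: ", task))
}

.rank_features_anova_f <- function(v, y) {
  # per-feature one-way F statistic for a binary grouping, vectorized
  n1 <- sum(y); n0 <- sum(!y); n <- n1 + n0
  m1 <- colMeans(v[y, , drop = FALSE]); m0 <- colMeans(v[!y, , drop = FALSE])
  gm <- colMeans(v)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums((t(t(v[y, , drop = FALSE]) - m1))^2) +
    colSums((t(t(v[!y, , drop = FALSE]) - m0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  names(f) <- colnames(v)
  f
}

.rank_features_mutual_info <- function(v, y, n_bins = 5) {
  # equal-frequency binning MI between each feature and the binary label
  apply(v, 2, function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    b <- cut(x, breaks = br, include.lowest = TRUE)
    tab <- table(b, y) / length(y)
    px <- rowSums(tab); py <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  })
}

.fold_seed <- function(cv_seed, fold) {
  as.integer((as.numeric(cv_seed) * 1009 + fold * 97) %% .Machine$integer.max)
}

#' Leakage-free cross-validated classification with network-guided selection
#'
#' For each fold, every step — elastic-net network inference, RWR feature
#' prioritization and random-forest training — runs exclusively on the
#' training split; test samples never enter network inference,
#' standardization statistics, or the ranking. Phenotype nodes are built from
#' training labels only and seed the walk. The random forest is trained on
#' the selected features alone; per-fold metrics are computed for every
#' requested subnetwork size N and the summary is reported at the N with the
#' highest mean test AUC (`best_n`), mirroring the optimal-subnetwork-size
#' reporting convention; `summary_by_n` retains the full grid so a nested
#' (honest) choice of N on training data alone can be made instead.
#'
#' @param data merged, imputed, log-transformed OmicsMatrix.
#' @param meta validated sample metadata.
#' @param task "ACPA_NEG_vs_CTRL", "ACPA_POS_vs_CTRL" or "RA_vs_CTRL" (the
#'   two RA subgroups pooled as positives, 2:1 against controls).
#' @param modality "multi", "proteomic" or "metabolomic".
#' @param selector "network_rwr", "none" (all features), "anova_f" or
#'   "mutual_info".
#' @param n_grid ascending subnetwork sizes; values above the available
#'   feature count are capped (use `Inf` for "all"). Ignored with a warning
#'   when `selector = "none"`.
#' @param k folds; `cv_seed` seeds the fold assignment and, via per-fold
#'   derived seeds, the network CV folds and forests.
#' @param rf_trees,rf_mtry_frac random-forest size and per-split feature
#'   fraction (default `NULL` = sqrt(p)).
#' @param restart,rwr_tol RWR parameters.
#' @param alpha_grid,n_cv elastic-net controls (see [fit_neighborhood()]).
#' @param covariates covariate nodes added to the per-fold networks.
#' @param folds optional precomputed fold assignment (as from
#'   [stratified_folds()] on the task's samples).
#' @param return_models keep per-fold fitted ranger objects (memory-heavy).
#' @return list of class `cv_result`: `per_fold` (metrics per fold x N),
#'   `summary_by_n` (mean AUC per N), `best_n`, `summary` (mean and SD of
#'   each metric at `best_n`), `selected` (per fold, features in rank order),
#'   `folds`, and optionally `models`.
#' @export
run_task <- function(data, meta, task, modality = "multi",
                     selector = c("network_rwr", "none", "anova_f",
                                  "mutual_info"),
                     n_grid = c(10, 20, 30, 40, 50, 75, 100, 150, 200, Inf),
                     k = 5, cv_seed = 1, rf_trees = 500, rf_mtry_frac = NULL,
                     restart = 0.5, rwr_tol = 1e-4,
                     alpha_grid = c(0.1, 0.5, 0.9), n_cv = 10,
                     covariates = c("sex", "age", "bmi", "smoking"),
                     folds = NULL, return_models = FALSE) {
  selector <- match.arg(selector)
  tg <- .task_groups(task)
  meta <- meta[meta$group %in% tg$groups, , drop = FALSE]
  data <- omics_subset(data, samples = meta$sample_id)
  if (modality != "multi") {
    kinds <- c(proteomic = "protein", metabolomic = "metabolite")[[modality]]
    data <- omics_subset(data, features = which(data$feature_info$kind == kinds))
  }
  p_all <- length(feature_ids(data))
  if (selector == "none") {
    if (!missing(n_grid)) warning("selector 'none' uses all features; N grid ignored")
    n_grid <- p_all
  }
  n_grid <- sort(unique(pmin(n_grid, p_all)))
  if (is.null(folds)) folds <- stratified_folds(meta, k = k, seed = cv_seed)
  stopifnot(setequal(names(folds), meta$sample_id))

  per_fold <- list(); selected <- list(); models <- list()
  for (f in sort(unique(folds))) {
    tr_ids <- names(folds)[folds != f]
    te_ids <- names(folds)[folds == f]
    seed_f <- .fold_seed(cv_seed, f)
    tr <- omics_subset(data, samples = tr_ids)
    meta_tr <- meta[match(tr_ids, meta$sample_id), , drop = FALSE]
    y_tr <- factor(ifelse(meta_tr$group %in% tg$positive, "pos", "neg"),
                   levels = c("neg", "pos"))
    y_te <- meta$group[match(te_ids, meta$sample_id)] %in% tg$positive

    ranked <- switch(selector,
      network_rwr = {
        g <- infer_network(tr, meta_tr, covariates = covariates,
                           alpha_grid = alpha_grid, n_cv = n_cv, seed = seed_f)
        pheno_nodes <- igraph::V(g)$name[igraph::V(g)$kind == "phenotype"]
        rk <- rwr(g, seeds = pheno_nodes, r = restart, tol = rwr_tol)
        top_n_features(g, rk, N = p_all)$nodes$node
      },
      anova_f = {
        s <- .rank_features_anova_f(tr$values, y_tr == "pos")
        names(s)[order(-s, names(s))]
      },
      mutual_info = {
        s <- .rank_features_mutual_info(tr$values, y_tr == "pos")
        names(s)[order(-s, names(s))]
      },
      none = feature_ids(data))
    selected[[as.character(f)]] <- ranked

    for (N in n_grid) {
      feat <- ranked[seq_len(N)]
      rf <- ranger::ranger(
        x = tr$values[, feat, drop = FALSE], y = y_tr,
        num.trees = rf_trees,
        mtry = if (is.null(rf_mtry_frac)) max(1, floor(sqrt(N)))
               else max(1, floor(rf_mtry_frac * N)),
        probability = TRUE, seed = seed_f, num.threads = 1)
      sc <- stats::predict(rf, data = data$values[te_ids, feat, drop = FALSE],
                           num.threads = 1)$predictions[, "pos"]
      m <- compute_metrics(y_te, sc)
      per_fold[[length(per_fold) + 1]] <- cbind(fold = f, n = N, m)
      if (return_models) models[[paste(f, N, sep = ":")]] <- rf
    }
  }
  per_fold <- do.call(rbind, per_fold)
  by_n <- stats::aggregate(auc ~ n, data = per_fold, FUN = mean)
  best_n <- by_n$n[which.max(by_n$auc)]
  at_best <- per_fold[per_fold$n == best_n, ]
  mets <- c("auc", "accuracy", "sensitivity", "specificity", "ppv", "npv",
            "f1", "mcc")
  summ <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(at_best[[m]], na.rm = TRUE), 0),
    sd = vapply(mets, function(m) stats::sd(at_best[[m]], na.rm = TRUE), 0))
  structure(list(task = task, modality = modality, selector = selector,
                 per_fold = per_fold, summary_by_n = by_n, best_n = best_n,
                 summary = summ, selected = selected, folds = folds,
                 models = if (return_models) models),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s | %s | selector=%s | best N=%d\n",
              x$task, x$modality, x$selector, x$best_n))
  auc <- x$summary[x$summary$metric == "auc", ]
  cat(sprintf("  mean test AUC at best N: %.3f (SD %.3f)\n", auc$mean, auc$sd))
  invisible(x)
}
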