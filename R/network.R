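#' Elastic-net neighborhood selection for one response feature
#'
#' Regresses one omic feature on all other columns of the predictor matrix
#' (remaining features, covariates, one-hot phenotype indicators) with the
#' elastic net, choosing the (mixing, penalty) pair that minimizes 10-fold
#' cross-validated RMSE over a mixing grid. The constrained parameterization
#' with L1 weight `lambda1` and L2 weight `lambda2 = 1 - lambda1` maps onto
#' glmnet's mixing parameter `alpha = lambda1` with overall penalty strength
#' chosen on the regularization path. Predictors are standardized within each
#' fit (glmnet's internal standardization, recomputed on each training split
#' during cross-validation), the response is centered via the intercept.
#'
#' @param data numeric matrix, samples x columns, containing the response
#'   column and all candidate predictors; column names required.
#' @param response name of the response column.
#' @param alpha_grid mixing values in (0, 1) to search.
#' @param n_cv number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @param nlambda,lambda_min_ratio,thresh glmnet path controls; the short
#'   path (20 points down to 10% of lambda_max) is plenty for neighborhood
#'   selection at these sample sizes and keeps whole-matrix inference
#'   tractable on a single core.
#' @return list of class `neighborhood_model`: `response`, `selected`
#'   (predictor names with nonzero coefficients), `coef` (their values),
#'   `intercept`, `lambda1`, `lambda2`, `penalty`, `cv_rmse`, `dropped`
#'   (zero-variance predictors removed).
#' @export
fit_neighborhood <- function(data, response, alpha_grid = c(0.1, 0.5, 0.9),
                             n_cv = 10, seed = 1, nlambda = 20,
                             lambda_min_ratio = 0.1, thresh = 1e-5) {
  if (length(alpha_grid) == 0) stop("empty mixing grid")
  if (any(alpha_grid <= 0 | alpha_grid >= 1)) {
    stop("mixing values must lie strictly in (0, 1)")
  }
  if (!response %in% colnames(data)) stop("response '", response, "' not in data")
  if (sum(colnames(data) == response) > 1) {
    stop("response '", response, "' appears more than once among predictors")
  }
  y <- data[, response]
  x <- data[, setdiff(colnames(data), response), drop = FALSE]
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance predictor(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  n <- nrow(x)
  foldid <- withr::with_seed(seed, sample(rep(seq_len(n_cv), length.out = n)))
  best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(x, y, alpha = a, foldid = foldid,
                            type.measure = "mse", nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio,
                            thresh = thresh, standardize = TRUE)
    i <- which.min(cv$cvm)
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      best <- list(cvm = cv$cvm[i], alpha = a, lambda = cv$lambda[i], fit = cv)
    }
  }
  cf <- stats::coef(best$fit, s = best$lambda)
  nz <- which(cf[-1, 1] != 0)
  structure(list(response = response,
                 selected = rownames(cf)[-1][nz],
                 coef = cf[-1, 1][nz],
                 intercept = cf[1, 1],
                 lambda1 = best$alpha, lambda2 = 1 - best$alpha,
                 penalty = best$lambda,
                 cv_rmse = sqrt(best$cvm),
                 dropped = dropped),
            class = "neighborhood_model")
}

#' Infer the multi-omic association network
#'
#' One elastic-net neighborhood regression per omic feature (covariates and
#' phenotype indicators are predictors only, never responses), merged into a
#' single undirected, unweighted graph. With the default union rule an edge
#' (u, v) exists iff v was selected in u's regression or u in v's; the
#' intersection rule requires both directions (and so only applies to
#' feature-feature pairs; feature-covariate edges, for which only one
#' regression exists, are kept when selected).
#'
#' @param data an OmicsMatrix with no missing cells (log-transformed proteins
#'   merged with scaled-imputed metabolites).
#' @param meta validated sample metadata covering the samples.
#' @param covariates covariate set added as predictor nodes (machine-learning
#'   encoding: unknown smoking is its own indicator level).
#' @param alpha_grid,n_cv,seed,... passed to [fit_neighborhood()].
#' @param merge "union" (default) or "intersection".
#' @return an igraph undirected graph; vertex attributes `name` and `kind`
#'   (protein/metabolite/covariate/phenotype).
#' @export
infer_network <- function(data, meta,
                          covariates = c("sex", "age", "bmi", "smoking"),
                          alpha_grid = c(0.1, 0.5, 0.9), n_cv = 10, seed = 1,
                          merge = c("union", "intersection"), ...) {
  merge <- match.arg(merge)
  if (nrow(data$values) < 10) stop("need at least 10 samples for 10-fold CV")
  if (anyNA(data$values)) stop("data contains missing cells; impute first")
  meta <- meta[match(sample_ids(data), meta$sample_id), , drop = FALSE]
  design <- encode_design(meta, include = c(covariates, "phenotype"),
                          smoking_mode = "UNKNOWN_LEVEL")
  Z <- cbind(data$values, design[sample_ids(data), , drop = FALSE])
  feats <- feature_ids(data)
  kind <- c(stats::setNames(data$feature_info$kind, feats),
            stats::setNames(rep("covariate", ncol(design)), colnames(design)))
  kind[attr(design, "phenotype_cols")] <- "phenotype"

  sel <- vector("list", length(feats))
  names(sel) <- feats
  for (j in feats) {
    m <- suppressWarnings(
      fit_neighborhood(Z, j, alpha_grid = alpha_grid, n_cv = n_cv,
                       seed = seed, ...))
    sel[[j]] <- m$selected
  }
  pairs <- do.call(rbind, lapply(feats, function(j) {
    if (length(sel[[j]])) cbind(j, sel[[j]]) else NULL
  }))
  nodes <- colnames(Z)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::set_vertex_attr(g, "kind", value = unname(kind[nodes]))
  if (!is.null(pairs)) {
    key <- function(u, v) paste(pmin(u, v), pmax(u, v))
    ks <- key(pairs[, 1], pairs[, 2])
    if (merge == "union") {
      keep <- !duplicated(ks)
    } else {
      both_dir <- ks %in% ks[duplicated(ks)]
      one_dir_only <- kind[pairs[, 2]] %in% c("covariate", "phenotype")
      keep <- (both_dir | one_dir_only) & !duplicated(ks)
    }
    ep <- pairs[keep, , drop = FALSE]
    g <- igraph::add_edges(g, as.vector(t(cbind(match(ep[, 1], nodes),
                                                match(ep[, 2], nodes)))))
    g <- igraph::simplify(g)
  }
  g
}

#' Edge and node tables of a multi-omic network
#' @param g igraph network from [infer_network()].
#' @return list with `edges` (node_u, node_v, kind_u, kind_v) and `nodes`
#'   (node, kind) data.frames.
#' @export
network_tables <- function(g) {
  e <- igraph::as_edgelist(g)
  kind <- stats::setNames(igraph::V(g)$kind, igraph::V(g)$name)
  list(edges = data.frame(node_u = e[, 1], node_v = e[, 2],
                          kind_u = unname(kind[e[, 1]]),
                          kind_v = unname(kind[e[, 2]]),
                          stringsAsFactors = FALSE),
       nodes = data.frame(node = names(kind), kind = unname(kind),
                          stringsAsFactors = FALSE))
}
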