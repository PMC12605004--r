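#' Subgroup-stratified Spearman correlation with a clinical marker
#'
#' For every feature, Spearman's rho (average ranks for ties) between the
#' feature abundance and the marker within each requested subgroup, using
#' pairwise-complete samples, with the two-sided p-value from the asymptotic
#' t approximation. A constant feature or marker yields `rho = NA` with
#' `degenerate = TRUE` rather than an error.
#'
#' @param data an OmicsMatrix.
#' @param meta validated sample metadata.
#' @param marker one of "esr", "crp", "das28crp".
#' @param subgroups groups to stratify by (defaults to the two RA subgroups,
#'   where the markers are measured).
#' @param min_pairs minimum complete pairs required in a subgroup.
#' @return data.frame: `feature_id`, `marker`, `subgroup`, `rho`, `p`,
#'   `n_pairs`, `degenerate`.
#' @export
spearman_by_subgroup <- function(data, meta, marker = c("esr", "crp", "das28crp"),
                                 subgroups = c("ACPA_NEG", "ACPA_POS"),
                                 min_pairs = 4) {
  marker <- match.arg(marker)
  out <- list()
  for (g in subgroups) {
    sid <- meta$sample_id[meta$group == g]
    mv <- meta[[marker]][match(sid, meta$sample_id)]
    ok <- !is.na(mv)
    if (sum(ok) < min_pairs) {
      stop("marker '", marker, "' present for fewer than ", min_pairs,
           " samples in subgroup ", g)
    }
    v <- data$values[sid, , drop = FALSE]
    res <- lapply(seq_len(ncol(v)), function(j) {
      x <- v[, j]
      use <- ok & !is.na(x)
      n <- sum(use)
      if (n < min_pairs || stats::sd(x[use]) == 0 || stats::sd(mv[use]) == 0) {
        return(data.frame(feature_id = colnames(v)[j], marker = marker,
                          subgroup = g, rho = NA_real_, p = NA_real_,
                          n_pairs = n, degenerate = TRUE))
      }
      ct <- suppressWarnings(
        stats::cor.test(x[use], mv[use], method = "spearman", exact = FALSE))
      data.frame(feature_id = colnames(v)[j], marker = marker, subgroup = g,
                 rho = unname(ct$estimate), p = ct$p.value, n_pairs = n,
                 degenerate = FALSE)
    })
    out[[g]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify cross-subgroup concordance of a feature-marker correlation
#'
#' Given the same feature and marker correlated within two subgroups, a
#' correlation "passes" in a subgroup when `|rho| > rho_thr` and `p < alpha`.
#' Categories: both pass with the same sign (`concordant_pos`/`_neg`); one
#' passes while the other is non-significant (`A_specific_*`/`B_specific_*`);
#' both significant with opposite signs (`opposite`); anything else `none`.
#'
#' @param resA,resB single rows of [spearman_by_subgroup()] output for the
#'   same feature and marker in two different subgroups.
#' @param rho_thr,alpha pass thresholds.
#' @return category string.
#' @export
classify_concordance <- function(resA, resB, rho_thr = 0.4, alpha = 0.05) {
  if (!identical(resA$feature_id, resB$feature_id) ||
      !identical(resA$marker, resB$marker)) {
    stop("concordance requires the same feature and marker in both subgroups")
  }
  if (isTRUE(resA$degenerate) || isTRUE(resB$degenerate)) return("none")
  passes <- function(r) abs(r$rho) > rho_thr && r$p < alpha
  sig <- function(r) r$p < alpha
  pa <- passes(resA); pb <- passes(resB)
  sgn <- function(r) if (r$rho >= 0) "pos" else "neg"
  if (pa && pb) {
    if (sgn(resA) == sgn(resB)) return(paste0("concordant_", sgn(resA)))
    return("opposite")
  }
  if (sig(resA) && sig(resB) && sgn(resA) != sgn(resB)) return("opposite")
  if (pa && !sig(resB)) return(paste0("A_specific_", sgn(resA)))
  if (pb && !sig(resA)) return(paste0("B_specific_", sgn(resB)))
  "none"
}

#' Pair subgroup correlations into a wide comparison table
#'
#' @param cors output of [spearman_by_subgroup()] over exactly two subgroups.
#' @param rho_thr,alpha thresholds handed to [classify_concordance()].
#' @return data.frame with one row per feature: rho/p per subgroup and the
#'   concordance category.
#' @export
concordance_table <- function(cors, rho_thr = 0.4, alpha = 0.05) {
  gs <- unique(cors$subgroup)
  if (length(gs) != 2) stop("exactly two subgroups required")
  a <- cors[cors$subgroup == gs[1], ]
  b <- cors[cors$subgroup == gs[2], ]
  b <- b[match(a$feature_id, b$feature_id), ]
  cat_v <- vapply(seq_len(nrow(a)), function(i) {
    classify_concordance(a[i, ], b[i, ], rho_thr, alpha)
  }, "")
  data.frame(feature_id = a$feature_id, marker = a$marker,
             subgroup_A = gs[1], rho_A = a$rho, p_A = a$p,
             subgroup_B = gs[2], rho_B = b$rho, p_B = b$p,
             category = cat_v, stringsAsFactors = FALSE)
}

#' Z-scores of group mean abundances
#'
#' Per feature: compute the group means, then standardize that mean vector
#' across the group axis (mean 0, sample SD 1 over the groups). Features
#' whose group means are all equal get zeros and a degenerate flag.
#'
#' @param data an OmicsMatrix without missing cells.
#' @param meta validated sample metadata.
#' @return list with `z` (feature x group matrix) and `degenerate`
#'   (logical per feature).
#' @export
group_mean_zscores <- function(data, meta) {
  g <- factor(meta$group[match(sample_ids(data), meta$sample_id)])
  if (nlevels(g) < 2) stop("at least 2 groups required")
  means <- t(apply(data$values, 2, function(x) tapply(x, g, mean)))
  sds <- apply(means, 1, stats::sd)
  degenerate <- sds == 0
  z <- (means - rowMeans(means)) / ifelse(degenerate, 1, sds)
  z[degenerate, ] <- 0
  list(z = z, degenerate = stats::setNames(degenerate, rownames(means)))
}
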