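#' Remove features with excessive missingness
#'
#' A feature is removed iff its missing fraction strictly exceeds `max_frac`
#' ("over 20%" by default); a feature missing in exactly 20% of samples is
#' retained.
#'
#' @param m an OmicsMatrix.
#' @param max_frac maximum tolerated missing fraction, in `[0, 1]`.
#' @return the filtered OmicsMatrix; the removal report (IDs and missing
#'   fractions of dropped features) is attached as attribute `"removed"`.
#' @export
filter_by_missingness <- function(m, max_frac = 0.20) {
  if (!is.numeric(max_frac) || length(max_frac) != 1 ||
      is.na(max_frac) || max_frac < 0 || max_frac > 1) {
    stop("max_frac must be a single value in [0, 1]")
  }
  frac <- colMeans(is.na(m$values))
  drop <- frac > max_frac
  out <- omics_subset(m, features = which(!drop))
  attr(out, "removed") <- data.frame(feature_id = feature_ids(m)[drop],
                                     missing_frac = unname(frac[drop]))
  out
}

#' Median-scale and minimum-impute (scaled-imputed convention)
#'
#' Per feature: observed values are divided by their median, so the median of
#' the originally-observed entries becomes exactly 1; missing cells are then
#' filled with the minimum of the scaled observed values. This is the
#' "scaled imputed" convention for untargeted metabolomics, where missingness
#' concentrates at low abundance and minimum imputation is the matching fill.
#'
#' @param m an OmicsMatrix; every feature must have at least one observed
#'   value (run [filter_by_missingness()] first).
#' @return an OmicsMatrix with an empty missingness mask.
#' @export
scale_and_impute <- function(m) {
  v <- m$values
  all_miss <- colSums(!is.na(v)) == 0
  if (any(all_miss)) {
    stop("features with all values missing (filter first): ",
         paste(feature_ids(m)[all_miss], collapse = ", "))
  }
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  if (any(med == 0)) stop("feature with zero median cannot be median-scaled")
  v <- sweep(v, 2, med, "/")
  for (j in which(colSums(is.na(v)) > 0)) {
    v[is.na(v[, j]), j] <- min(v[, j], na.rm = TRUE)
  }
  omics_matrix(v, m$feature_info, m$log_transformed)
}

#' Column-bind two omic blocks over the same samples
#'
#' Sample sets must be identical (order may differ; the metabolite block is
#' realigned to the protein block's order). Feature IDs must be disjoint.
#'
#' @param prot,met OmicsMatrix objects (typically proteins and metabolites).
#' @return merged OmicsMatrix with `feature_info` stacked (annotation columns
#'   unioned, absent ones filled with NA).
#' @export
merge_omics <- function(prot, met) {
  sa <- sample_ids(prot); sb <- sample_ids(met)
  if (!setequal(sa, sb)) {
    stop("sample sets differ; only in first: ",
         paste(setdiff(sa, sb), collapse = ", "),
         "; only in second: ", paste(setdiff(sb, sa), collapse = ", "))
  }
  overlap <- intersect(feature_ids(prot), feature_ids(met))
  if (length(overlap)) {
    stop("feature IDs present in both blocks: ", paste(overlap, collapse = ", "))
  }
  if (!identical(prot$log_transformed, met$log_transformed)) {
    stop("cannot merge blocks on different scales (log_transformed differs)")
  }
  met_v <- met$values[sa, , drop = FALSE]
  cols <- union(names(prot$feature_info), names(met$feature_info))
  pad <- function(fi) {
    for (cl in setdiff(cols, names(fi))) fi[[cl]] <- NA
    fi[, cols, drop = FALSE]
  }
  omics_matrix(cbind(prot$values, met_v),
               rbind(pad(prot$feature_info), pad(met$feature_info)),
               prot$log_transformed)
}

#' Build a design matrix from sample metadata
#'
#' Two encodings are supported, matching the two downstream consumers.
#' Regression mode (`smoking_mode = "DROP_UNKNOWN"`) removes samples with
#' unknown smoking history and encodes treatment contrasts (reference levels
#' absorbed by the model intercept: `sex_M`, `smoking_CURRENT`). Machine
#' learning mode (`smoking_mode = "UNKNOWN_LEVEL"`) keeps all samples and
#' one-hot encodes smoking into its three levels. The phenotype, when
#' included, is always one-hot encoded into one indicator per group present.
#'
#' @param meta validated [sample_metadata()] data.frame.
#' @param include character subset of
#'   `c("sex", "age", "bmi", "smoking", "meds", "phenotype")`.
#' @param smoking_mode "DROP_UNKNOWN" or "UNKNOWN_LEVEL".
#' @return numeric matrix with sample IDs as rownames; attribute
#'   `"phenotype_cols"` names the phenotype indicator columns (if any).
#' @export
encode_design <- function(meta,
                          include = c("sex", "age", "bmi", "smoking", "meds"),
                          smoking_mode = c("DROP_UNKNOWN", "UNKNOWN_LEVEL")) {
  smoking_mode <- match.arg(smoking_mode)
  allowed <- c("sex", "age", "bmi", "smoking", "meds", "phenotype")
  bad <- setdiff(include, allowed)
  if (length(bad)) stop("unknown include flag(s): ", paste(bad, collapse = ", "))

  if ("smoking" %in% include && smoking_mode == "DROP_UNKNOWN") {
    meta <- meta[meta$smoking != "UNKNOWN", , drop = FALSE]
  }
  cols <- list()
  if ("sex" %in% include) cols$sex_M <- as.numeric(meta$sex == "M")
  if ("age" %in% include) cols$age <- meta$age
  if ("bmi" %in% include) cols$bmi <- meta$bmi
  if ("smoking" %in% include) {
    if (smoking_mode == "UNKNOWN_LEVEL") {
      cols$smoking_NEVER_FORMER <- as.numeric(meta$smoking == "NEVER_FORMER")
      cols$smoking_CURRENT <- as.numeric(meta$smoking == "CURRENT")
      cols$smoking_UNKNOWN <- as.numeric(meta$smoking == "UNKNOWN")
    } else {
      cols$smoking_CURRENT <- as.numeric(meta$smoking == "CURRENT")
    }
  }
  if ("meds" %in% include) {
    cols$med_prednisone <- as.numeric(meta$med_prednisone)
    cols$med_bdmard <- as.numeric(meta$med_bdmard)
    cols$med_csdmard <- as.numeric(meta$med_csdmard)
    cols$med_mtx <- as.numeric(meta$med_mtx)
  }
  pheno_cols <- character()
  if ("phenotype" %in% include) {
    for (g in intersect(c("ACPA_NEG", "ACPA_POS", "CONTROL"), unique(meta$group))) {
      nm <- paste0("pheno_", g)
      cols[[nm]] <- as.numeric(meta$group == g)
      pheno_cols <- c(pheno_cols, nm)
    }
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(meta), ncol = 0)
  rownames(X) <- meta$sample_id
  attr(X, "phenotype_cols") <- pheno_cols
  X
}
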