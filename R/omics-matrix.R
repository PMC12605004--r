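#' Construct an OmicsMatrix
#'
#' The package's central container: a samples x features abundance matrix with
#' per-feature metadata. Missing cells are stored as `NA` in `values`; the
#' missingness mask is always `is.na(values)` and can be retrieved with
#' [missing_mask()]. Protein feature identity is the pair
#' (display_name, platform_barcode), so the same protein measured by two
#' aptamer reagents yields two distinct features.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   Row names are sample IDs, column names feature IDs. Observed values must
#'   be non-negative for abundance data (not enforced, to allow log scale).
#' @param feature_info data.frame with one row per feature, columns
#'   `feature_id`, `kind` ("protein" or "metabolite"), `display_name`,
#'   `platform_barcode` (NA for metabolites), and optional annotation columns
#'   such as `super_pathway`, `sub_pathway`.
#' @param log_transformed logical flag recording whether `values` are on the
#'   natural-log scale.
#' @return an object of class `OmicsMatrix`.
#' @export
omics_matrix <- function(values, feature_info, log_transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample IDs as rownames and feature IDs as colnames")
  }
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  }
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f)) {
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  }
  stopifnot(is.data.frame(feature_info))
  req <- c("feature_id", "kind", "display_name", "platform_barcode")
  miss <- setdiff(req, names(feature_info))
  if (length(miss)) stop("feature_info lacks columns: ", paste(miss, collapse = ", "))
  if (!identical(feature_info$feature_id, colnames(values))) {
    stop("feature_info$feature_id must match colnames(values) in order")
  }
  if (!all(feature_info$kind %in% c("protein", "metabolite"))) {
    stop("feature kind must be 'protein' or 'metabolite'")
  }
  rownames(feature_info) <- NULL
  structure(
    list(values = values, feature_info = feature_info,
         log_transformed = isTRUE(log_transformed)),
    class = "OmicsMatrix"
  )
}

#' @exportS3Method base::print
print.OmicsMatrix <- function(x, ...) {
  nk <- table(x$feature_info$kind)
  cat(sprintf("OmicsMatrix: %d samples x %d features (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", nk, names(nk)), collapse = ", "),
              if (x$log_transformed) ", log scale" else ""))
  nm <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nm, 100 * nm / length(x$values)))
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' Sample and feature identifiers of an OmicsMatrix
#' @param m an OmicsMatrix.
#' @return character vector of IDs.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(m) colnames(m$values)

#' Missingness mask
#' @param m an OmicsMatrix.
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(m) is.na(m$values)

#' Subset an OmicsMatrix
#' @param m an OmicsMatrix.
#' @param samples,features character or integer index; `NULL` keeps all.
#' @return an OmicsMatrix.
#' @export
omics_subset <- function(m, samples = NULL, features = NULL) {
  v <- m$values
  fi <- m$feature_info
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) {
    v <- v[, features, drop = FALSE]
    fi <- fi[match(colnames(v), fi$feature_id), , drop = FALSE]
  }
  omics_matrix(v, fi, m$log_transformed)
}

#' Natural-log transform protein abundances
#'
#' Aptamer readouts are strictly positive relative fluorescence units with
#' multiplicative noise; downstream statistics operate on the log scale by
#' default. Metabolite columns (already median-scaled) are logged too when
#' `kinds` includes them; the default transforms only proteins.
#'
#' @param m an OmicsMatrix with strictly positive observed values for the
#'   selected kinds.
#' @param kinds feature kinds to transform.
#' @return an OmicsMatrix flagged `log_transformed`.
#' @export
log_transform <- function(m, kinds = "protein") {
  if (m$log_transformed) stop("matrix is already log transformed")
  sel <- m$feature_info$kind %in% kinds
  v <- m$values
  bad <- which(v[, sel, drop = FALSE] <= 0)
  if (length(bad)) stop("non-positive values cannot be log transformed")
  v[, sel] <- log(v[, sel, drop = FALSE])
  omics_matrix(v, m$feature_info, log_transformed = TRUE)
}

#' Validate a sample metadata table
#'
#' @param df data.frame with columns `sample_id`, `group` (one of
#'   "ACPA_NEG", "ACPA_POS", "CONTROL"), `sex` ("F"/"M"), `age` (years),
#'   `bmi` (kg/m^2), `smoking` ("NEVER_FORMER"/"CURRENT"/"UNKNOWN"),
#'   logical medication flags `med_prednisone`, `med_bdmard`, `med_csdmard`,
#'   `med_mtx`, and optional clinical markers `esr` (mm/hr), `crp` (mg/L),
#'   `das28crp` (which may be NA, e.g. for controls).
#' @return the validated data.frame (factors normalised, flags coerced to
#'   logical, missing marker columns added as NA).
#' @export
sample_metadata <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("sample_id", "group", "sex", "age", "bmi", "smoking",
           "med_prednisone", "med_bdmard", "med_csdmard", "med_mtx")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample IDs: ", paste(dup, collapse = ", "))
  df$group <- as.character(df$group)
  if (any(is.na(df$group)) || !all(df$group %in% c("ACPA_NEG", "ACPA_POS", "CONTROL"))) {
    stop("group must be one of ACPA_NEG, ACPA_POS, CONTROL and never missing")
  }
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(df$smoking %in% c("NEVER_FORMER", "CURRENT", "UNKNOWN"))) {
    stop("smoking must be NEVER_FORMER, CURRENT or UNKNOWN")
  }
  for (fl in c("med_prednisone", "med_bdmard", "med_csdmard", "med_mtx")) {
    df[[fl]] <- as.logical(df[[fl]])
    if (any(is.na(df[[fl]]))) stop("medication flag ", fl, " must not be missing")
  }
  for (mk in c("esr", "crp", "das28crp")) {
    if (is.null(df[[mk]])) df[[mk]] <- NA_real_
    df[[mk]] <- as.numeric(df[[mk]])
  }
  rownames(df) <- NULL
  df
}
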