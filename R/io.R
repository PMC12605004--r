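#' Read a delimited abundance table into an OmicsMatrix
#'
#' Expects one header row of feature IDs and one ID column of samples (or the
#' transpose — the orientation is declared, never guessed from shape).
#' Protein feature IDs carry the platform barcode after a separator
#' (e.g. `"C9|SL000461"`), so the same display name measured by different
#' aptamer reagents stays two distinct features. Cells matching `na_tokens`
#' are recorded as missing; any other non-numeric cell is a hard error with
#' its coordinates.
#'
#' @param path TSV/CSV file path (delimiter inferred from the extension:
#'   `.csv` means comma, anything else tab).
#' @param omic_kind "protein" or "metabolite".
#' @param exclusion_list optional character vector of feature IDs to drop
#'   (control/non-human analytes and the like).
#' @param samples_in "rows" (default) or "cols": where samples live.
#' @param na_tokens cell values treated as missing.
#' @param barcode_sep separator between display name and platform barcode in
#'   protein feature IDs.
#' @return an OmicsMatrix; the QC counts (features read, excluded, missing
#'   cells) are attached as attribute `"qc"`.
#' @export
load_feature_table <- function(path, omic_kind = c("protein", "metabolite"),
                               exclusion_list = NULL,
                               samples_in = c("rows", "cols"),
                               na_tokens = c("", "NA", "NaN", "nan"),
                               barcode_sep = "|") {
  omic_kind <- match.arg(omic_kind)
  samples_in <- match.arg(samples_in)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", na.strings = character(0))
  ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  rownames(cells) <- ids
  if (samples_in == "cols") cells <- t(cells)
  # rows = samples, cols = features from here on
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                dimnames = dimnames(cells)))
  is_na_tok <- array(cells %in% na_tokens | is.na(cells), dim = dim(cells))
  bad <- which(is.na(num) & !is_na_tok, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at sample '%s', feature '%s'",
                 cells[bad[1, 1], bad[1, 2]],
                 rownames(cells)[bad[1, 1]], colnames(cells)[bad[1, 2]]))
  }
  num[is_na_tok] <- NA_real_

  fids <- colnames(num)
  dupf <- unique(fids[duplicated(fids)])
  if (length(dupf)) stop("duplicate feature IDs: ", paste(dupf, collapse = ", "))
  dups <- unique(rownames(num)[duplicated(rownames(num))])
  if (length(dups)) stop("duplicate sample IDs: ", paste(dups, collapse = ", "))

  n_total <- length(fids)
  if (!is.null(exclusion_list)) {
    keep <- !(fids %in% exclusion_list)
    num <- num[, keep, drop = FALSE]
    fids <- fids[keep]
  }
  n_excluded <- n_total - length(fids)

  if (omic_kind == "protein") {
    parts <- strsplit(fids, barcode_sep, fixed = TRUE)
    display <- vapply(parts, `[`, "", 1L)
    barcode <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  } else {
    display <- fids
    barcode <- rep(NA_character_, length(fids))
  }
  fi <- data.frame(feature_id = fids, kind = omic_kind, display_name = display,
                   platform_barcode = barcode, stringsAsFactors = FALSE)
  m <- omics_matrix(num, fi)
  attr(m, "qc") <- list(n_features_read = n_total, n_excluded = n_excluded,
                        n_missing_cells = sum(is.na(num)))
  m
}

#' Read a sample metadata table
#'
#' @param path TSV/CSV with the [sample_metadata()] columns.
#' @return validated metadata data.frame.
#' @export
load_sample_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  sample_metadata(df)
}

#' Write an OmicsMatrix as a TSV (samples in rows)
#' @param m an OmicsMatrix.
#' @param path output file.
#' @export
write_omics_table <- function(m, path) {
  df <- data.frame(sample_id = sample_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
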