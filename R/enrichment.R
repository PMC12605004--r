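#' Build an annotation collection
#'
#' Terms are intersected with the declared universe; terms left empty by the
#' intersection are dropped.
#'
#' @param term_members named list mapping term IDs to character vectors of
#'   member feature IDs.
#' @param universe character vector of all eligible feature IDs.
#' @param term_names optional named character vector of display names.
#' @return an `annotation_collection` list.
#' @export
annotation_collection <- function(term_members, universe, term_names = NULL) {
  stopifnot(is.list(term_members), length(universe) > 0)
  members <- lapply(term_members, function(m) intersect(unique(m), universe))
  members <- members[lengths(members) > 0]
  structure(list(members = members, universe = unique(universe),
                 term_names = term_names),
            class = "annotation_collection")
}

#' Read annotations from a two-column TSV or a GMT file
#'
#' TSV format: two columns, `term_id` and `feature_id`, one membership per
#' row. GMT format: one term per line, tab-separated
#' `term<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path; GMT detected by the `.gmt` extension.
#' @param universe eligible feature universe.
#' @return an [annotation_collection()].
#' @export
read_annotations <- function(path, universe) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    tm <- lapply(parts, function(p) p[-(1:2)])
    names(tm) <- vapply(parts, `[`, "", 1L)
    nm <- stats::setNames(vapply(parts, `[`, "", 2L), names(tm))
    return(annotation_collection(tm, universe, nm))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  annotation_collection(split(df[[2]], df[[1]]), universe)
}

#' One-tailed Fisher exact (hypergeometric) set enrichment
#'
#' For each term with overlap `k`, term size `K`, hit-set size `n` and
#' universe size `N`: the standard mode reports the upper hypergeometric
#' tail `P(X >= k)`; the EASE mode reports `P(X >= k - 1)` (with `k - 1`
#' floored at 0), the conservative "modified" one-tailed Fisher variant used
#' by DAVID. A term is flagged enriched iff `p < alpha` and `k >= min_overlap`.
#' Benjamini-Hochberg q-values are an extra column, not part of the flag.
#'
#' @param hits character vector of hit feature IDs; must be a subset of the
#'   universe.
#' @param ann an [annotation_collection()]; its universe defines `N`.
#' @param mode "standard" or "ease".
#' @param alpha significance gate.
#' @param min_overlap minimum overlap for the enriched flag.
#' @return data.frame per term: `term_id`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `enriched`.
#' @export
fisher_enrichment <- function(hits, ann, mode = c("standard", "ease"),
                              alpha = 0.05, min_overlap = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(ann, "annotation_collection"))
  hits <- unique(hits)
  outside <- setdiff(hits, ann$universe)
  if (length(outside)) {
    stop("hits outside the universe: ", paste(outside, collapse = ", "))
  }
  N <- length(ann$universe)
  n <- length(hits)
  res <- lapply(names(ann$members), function(t) {
    K <- length(ann$members[[t]])
    k <- length(intersect(hits, ann$members[[t]]))
    k_eff <- if (mode == "ease") max(k - 1L, 0L) else k
    # P(X >= k_eff), X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p < alpha & out$k >= min_overlap
  out[order(out$p), ]
}

#' Annotation collection from OmicsMatrix pathway metadata
#'
#' Convenience builder that turns `super_pathway`/`sub_pathway` feature
#' annotation columns into terms over the features passing QC.
#'
#' @param m an OmicsMatrix whose `feature_info` carries the given column.
#' @param level annotation column name ("sub_pathway" or "super_pathway").
#' @return an [annotation_collection()] over `feature_ids(m)`.
#' @export
pathway_annotations <- function(m, level = "sub_pathway") {
  fi <- m$feature_info
  if (is.null(fi[[level]])) stop("feature_info has no column '", level, "'")
  ok <- !is.na(fi[[level]])
  annotation_collection(split(fi$feature_id[ok], fi[[level]][ok]),
                        feature_ids(m))
}
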