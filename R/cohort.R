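#' Two-sided Fisher exact test for an r x c contingency table
#'
#' For 2x2 tables this is the usual exact convention: the sum of
#' hypergeometric point probabilities no larger than the observed table's.
#' Larger tables use the Freeman-Halton generalization (full enumeration
#' over tables with fixed margins). Tables with totals beyond the
#' enumeration bound must use the Monte-Carlo mode.
#'
#' @param tab integer matrix (at least 2x2, non-negative counts).
#' @param monte_carlo use Monte-Carlo p-value estimation instead of
#'   enumeration (required when the total exceeds `max_total`).
#' @param B Monte-Carlo replicates.
#' @param max_total enumeration bound on the table total.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab, monte_carlo = FALSE, B = 1e5,
                         max_total = 10000) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  if (!monte_carlo && sum(tab) > max_total) {
    stop("table total ", sum(tab), " exceeds the enumeration bound ",
         max_total, "; use monte_carlo = TRUE")
  }
  if (monte_carlo) {
    stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
  } else {
    stats::fisher.test(tab, workspace = 2e7)$p.value
  }
}

#' Kruskal-Wallis rank sum test across groups
#'
#' H statistic with tie correction and the chi-square p-value on k-1 degrees
#' of freedom. When every value is identical the test is undefined; p = 1 is
#' returned with a flag instead of an error.
#'
#' @param groups list of numeric vectors (>= 2 groups, >= 2 values each).
#' @return list with `H`, `df`, `p`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) {
    return(list(H = 0, df = length(groups) - 1, p = 1, degenerate = TRUE))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, degenerate = FALSE)
}

.q17 <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))

#' Cohort characteristics table
#'
#' Per-group summaries with the usual test pairing: Fisher exact for
#' categorical variables, Kruskal-Wallis for continuous ones. Continuous
#' variables report mean +/- SD, [Q1, Q3] (linear-interpolation quantiles)
#' and min-max, with unknown (NA) counts reported but excluded from the
#' test; the "Unknown" smoking level is likewise its own row, excluded from
#' the smoking test. Medication flags and clinical markers are compared
#' between the two RA subgroups only (controls carry no disease activity or
#' treatment).
#'
#' @param meta validated sample metadata.
#' @return data.frame: `variable`, `type`, one summary column per group,
#'   `p_value`, `test`.
#' @export
cohort_table <- function(meta) {
  gs <- intersect(c("ACPA_NEG", "ACPA_POS", "CONTROL"), unique(meta$group))
  if (length(gs) < 2) stop("at least 2 groups required")
  ra <- intersect(c("ACPA_NEG", "ACPA_POS"), gs)
  rows <- list()

  cont_summary <- function(x) {
    if (all(is.na(x))) return("N/A")
    sprintf("%.1f ± %.1f [%.1f, %.1f] %.1f–%.1f (unknown %d)",
            mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE),
            .q17(x, 0.25), .q17(x, 0.75),
            min(x, na.rm = TRUE), max(x, na.rm = TRUE), sum(is.na(x)))
  }
  cont_row <- function(name, col, test_groups = gs) {
    vals <- lapply(gs, function(g) meta[[col]][meta$group == g])
    names(vals) <- gs
    tv <- lapply(test_groups, function(g) vals[[g]][!is.na(vals[[g]])])
    p <- if (length(tv) >= 2 && all(lengths(tv) >= 2)) {
      kruskal_wallis(tv)$p
    } else NA_real_
    c(list(variable = name, type = "continuous"),
      lapply(vals, cont_summary), list(p_value = p, test = "Kruskal-Wallis"))
  }
  cat_row <- function(name, x, test_groups = gs, drop_level = NULL) {
    vals <- lapply(gs, function(g) x[meta$group == g])
    names(vals) <- gs
    lv <- sort(unique(x))
    summ <- lapply(vals, function(v) {
      paste(sprintf("%s:%d", lv, vapply(lv, function(l) sum(v == l), 0L)),
            collapse = " ")
    })
    xt <- x
    keep <- meta$group %in% test_groups
    if (!is.null(drop_level)) keep <- keep & xt != drop_level
    tab <- table(meta$group[keep], xt[keep])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    p <- if (nrow(tab) >= 2 && ncol(tab) >= 2) fisher_exact(tab) else NA_real_
    c(list(variable = name, type = "categorical"), summ,
      list(p_value = p, test = "Fisher exact"))
  }

  rows$sex <- cat_row("Sex", meta$sex)
  rows$age <- cont_row("Age (years)", "age")
  rows$bmi <- cont_row("BMI (kg/m2)", "bmi")
  rows$smoking <- cat_row("Smoking history", meta$smoking,
                          drop_level = "UNKNOWN")
  if (length(ra) == 2) {
    rows$esr <- cont_row("ESR (mm/hr)", "esr", test_groups = ra)
    rows$crp <- cont_row("CRP (mg/L)", "crp", test_groups = ra)
    rows$das <- cont_row("DAS28-CRP", "das28crp", test_groups = ra)
    for (fl in c("med_mtx", "med_prednisone", "med_bdmard", "med_csdmard")) {
      rows[[fl]] <- cat_row(fl, ifelse(meta[[fl]], "yes", "no"),
                            test_groups = ra)
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  rownames(out) <- NULL
  out
}
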