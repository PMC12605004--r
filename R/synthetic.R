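#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a three-group
#' (ACPA-negative RA, ACPA-positive RA, healthy control) plasma multi-omic
#' study: two omic blocks of very different dimensionality, lognormal
#' abundances with latent-factor correlation, planted group mean-shifts of a
#' target Cohen's d, optional covariate effects and group-conditional
#' covariate confounding, inflammation markers coupled to planted features in
#' the RA samples, and abundance-dependent (lowest-value) metabolite
#' censoring.
#'
#' @param n_per_group samples per group (balanced three-group design).
#' @param n_proteins,n_metabolites features per omic block.
#' @param planted data.frame with columns `feature_id`, `group` (one of
#'   "ACPA_NEG", "ACPA_POS", "BOTH"), `target_d` (population Cohen's d of the
#'   shifted group vs the others on the latent log scale); NULL for none.
#' @param n_factors number of shared latent factors.
#' @param loading_scale SD of the Gaussian factor loadings.
#' @param covariate_effects named list mapping a covariate
#'   (`"sex_M"`, `"age"`, `"bmi"`, `"smoking_CURRENT"`, `"med_prednisone"`,
#'   `"med_bdmard"`, `"med_csdmard"`, `"med_mtx"`) to a data.frame
#'   `(feature_id, coef)`; continuous covariates act standardized.
#' @param confounding named list switching on group-conditional covariate
#'   distributions: `"age"` / `"bmi"` map to numeric per-group mean offsets
#'   named by group; `"meds_zero_groups"` names groups whose medication
#'   flags are forced FALSE (e.g. `"CONTROL"` for an untreated control arm,
#'   which makes the flags partially collinear with the phenotype, as in
#'   real cohorts). The default (empty list) draws every covariate from the
#'   same distribution in all three groups, so the cohort is exchangeable
#'   across groups apart from the planted shifts.
#' @param marker_coupling data.frame `(feature_id, marker, coef)` with marker
#'   in `c("esr", "crp", "das28crp")`; couples RA clinical markers to planted
#'   (or any) features. NULL for none.
#' @param missing_censor_frac fraction of each metabolite's lowest values
#'   censored to missing, in `[0, 0.5]`.
#' @param noise_sd SD of the per-cell Gaussian noise on the log scale.
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = 40, n_proteins = 250,
                             n_metabolites = 50, planted = NULL,
                             n_factors = 5, loading_scale = 0.2,
                             covariate_effects = list(),
                             confounding = list(),
                             marker_coupling = NULL,
                             missing_censor_frac = 0.10,
                             noise_sd = 0.5, seed = 1) {
  stopifnot(n_per_group >= 1, n_proteins >= 1, n_metabolites >= 1,
            n_factors >= 1, noise_sd > 0)
  if (missing_censor_frac < 0 || missing_censor_frac > 0.5) {
    stop("missing_censor_frac must lie in [0, 0.5]")
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("feature_id", "group", "target_d") %in% names(planted)))
    if (!all(is.finite(planted$target_d))) stop("target_d must be finite")
    if (!all(planted$group %in% c("ACPA_NEG", "ACPA_POS", "BOTH"))) {
      stop("planted group must be ACPA_NEG, ACPA_POS or BOTH")
    }
  }
  structure(list(n_per_group = n_per_group, n_proteins = n_proteins,
                 n_metabolites = n_metabolites, planted = planted,
                 n_factors = n_factors, loading_scale = loading_scale,
                 covariate_effects = covariate_effects,
                 confounding = confounding,
                 marker_coupling = marker_coupling,
                 missing_censor_frac = missing_censor_frac,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Feature IDs a config will generate
#' @param cfg a [synthetic_config()].
#' @return list with `proteins` and `metabolites` character vectors.
#' @export
synthetic_feature_ids <- function(cfg) {
  list(proteins = sprintf("P%04d|SOMA%04d", seq_len(cfg$n_proteins),
                          seq_len(cfg$n_proteins)),
       metabolites = sprintf("M%04d", seq_len(cfg$n_metabolites)))
}

#' Mean shift achieving a target Cohen's d
#'
#' Returns the additive shift `delta = target_d * total_sd` such that the
#' population standardized mean difference (pooled-SD Cohen's d) between the
#' shifted and unshifted group equals `target_d`, given the common
#' within-group SD `total_sd`.
#'
#' @param target_d desired population Cohen's d.
#' @param total_sd within-group SD of the variable being shifted (> 0).
#' @return the shift, a single numeric.
#' @export
calibrate_shift <- function(target_d, total_sd) {
  if (!is.finite(target_d)) stop("target_d must be finite")
  if (!is.numeric(total_sd) || total_sd <= 0) stop("total_sd must be positive")
  target_d * total_sd
}

#' Generate a synthetic multi-omic cohort
#'
#' Latent log-abundance per cell: baseline + factor term + planted group
#' shift + covariate term + Gaussian noise. Proteins are exported as
#' `exp(z)` (RFU-like positive reals). Metabolites are exported after
#' per-feature censoring of the lowest `missing_censor_frac` of values
#' (missing-not-at-random, the mechanism minimum imputation presumes) and
#' division by the median of the observed values. ESR/CRP/DAS28-CRP are
#' monotone transforms of a linear combination of the coupled features'
#' latents plus noise, generated for RA samples only (controls NA).
#'
#' Planted shifts are calibrated with [calibrate_shift()] against the
#' covariate-free within-group SD `sqrt(sum(loadings^2) + noise_sd^2)`;
#' configured covariate effects add variance on top of that calibration.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `proteins` (OmicsMatrix), `metabolites`
#'   (OmicsMatrix with missing cells), `meta` (validated sample metadata) and
#'   `truth` (planted shifts, loadings, covariate coefficients, censored-cell
#'   mask, marker coupling).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ids <- synthetic_feature_ids(cfg)
  all_ids <- c(ids$proteins, ids$metabolites)
  if (!is.null(cfg$planted)) {
    bad <- setdiff(cfg$planted$feature_id, all_ids)
    if (length(bad)) stop("planted feature IDs outside the feature range: ",
                          paste(bad, collapse = ", "))
  }
  withr::with_seed(cfg$seed, .generate_cohort_impl(cfg, ids, all_ids))
}

.generate_cohort_impl <- function(cfg, ids, all_ids) {
  ng <- cfg$n_per_group
  n <- 3L * ng
  p <- length(all_ids)
  groups <- rep(c("ACPA_NEG", "ACPA_POS", "CONTROL"), each = ng)
  sid <- sprintf("S%04d", seq_len(n))

  off <- function(cov) {
    o <- cfg$confounding[[cov]]
    if (is.null(o)) rep(0, n) else unname(o[groups])
  }
  age <- stats::rnorm(n, 58, 10.5) + off("age")
  bmi <- stats::rnorm(n, 29.5, 7) + off("bmi")
  sex <- ifelse(stats::runif(n) < 0.72, "F", "M")
  smoking <- sample(c("NEVER_FORMER", "CURRENT", "UNKNOWN"), n, replace = TRUE,
                    prob = c(0.90, 0.07, 0.03))
  is_ra <- groups != "CONTROL"
  med_on <- !(groups %in% (cfg$confounding$meds_zero_groups %||% character()))
  med <- function(pr) med_on & stats::runif(n) < pr
  meta <- sample_metadata(data.frame(
    sample_id = sid, group = groups, sex = sex, age = age, bmi = bmi,
    smoking = smoking,
    med_prednisone = med(0.25), med_bdmard = med(0.20),
    med_csdmard = med(0.30), med_mtx = med(0.50),
    stringsAsFactors = FALSE))

  L <- matrix(stats::rnorm(p * cfg$n_factors, sd = cfg$loading_scale),
              p, cfg$n_factors, dimnames = list(all_ids, NULL))
  f <- matrix(stats::rnorm(n * cfg$n_factors), n, cfg$n_factors)
  total_sd <- sqrt(rowSums(L^2) + cfg$noise_sd^2)

  mu <- c(stats::rnorm(cfg$n_proteins, 7, 1), rep(0, cfg$n_metabolites))
  z <- matrix(rep(mu, each = n), n, p, dimnames = list(sid, all_ids)) +
    f %*% t(L) +
    matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)

  planted <- cfg$planted
  if (!is.null(planted)) {
    planted$shift <- vapply(seq_len(nrow(planted)), function(i) {
      calibrate_shift(planted$target_d[i], total_sd[planted$feature_id[i]])
    }, 0)
    for (i in seq_len(nrow(planted))) {
      gsel <- if (planted$group[i] == "BOTH") is_ra else groups == planted$group[i]
      z[gsel, planted$feature_id[i]] <- z[gsel, planted$feature_id[i]] + planted$shift[i]
    }
  }

  cov_tab <- cbind(sex_M = as.numeric(sex == "M"),
                   age = (age - mean(age)) / stats::sd(age),
                   bmi = (bmi - mean(bmi)) / stats::sd(bmi),
                   smoking_CURRENT = as.numeric(smoking == "CURRENT"),
                   med_prednisone = as.numeric(meta$med_prednisone),
                   med_bdmard = as.numeric(meta$med_bdmard),
                   med_csdmard = as.numeric(meta$med_csdmard),
                   med_mtx = as.numeric(meta$med_mtx))
  for (cov in names(cfg$covariate_effects)) {
    if (!cov %in% colnames(cov_tab)) stop("unknown covariate in effects: ", cov)
    eff <- cfg$covariate_effects[[cov]]
    z[, eff$feature_id] <- z[, eff$feature_id] +
      outer(cov_tab[, cov], eff$coef)
  }

  # clinical markers from coupled latents, RA samples only
  mk <- function(marker) {
    m <- stats::rnorm(n)
    mc <- cfg$marker_coupling
    if (!is.null(mc)) {
      mc <- mc[mc$marker == marker, , drop = FALSE]
      for (i in seq_len(nrow(mc))) {
        zz <- z[, mc$feature_id[i]]
        m <- m + mc$coef[i] * (zz - mean(zz)) / stats::sd(zz)
      }
    }
    m
  }
  meta$esr <- ifelse(is_ra, 12 * exp(0.6 * mk("esr")), NA_real_)
  meta$crp <- ifelse(is_ra, 5 * exp(0.8 * mk("crp")), NA_real_)
  meta$das28crp <- ifelse(is_ra, 1.5 + 5 * stats::plogis(mk("das28crp")), NA_real_)

  prot_v <- exp(z[, ids$proteins, drop = FALSE])
  prot_fi <- data.frame(feature_id = ids$proteins, kind = "protein",
                        display_name = sub("\\|.*", "", ids$proteins),
                        platform_barcode = sub(".*\\|", "", ids$proteins),
                        stringsAsFactors = FALSE)
  proteins <- omics_matrix(prot_v, prot_fi)

  met_v <- exp(z[, ids$metabolites, drop = FALSE])
  k_cens <- floor(cfg$missing_censor_frac * n)
  cens <- matrix(FALSE, n, cfg$n_metabolites,
                 dimnames = dimnames(met_v))
  if (k_cens > 0) {
    for (j in seq_len(ncol(met_v))) {
      cens[order(met_v[, j])[seq_len(k_cens)], j] <- TRUE
    }
  }
  met_v[cens] <- NA_real_
  met_v <- sweep(met_v, 2, apply(met_v, 2, stats::median, na.rm = TRUE), "/")
  sub_paths <- paste0("pathway_", 1 + (seq_len(cfg$n_metabolites) - 1) %% 8)
  met_fi <- data.frame(feature_id = ids$metabolites, kind = "metabolite",
                       display_name = ids$metabolites,
                       platform_barcode = NA_character_,
                       super_pathway = ifelse(sub_paths %in% paste0("pathway_", 1:4),
                                              "super_A", "super_B"),
                       sub_pathway = sub_paths,
                       stringsAsFactors = FALSE)
  metabolites <- omics_matrix(met_v, met_fi)

  list(proteins = proteins, metabolites = metabolites, meta = meta,
       truth = list(planted = planted, loadings = L,
                    covariate_effects = cfg$covariate_effects,
                    censored_mask = cens,
                    marker_coupling = cfg$marker_coupling,
                    total_sd = total_sd))
}

#' Write a generated cohort to disk in the formats the loaders read
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(proteins = file.path(dir, "proteins.tsv"),
                metabolites = file.path(dir, "metabolites.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  write_omics_table(cohort$proteins, paths$proteins)
  write_omics_table(cohort$metabolites, paths$metabolites)
  utils::write.table(cohort$meta, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(planted = tr$planted,
         n_censored_cells = sum(tr$censored_mask),
         marker_coupling = tr$marker_coupling),
    paths$truth, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
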