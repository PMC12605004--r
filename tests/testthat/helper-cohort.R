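# Shared fixture builders; everything is generated in code at test time.

plant <- function(n = 20, group = "BOTH", d = 1.2, kind = "protein") {
  ids <- if (kind == "protein") sprintf("P%04d|SOMA%04d", seq_len(n), seq_len(n))
         else sprintf("M%04d", seq_len(n))
  data.frame(feature_id = ids, group = group, target_d = d,
             stringsAsFactors = FALSE)
}

# small three-group cohort with both blocks merged and analysis-ready
make_merged_cohort <- function(seed, n_per_group = 40, n_proteins = 60,
                               n_metabolites = 20, planted = NULL, ...) {
  co <- generate_cohort(synthetic_config(
    n_per_group = n_per_group, n_proteins = n_proteins,
    n_metabolites = n_metabolites, planted = planted, seed = seed, ...))
  co$data <- merge_analysis_ready(co)
  co
}

merge_analysis_ready <- function(co) {
  met <- scale_and_impute(filter_by_missingness(co$metabolites))
  met$log_transformed <- TRUE  # metabolites stay on the scaled-imputed scale
  merge_omics(log_transform(co$proteins), met)
}

# tiny hand-built OmicsMatrix
toy_matrix <- function(values, kind = "protein") {
  fi <- data.frame(feature_id = colnames(values), kind = kind,
                   display_name = sub("\\|.*", "", colnames(values)),
                   platform_barcode = NA_character_,
                   stringsAsFactors = FALSE)
  omics_matrix(values, fi)
}

toy_meta <- function(n, groups = c("ACPA_NEG", "ACPA_POS", "CONTROL"),
                     seed = 1) {
  withr::with_seed(seed, sample_metadata(data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    group = rep(groups, length.out = n),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = stats::rnorm(n, 58, 10),
    bmi = stats::rnorm(n, 29, 6),
    smoking = sample(c("NEVER_FORMER", "CURRENT", "UNKNOWN"), n,
                     replace = TRUE, prob = c(0.9, 0.07, 0.03)),
    med_prednisone = stats::runif(n) < 0.25,
    med_bdmard = stats::runif(n) < 0.2,
    med_csdmard = stats::runif(n) < 0.3,
    med_mtx = stats::runif(n) < 0.5,
    stringsAsFactors = FALSE)))
}

# independent hypergeometric upper-tail oracle (direct enumeration)
hyper_tail_oracle <- function(k, K, n, N) {
  js <- seq(max(0, k), min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# independent 2x2 two-sided Fisher oracle: sum of point probabilities
# no larger than the observed table's, over all tables with fixed margins
fisher2x2_oracle <- function(a, b, c, d) {
  rs <- a + b; cs <- a + c; N <- a + b + c + d
  lo <- max(0, cs - (N - rs)); hi <- min(rs, cs)
  probs <- vapply(lo:hi, function(x) {
    choose(rs, x) * choose(N - rs, cs - x) / choose(N, cs)
  }, 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
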