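# omninet

Network-guided integration of plasma proteomics and metabolomics for
clinically stratified cohorts, built around rheumatoid arthritis (RA)
subgroups defined by anti-citrullinated protein antibody (ACPA) status.
It is aimed at computational biologists who have paired sample × feature
abundance tables (aptamer-based protein RFUs; scaled-imputed metabolite
intensities), a clinical metadata table, and want the full chain from QC to
phenotype-predictive feature subnetworks — or who want to validate that
chain on synthetic cohorts with known ground truth.

## What it computes

**Differential abundance.** Per feature, OLS of abundance on a phenotype
indicator adjusted for sex, age, BMI, smoking and medication use; a feature
is phenotype-associated when the coefficient's two-sided *P* < 0.01 and the
pooled-SD effect size |*d*| > 0.5 (relaxed gate *P* < 0.05 for pathway
analysis).

**Network inference.** Per-feature elastic-net neighborhood selection:
each omic feature *y* is regressed on all other features, covariates and
one-hot phenotype indicators with penalty
λ·(λ₁‖β‖₁ + λ₂‖β‖₂²), λ₁ + λ₂ = 1, tuned by 10-fold CV minimizing RMSE;
non-zero coefficients become edges of one undirected, unweighted multi-omic
graph (union merge).

**Diffusion.** Random walk with restart from the phenotype nodes,
*p*⁽ᵗ⁺¹⁾ = (1−*r*)*A′p*⁽ᵗ⁾ + *r·p*⁰ with column-normalized adjacency *A′*,
restart *r* = 0.5, L1 termination at 1e-4; the stationary scores rank
features by phenotype proximity and the top-*N* induce a phenotype-centric
subnetwork.

**Classification.** Leakage-free stratified 5-fold CV: network inference,
RWR ranking and random-forest training all run per fold on the training
split only; metrics (rank-based AUC, accuracy, sensitivity, specificity,
PPV, NPV, F1, MCC) are reported at the subnetwork size with the highest mean
test AUC, with ANOVA-F, mutual-information and no-selection baselines on
identical folds.

Also included: subgroup-stratified Spearman correlation of features with
ESR/CRP/DAS28-CRP and cross-subgroup concordance calls; one-tailed
Fisher-exact set enrichment with DAVID's EASE-style conservative variant;
Fisher / Kruskal–Wallis cohort characteristics tables; and a synthetic
cohort generator (balanced three-group design, latent-factor correlation,
planted Cohen's-d shifts, MNAR metabolite censoring, marker coupling,
optional covariate confounding) so every stage is testable offline.

## Worked example

```r
library(omninet)

planted <- data.frame(feature_id = sprintf("P%04d|SOMA%04d", 1:10, 1:10),
                      group = "ACPA_NEG", target_d = 1.2)
cfg <- synthetic_config(n_per_group = 40, n_proteins = 120, n_metabolites = 30,
                        planted = planted, seed = 42)
cohort <- generate_cohort(cfg)

metab <- scale_and_impute(filter_by_missingness(cohort$metabolites))
metab$log_transformed <- TRUE   # metabolites stay on the scaled-imputed scale
data <- merge_omics(log_transform(cohort$proteins), metab)
data
#> OmicsMatrix: 120 samples x 150 features (30 metabolite, 120 protein), log scale
#>   missing cells: 0 (0.0%)

hits <- differential_features(data, cohort$meta, "ACPA_NEG_vs_CTRL")
head(hits[order(hits$p), c("feature_id", "beta", "p", "q", "d", "passes_strict")], 5)
#>       feature_id      beta            p            q        d passes_strict
#> 9 P0009|SOMA0009 1.0491347 2.075626e-12 3.113439e-10 1.993829          TRUE
#> 3 P0003|SOMA0003 0.6581795 9.858977e-10 7.394233e-08 1.739576          TRUE
#> 5 P0005|SOMA0005 1.2696417 1.521583e-08 7.607914e-07 1.526110          TRUE
#> 6 P0006|SOMA0006 1.2818376 4.262832e-07 1.598562e-05 1.368727          TRUE
#> 4 P0004|SOMA0004 0.6566181 6.847320e-06 2.054196e-04 1.204984          TRUE
sum(hits$passes_strict)
#> [1] 11

net <- infer_network(data, cohort$meta, seed = 1)
pheno <- igraph::V(net)$name[igraph::V(net)$kind == "phenotype"]
ranking <- rwr(net, seeds = pheno, r = 0.5)
top <- top_n_features(net, ranking, N = 20)
mean(planted$feature_id %in% top$nodes$node)   # planted-feature recall
#> [1] 0.6

cv <- run_task(data, cohort$meta, task = "ACPA_NEG_vs_CTRL",
               selector = "network_rwr", n_grid = c(10, 20, 50), cv_seed = 7)
cv
#> cv_result: ACPA_NEG_vs_CTRL | multi | selector=network_rwr | best N=50
#>   mean test AUC at best N: 0.994 (SD 0.014)
```

The differential table ranks the planted proteins on top, with *P* far
below 0.01, |*d*| scattered around the planted 1.2, and 11 strict calls
(the ten planted features plus one false positive at these thresholds). A
tight top-20 cut of the 150-node diffusion ranking already recovers 6 of
the 10 planted features, and the cross-validated classifier separates
ACPA− RA from controls with mean test AUC 0.994 at the best subnetwork
size — the expected behavior when ten features carry a standardized shift
of 1.2 at 40 samples per group.

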