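---
title: "Network-guided multi-omic analysis of RA subgroups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided multi-omic analysis of RA subgroups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Rheumatoid arthritis stratifies serologically into ACPA-positive and
ACPA-negative disease, and the ACPA-negative subgroup is the harder one to
characterize molecularly. `omninet` implements an end-to-end analysis for
paired plasma proteomic (aptamer RFU readouts, thousands of features) and
metabolomic (scaled-imputed LC-MS readouts, ~1/7 as many features) profiles
across three balanced groups — ACPA− RA, ACPA+ RA, healthy controls — with
five analysis layers:

1. covariate-adjusted differential abundance with an effect-size gate,
2. subgroup-stratified Spearman correlation against clinical inflammation
   markers (ESR, CRP, DAS28-CRP) with cross-subgroup concordance calls,
3. one-tailed Fisher-exact set enrichment over user-supplied annotations,
4. elastic-net neighborhood-selection network inference followed by random
   walk with restart (RWR) from phenotype seed nodes, and
5. leakage-free stratified cross-validated random-forest classification with
   the RWR ranking as the feature selector.

Every layer is testable without any external download because the package
ships a synthetic cohort generator that emulates the statistical structure
the analysis assumes.

# Preprocessing

**Metabolites.** Features missing in strictly more than 20% of samples are
removed (`filter_by_missingness`, a feature missing in exactly 20% stays).
Remaining features are divided by the median of their observed values (so
the observed median becomes exactly 1) and missing cells are filled with the
minimum of the scaled observed values (`scale_and_impute`). Scaling precedes
imputation; the package exposes this as the fixed order because minimum
imputation presumes missingness concentrated at low abundance, and the fill
value should live on the same per-feature scale as the observed data.

**Proteins.** Aptamer readouts are strictly positive RFUs with
multiplicative noise; the pipeline log-transforms them (natural log) before
all downstream statistics. This is a config flag (`log_transform`, default
on). Protein feature identity is the pair (display name, platform barcode):
two reagents measuring the same protein are two features, never collapsed.

**Design matrices.** Two encodings serve the two consumers. Regression mode
drops samples with unknown smoking history and uses treatment contrasts
(`sex_M`, `smoking_CURRENT`); machine-learning mode keeps all samples and
one-hot encodes smoking into its three levels. The phenotype is always
one-hot encoded (one indicator per group present), which is what makes
phenotype *nodes* possible in the network below.

# Differential abundance

Per feature, ordinary least squares of abundance on a phenotype indicator
plus confounders (sex, age, BMI, smoking, prednisone, bDMARD, csDMARD use),
run separately for ACPA− vs control and ACPA+ vs control. A feature is
called at the strict gate when the phenotype coefficient has two-sided
p < 0.01 *and* |Cohen's d| > 0.5; the relaxed gate (p < 0.05, used to feed
pathway analysis) is otherwise identical. Cohen's d uses the pooled-SD
definition on the unadjusted abundances of the same retained samples —
pairing a covariate-adjusted p with a plain standardized mean difference.
Design choices worth stating:

- d uses pooled SD (not control-arm SD); both appear in the literature and
  the package documents its pick rather than guessing at consensus.
- p-values are two-sided; no multiple-testing correction enters the gates,
  but Benjamini–Hochberg q-values are always emitted as an extra column.
- Medication covariates that are constant in a subset (e.g. a
  treatment-naive rerun via `subset_treatment_naive`, which always keeps
  controls) are dropped automatically; any *remaining* rank deficiency is a
  hard error naming the collinear columns.

# Clinical-marker correlation

Spearman's rho with average ranks for ties, pairwise-complete samples, and
the asymptotic two-sided t approximation for p (the exact-permutation
alternative matters only below ~10 pairs; the asymptotic choice is
documented). Concordance between subgroups for the same feature and marker:
a subgroup "passes" at |rho| > 0.4 and p < 0.05; both passing with one sign
is concordant, one passing while the other is non-significant is
subgroup-specific, both significant with opposite signs is opposite.
Group-mean Z-scores (`group_mean_zscores`) standardize each feature's group
means across the group axis with the sample (n−1) SD — with three groups the
choice of SD convention changes the magnitudes, so it is fixed and stated.

# Enrichment

Hypergeometric upper tails. Standard mode reports P(X ≥ k) for overlap k,
term size K, hit count n, universe N. The conservative EASE-style variant
(P(X ≥ k−1), floored at zero overlap) is the documented "modified one-tailed
Fisher" used by DAVID; both modes are always computable so reports can show
them side by side. A term is flagged only when p < 0.05 and k ≥ 2. The
universe defaults to all features passing QC on the platform; terms are
intersected with it.

# Network inference

One elastic-net regression per omic feature on all other features plus
covariates and the one-hot phenotype indicators (clinical variables are
predictors only, never responses). The penalty mixes L1 and L2 with weights
λ₁ + λ₂ = 1, which maps onto glmnet's mixing parameter α = λ₁; the overall
strength is chosen by 10-fold cross-validation minimizing RMSE, with the
mixing searched over {0.1, 0.5, 0.9}. A coarse 3-point mixing grid is a
deliberate numerical choice: neighborhood *selection* is insensitive to α at
finer granularity while the penalty-strength CV does the real work, and the
coarse grid keeps whole-matrix inference (hundreds of regressions per
network, one network per CV fold in the classifier) tractable on one core.
For the same reason the regularization path uses 20 points down to 10% of
λ_max with a slightly relaxed coordinate-descent threshold (1e-5).
Standardization happens inside each CV training split (glmnet refits per
fold), so hyperparameter selection never sees held-out rows.

The per-response neighborhoods merge into one undirected, unweighted graph.
The default is the permissive union rule (edge if either regression selected
the pair); the intersection rule is available and is strictly tighter. Union
is permissive by construction: at moderate n the RMSE-minimizing penalty
admits a few small spurious coefficients, so block-structure purity improves
with sample size (the test suite exercises this at n = 240, where planted
3-block data yields >90% within-block edges).

# Diffusion and prioritization

RWR iterates p⁽ᵗ⁺¹⁾ = (1−r) A′ p⁽ᵗ⁾ + r p⁰ with A′ the column-normalized
binary adjacency (the undirected graph walked as a doubly-directed one),
restart rate r = 0.5, and p⁰ uniform over the phenotype seed nodes.
Iteration stops when the L1 difference between successive vectors drops
below 1e-4 (1e-10 in oracle comparisons). Numerical conventions:

- Zero-degree (dangling) columns would leak probability mass; their mass is
  redirected to the restart distribution, keeping Σp = 1 exactly.
- Seeds stay in the ranking output but phenotype and covariate nodes are
  excluded from top-N feature cuts; ties break lexicographically by node ID
  so rankings are reproducible.
- The iterative solver is validated against the direct linear solve
  p = r(I − (1−r)A′)⁻¹p⁰ on random connected graphs.

# Classification

Stratified 5-fold cross-validation: with 40 samples per group every test
fold is exactly 8 per group. Within each fold, *everything* — network
inference, RWR ranking, random-forest training — runs on the training split
only; phenotype nodes are built from training labels. The top-N features
(default grid 10, 20, 30, 40, 50, 75, 100, 150, 200, all) feed a
500-tree random forest (√p features per split, fixed per-fold seed);
held-out samples are only scored. Baselines (no selection, per-feature
ANOVA F, binned mutual information) run on identical folds for paired
comparison. The summary reports the metric panel (rank-based AUC with tie
credit, accuracy, sensitivity, specificity, PPV, NPV, F1, MCC; PPV/NPV
folds with zero denominators are omitted from averaging) at the N with the
highest mean test AUC — the optimal-subnetwork-size reporting convention
common in this literature. That convention
is optimistic about N itself, so `summary_by_n` retains the whole grid and
an honest nested choice of N (pick on training folds only) can be made from
the same object. For RA vs control the two RA subgroups pool into a 2:1
positive class with no re-balancing.

# The synthetic cohort generator

`generate_cohort` draws, per sample, a latent log-abundance
z = baseline + factor term + planted group shift + covariate term + noise,
then exports proteins as exp(z) (RFU-like) and metabolites after per-feature
censoring of the lowest values followed by median scaling. Defaults and what
they emulate:

- 40 samples per group, three balanced groups — the cohort design.
- 250 proteins + 50 metabolites — a deliberately desk-scale emulation
  keeping the two-block dimensionality asymmetry; per-feature elastic-net
  inference over the full platform (thousands of features) is a
  cluster-scale computation and reproducing cohort-specific hit lists is
  out of scope by design.
- 5 latent factors with loading SD 0.2 against noise SD 0.5 — about 44%
  shared variance, a realistic plasma-omics communality, giving the
  correlated backdrop the network stage needs.
- Planted shifts are calibrated as δ = d · sd so the *population* Cohen's d
  on the log scale equals the target; the calibration uses the
  covariate-free within-group SD, and a Monte-Carlo check at n = 2000/group
  confirms empirical d within [0.9, 1.1] of a 1.0 target.
- Metabolite missingness censors exactly the lowest ⌊frac·n⌋ values per
  feature (missing-not-at-random), the mechanism minimum imputation
  presumes; default fraction 0.10, below the 20% removal threshold.
- ESR/CRP/DAS28-CRP are monotone transforms (exp, scaled logistic) of a
  linear combination of coupled feature latents plus noise, for RA samples
  only (controls carry NA, as in real cohort tables). Monotone transforms
  leave Spearman-based contracts exact while giving realistic scales.
- By default every covariate — including medication flags — is drawn from
  the same distribution in all three groups, so the cohort is exchangeable
  across groups apart from planted shifts. Group-conditional structure is
  opt-in via `confounding`: per-group mean offsets for age/BMI, and
  `meds_zero_groups = "CONTROL"` for the realistic untreated-control design.
  The opt-in matters: an untreated control arm makes medication flags
  partially collinear with the phenotype indicator and measurably inflates
  the adjusted model's standard errors, which is exactly the phenomenon the
  confounding switch exists to demonstrate.

What the generator does *not* emulate: platform artifacts (plate effects,
inter-day drift — assumed handled upstream), heavy-tailed or skewed noise
beyond lognormality, nonlinear feature interactions, and real biological
pathway structure (annotations in tests are synthetic labels). Passing tests
therefore demonstrate that the machinery is correct and powered under the
stated statistical structure, not that any particular biological finding
replicates.

# Cohort tables

`cohort_table` pairs Fisher's exact test (2×2 and Freeman–Halton r×c via
full enumeration; Monte-Carlo beyond a total of 10,000) with Kruskal–Wallis
for continuous variables. Two-sided 2×2 p-values use the standard exact
convention (sum of point probabilities no larger than the observed table's);
quartiles use linear interpolation (type 7). Unknown smoking history is
reported as its own row and excluded from the test; medication flags and
disease-activity markers are compared between the two RA subgroups only.

# Problem sizes in the test suite

The acceptance-style tests run at the sizes the package is designed around:
null and power simulations at 40/group with 300 features over 10 generator
seeds; prioritization recovery at p = 300 over 10 seeds; end-to-end
classification at 100 features over 5 seeds plus a 2-seed label-permutation
control. These are the package's own validation sizes, chosen to exercise
the full pipeline depth (per-fold network inference included) at desk scale.

# Known limitations

- The elastic-net stage is O(p²) in features per network; the full
  aptamer-platform scale needs either feature prescreening or parallel
  hardware, neither of which the package prescribes.
- The best-N reporting convention is test-set-optimistic (see above).
- Freeman–Halton enumeration is exact but bounded; very large tables fall
  back to Monte-Carlo estimation.
- The EASE interpretation of "modified" Fisher is the documented DAVID
  variant; if an upstream tool means something else by "modified", compare
  both emitted columns.
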