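# envgblup

Kernel-based genomic prediction for multi-environment plant breeding
trials, built around the question a breeder actually faces: *how well can I
predict untested genotypes in an environment where nothing was ever
phenotyped, and which environments should train that prediction?*

The package provides:

* **Marker pipeline** — missingness/MAF filtering (markers with more than
  50% missing calls or minor allele frequency below 0.03 removed), mean
  imputation, column standardization, and the genomic relationship matrix
  **G** = XX′/p.
* **Weather pipeline** — daily covariate tables (min/max temperature,
  precipitation), single-day gap imputation, the environmental kinship
  **Ω** = WW′/q from the standardized environment × covariate grid, PCA
  diagnostics, cross-environment phenotypic correlations, and
  per-environment heritability H² = σ²_L / (σ²_L + σ²_resid).
* **Multi-kernel mixed models** — the standard model ladder for records
  y_ij (genotype i, environment j):

  | model | linear predictor | interaction covariance |
  |-------|------------------|------------------------|
  | M0 | μ + E_j + L_i + e | — (IID lines, no markers) |
  | M1 | μ + E_j + g_i + e | — with g ~ N(0, G σ²_g) |
  | M2 | μ + E_j + g_i + gE_ij + e | (Z_E Z_E′ # Z_g G Z_g′) σ²_gE |
  | M3 | μ + E_j + g_i + gw_ij + e | (Z_E Ω Z_E′ # Z_g G Z_g′) σ²_gΩ |

  (# is the Hadamard product.) Fitting is by an eigenbasis Gibbs sampler
  with scaled-inverse-χ² variance priors, plus an exact fixed-variance BLUP
  mode used for oracle checks and fast cross-validation sweeps. M2's
  interaction is block-diagonal across environments and transfers nothing
  to an unseen one; M3's Ω-structured kernel lets interaction signal flow
  into an environment that resembles a training environment's weather.
* **CV00 engine** — for a target environment, disjoint test/training
  genotype sets (defaults 200/300 of a 500-genotype sample), evaluation of
  every non-empty training-environment subset (2^m − 1 of them; 255 for
  eight candidates), untruncated Pearson accuracies, leakage auditing, and
  best-subset / relative-improvement summaries.
* **NAM-style trial simulator** — RIL families sharing a common parent,
  Markov recombination along a synthetic map, seasonal weather with a
  configurable covariate-divergent environment, and phenotypes drawn from
  the same reaction-norm model, so the whole pipeline is testable without
  external data.

## Worked example

A scaled-down study: 120 RILs in 4 families, 6 environments, one of them a
weather outlier, reaction-norm interaction variance equal to the genomic
variance on a kg/ha scale.

```r
library(envgblup)

cfg <- sim_config(n_families = 4, family_size = 30, n_markers = 300,
                  n_environments = 6, n_days = 30,
                  variance_components = c(sigma2_E = 250000, sigma2_g = 90000,
                                          sigma2_gE = 0, sigma2_gW = 90000,
                                          sigma2_resid = 90000),
                  mu = 2500, n_divergent_envs = 1, seed = 41)
study <- simulate_study(cfg)

report <- env_similarity_report(study$pheno, study$ec)
print(report)
#> Environment similarity report
#>   most extreme (lowest mean r):  MO_2011   (0.170)
#>   least extreme (highest mean r): IA_2011   (0.416)
#>   EC PCA: PC1 76.0%, PC2 9.2% of variance
```

The environment the generator made a weather outlier (`MO_2011`) is exactly
the one whose yields correlate least with the rest — the phenotypic and
covariate views of "extreme" agree. Heritability in the most typical
environment sits at the expected level:

```r
per_env_heritability(study$pheno, report$least_extreme, G = study$G,
                     n_iter = 2000, burn_in = 400, thin = 4, seed = 1)
#>   environment sigma2_L sigma2_resid   H2
#> 1     IA_2011   117299       112794 0.51
```

Now the CV00 question: predict 40 untested genotypes in the extreme
environment, training on 80 other genotypes in every subset of the five
remaining environments (31 subsets × 3 models):

```r
design <- make_cv00_design(study$pheno, target_env = report$most_extreme,
                           n_test = 40, n_train = 80, seed = 7)
res <- run_cv00(study$pheno, study$G, study$Omega, design,
                models = c("M1", "M2", "M3"), mode = "blup", seed = 7)
summarize_cv00(res)$summary
#>  model_id best_accuracy     best_subset best_size baseline_accuracy rel_improvement_pct
#>        M1         0.326 IA_2011;KS_2011         2             0.277                17.5
#>        M2         0.324 IA_2011;KS_2011         2             0.280                15.6
#>        M3         0.319 IL_2011;KS_2011         2             0.127               150.4
```

Two environments already beat training on all five — adding dissimilar
environments dilutes rather than helps, and the covariate-informed model
(M3) is hurt most by the full training set because the target's weather
resembles almost none of it. Accuracies are Pearson correlations between
observed target-environment yields of the test genotypes and their
predicted GEBVs; `rel_improvement_pct` compares the best subset against the
all-environments baseline.

See the vignette
(`vignettes/multi-environment-genomic-prediction.Rmd`) for the model
details, prior choices, and the generator's assumptions.

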