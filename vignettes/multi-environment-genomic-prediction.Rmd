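---
title: "Multi-environment genomic prediction with environmental covariate kernels"
author: "envgblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-environment genomic prediction with environmental covariate kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envgblup)
```

## The problem

Plant breeding programs evaluate candidate genotypes in multi-environment
trials, but a new variety will ultimately be grown in places and years where
it was never tested. Genomic prediction addresses the *untested genotype*
problem by borrowing information through a marker-based relationship matrix;
the harder *untested environment* problem additionally requires a way to say
how similar an unobserved environment is to the observed ones. This package
implements the kernel-based model family that attacks both at once: genomic
main effects, genotype-by-environment (G×E) interaction kernels, and
reaction-norm kernels built from daily weather covariates, evaluated under
the CV00 scheme in which neither the test genotypes nor the target
environment contribute any training data.

## Models

All four models act on long-format records $y_{ij}$ (genotype $i$,
environment $j$, grain yield in kg ha$^{-1}$):

* **M0** (baseline): $y_{ij} = \mu + E_j + L_i + e_{ij}$ with an IID line
  effect — no marker information.
* **M1** (main genomic effect): $y_{ij} = \mu + E_j + g_i + e_{ij}$ with
  $\mathbf{g} \sim N(0, \mathbf{G}\sigma^2_g)$ and
  $\mathbf{G} = \mathbf{XX}'/p$, where $\mathbf{X}$ is the column-centered
  and column-scaled marker matrix over $p$ markers.
* **M2** (naive interaction): adds $gE_{ij}$ with record-level covariance
  $(\mathbf{Z}_E\mathbf{Z}_E' \,\#\, \mathbf{Z}_g\mathbf{G}\mathbf{Z}_g')
  \sigma^2_{gE}$, where $\#$ is the Hadamard product and
  $\mathbf{Z}_E, \mathbf{Z}_g$ are the incidence matrices. Because the
  environmental factor is the identity on environment labels, this kernel is
  block-diagonal across environments: interaction deviations are independent
  between environments, so the term transfers nothing to an unobserved one.
* **M3** (covariate-informed reaction norm): replaces the identity
  environment factor by the environmental kinship
  $\mathbf{\Omega} = \mathbf{WW}'/q$, where $\mathbf{W}$ is the
  column-standardized environment × covariate grid ($q$ daily weather
  covariates). The interaction covariance
  $(\mathbf{Z}_E\mathbf{\Omega}\mathbf{Z}_E' \,\#\,
  \mathbf{Z}_g\mathbf{G}\mathbf{Z}_g')\sigma^2_{g\Omega}$ has non-zero
  cross-environment blocks, so interaction signal can flow into an
  environment that contributed no phenotypes — provided its weather
  resembles a training environment's.

All random effects and residuals are Gaussian; the Schur product theorem
guarantees the Hadamard kernels are positive semidefinite.

### Kernel conventions

Markers are filtered (missing fraction strictly above 0.5 or minor allele
frequency strictly below 0.03 removed, MAF computed on non-missing calls),
mean-imputed per marker, then centered and scaled with the sample standard
deviation ($n-1$). A consequence used as a test invariant is
$\mathrm{tr}(\mathbf{G}) = n - 1$; the analogous standardization of the
covariate grid gives $\mathrm{tr}(\mathbf{\Omega}) = m - 1$ for $m$
environments. Weather columns that are constant across environments carry no
similarity information and are dropped before standardization (with $q$
reduced); gaps of a single day are filled with the mean of the two adjacent
days, a missing first or last day takes its single neighbor, and longer gaps
are refused rather than guessed. Temperatures stay in tenths of degrees
Celsius and precipitation in inches — the units weather archives report —
because standardization makes the kernel invariant to per-column affine
changes of units anyway.

## Estimation

`fit_gibbs()` samples $(\mu, \{u_t\}, \{\sigma^2_t\}, \sigma^2)$ with a flat
prior on $\mu$ and scaled-inverse-$\chi^2$ priors on every variance
(df $= 5$; scale set so each term's prior mode explains an equal share of
half the observed response variance). Each term's kernel is eigendecomposed
once, eigenvalues below $10^{-8}$ truncated, and effects are sampled in the
eigenbasis: with orthonormal eigenvectors the conditional posterior of the
basis coefficients is independent across components, so one sweep costs two
matrix–vector products per term. Records declared with a missing response
are refreshed from their Gaussian predictive distribution each sweep (data
augmentation); this is marginally equivalent to omitting them from the
likelihood and keeps the eigenbasis algebra exact, and their posterior-mean
linear predictors are the GEBVs used for prediction. Chains are
bit-reproducible under a fixed seed. Defaults are 6,000 iterations, 1,000
burn-in, thinning 5; the package's own studies use shorter chains (stated
below) because the monitored posterior means stabilize quickly at these
problem sizes.

Two numerical caveats are worth knowing. First, the inverse-$\chi^2$ prior
density vanishes at zero, so a variance whose true value is exactly zero
retains a small positive posterior floor (at 500 lines × 2 replicates the
exact posterior mean of a null line variance is ≈ 0.16 on a unit-residual
scale — verified against a grid-integration oracle, and the sampler
reproduces it). Estimated heritabilities for truly heritability-free traits
are therefore biased upward by a prior-dependent amount; this flattens out
as record counts grow. Second, posterior means of variance ratios are
computed as ratios of posterior means, so the reported `H2` always equals
`sigma2_L / (sigma2_L + sigma2_resid)` from the same table.

`fit_blup()` is the deterministic companion: with all variances held fixed
the Gaussian posterior is available in closed form
($\hat\mu$ by GLS under $V = \sum_t \sigma^2_t K_t + \sigma^2 I$ on observed
records, effects as conditional means). It is exact, fast enough to solve
hundreds of training subsets, and doubles as the oracle target for the
sampler: the test suite checks it against an independently coded
Henderson mixed-model-equation solver to $10^{-6}$.

## Environment similarity and heritability diagnostics

`env_similarity_report()` combines two views of environment similarity:
the mean Pearson correlation of yield between each environment and the
remaining ones (computed on the complete genotype × environment grid), and a
PCA of the same standardized covariate grid that defines
$\mathbf{\Omega}$ — by construction the full PC score cross-product divided
by $q$ reconstructs $\mathbf{\Omega}$ exactly. The most/least extreme
designation uses the phenotypic criterion (argmin/argmax of the mean
correlation, ties broken by label order with a warning); the covariate view
serves as a concordance check, and `sample_until_concordant()` re-draws
genotype subsets until the two rankings agree, mirroring how a study would
align its phenotypic and weather-based pictures before choosing test
environments.

Within-environment heritability is estimated from the one-environment model
$y = \mu + L + e$. With replicated plots the line covariance is the record
expansion of the identity; with one record per line that model is
unidentifiable, so a genomic kinship must be supplied and the line
covariance becomes $\mathbf{Z}_g\mathbf{G}\mathbf{Z}_g'$. Both modes run
through the same sampler restricted to one environment.

## The CV00 engine

For a chosen target environment, `make_cv00_design()` draws disjoint test
(default 200) and training (default 300) genotype sets from the sampled
panel (default 500). `run_cv00()` then scores every model on every non-empty
subset of the candidate training environments ($2^m - 1$ subsets, ordered by
size then lexicographically), predicting the test genotypes in the target
environment and reporting the untruncated Pearson correlation with their
observed yields. An automated leakage check re-derives each training record
set and aborts if a target-environment record or a test genotype ever enters
training.

Design choices where the scheme was genuinely open:

* **Variance policy.** The default sweep estimates variance components once
  per model on the full training grid (all candidate environments) and then
  solves each subset with the exact fixed-variance path; `mode = "gibbs"`
  re-estimates per subset instead. Re-estimation per subset multiplies cost
  by the subset count without changing the logic of the comparison, so the
  single-estimation mode is the default.
* **Split reuse.** Within a replicate, the same 200/300 split is reused
  across target environments by default (`resample_per_target` flips this),
  so that target contrasts are not confounded with sampling noise.
* **Seed discipline.** Every consumer of randomness derives a child seed
  from the master seed and a string key via the documented rule in
  `derive_seed()`; whole sweeps replay bit-identically, and the
  fixed-variance sweep is deterministic end to end.
* **Undefined accuracies.** A constant prediction vector yields `NA` with a
  warning instead of halting the sweep; `summarize_cv00()` likewise flags
  the relative improvement undefined when the all-environment baseline is
  not positive.

## The synthetic trial generator

The generator exists so every stage above is testable end to end without
external downloads. It emulates a nested-association-mapping soybean panel:
biparental recombinant inbred line families sharing one common parent
(default 40 families × 140 RILs = 5,600 genotypes, dosages coded 0/2 because
RILs are effectively fully inbred), 4,450 biallelic markers on a single
synthetic linear map with a first-order Markov recombination process
(default switch probability 0.05 between adjacent markers), 9 LOC_YEAR
environments with three daily weather series (min/max temperature in tenths
of °C, precipitation in inches) over a 125-day season, and phenotypes drawn
from the same reaction-norm model the fitters assume, with the realized
genomic values rescaled so their sample variance hits $\sigma^2_g$ exactly
(this makes heritability targets sharp rather than approximate).
Interaction deviations are sampled exactly through eigendecompositions of
$\mathbf{G}$ and $\mathbf{\Omega}$, which is feasible at the desk scales the
package targets.

Default variance components are on a grain-yield scale: environment s.d.
500 kg ha$^{-1}$, genomic and residual s.d. 300 kg ha$^{-1}$ each (within-
environment heritability ≈ 0.5, the level reported for this crop), and both
interaction variances at one quarter of the genomic variance — the
generative magnitudes of the interaction terms are a convention, since no
field estimate pins them down. One environment (by default) receives a
+3 within-environment-s.d. mean shift on all three weather series, making it
a covariate-space outlier; both temperature series share the shift so the
max–min ordering is preserved. This is the switch that produces the
study contrast between a weather-divergent target (hard to predict,
especially for the reaction-norm model, because $\mathbf{\Omega}$ couples it
weakly to every training environment) and a typical target.

What the generator does *not* emulate: real genetic maps or linkage
disequilibrium, weather physics or station noise, spatial field trends,
multi-trait genetics. Passing tests therefore demonstrate that the
estimators and the cross-validation engine are correct and well calibrated
*under the model's own assumptions* — they do not certify performance on
real trial data, where model misspecification dominates.

## Problem sizes used by the test suite

The shipped tests exercise scaled-down studies chosen to keep the full suite
comfortably reproducible on a single CPU: heritability recovery at 500 lines
× 2 replicates over 10 seeds per level (chains of 1,200–2,000 iterations);
variance-component recovery at 1,800 records (300 genotypes × 6
environments, 4,000 iterations); null-interaction equivalence on a
5-environment study (15 subsets × 3 models); the leakage audit and the
divergent-vs-typical contrast on 6-environment studies of 120 genotypes
(31 subsets per target). The full-scale 9-environment, 255-subset sweep uses
the same code paths — only the loop sizes differ.

## Known limitations

* The record-level kernels are dense $n \times n$ matrices; the
  eigendecomposition puts a practical ceiling of a few thousand records per
  fit. Factored (genotype × environment) updates would extend this but are
  not implemented.
* Variance components near zero inherit the prior floor discussed above.
* `mean_phenotypic_correlation()` requires the complete grid; unbalanced
  trials must be completed or subset upstream.
* REML estimation, non-Gaussian responses, multi-trait models, and
  alternative kinships (dominance, epistasis, Gaussian kernels on ECs) are
  out of scope.
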