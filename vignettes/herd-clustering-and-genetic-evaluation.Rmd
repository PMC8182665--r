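---
title: "Herd clustering on mixed survey data and herd-cluster contemporary groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herd clustering on mixed survey data and herd-cluster contemporary groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdclust)
```

## The problem

Local cattle breeds are typically kept in many small herds. Genetic
evaluation models group records into contemporary groups (CGs) — usually
herd × test date — so that animals are compared against herdmates that
experienced the same environment. With herds of a handful of cows, most
herd-test-day groups hold one or two records, which wastes information and
depresses the reliability of estimated breeding values (EBVs). `herdclust`
implements a two-stage remedy:

1. **Cluster the herds** on a broad mixed-type survey of farm conditions,
   husbandry, feeding, management, health and social descriptors, so that
   herds in one cluster plausibly share an environment.
2. **Replace the herd by the herd cluster** in the CG definition of a
   pedigree-based repeatability test-day animal model, and quantify what
   that does to variance components, heritability and EBV reliabilities.

## Stage 1: mixed-data dissimilarity and four clustering strategies

### Variable editing

Survey instruments carry variables with little information. Before
clustering, `edit_variables()` removes qualitative variables with fewer
than two observed levels or with a dominant level covering at least 95 % of
herds, and one of each pair of quantitative variables with |Pearson r| >
0.95 (both thresholds configurable, every removal logged with its reason).
The removal log makes the editing auditable rather than implicit.

### Gower dissimilarity

`gower_matrix()` computes
$$d(i,j) = \frac{\sum_k w_k\,\delta_{ijk}\,d_{ijk}}{\sum_k w_k\,\delta_{ijk}},$$
with per-variable contributions: range-normalised absolute differences for
quantitative variables; simple mismatch for nominal and symmetric binary
variables; ordinal levels mapped to ranks and treated as quantitative
(rank normalisation — the same convention as `cluster::daisy`); and
asymmetric binary variables whose joint absences are excluded via
$\delta_{ijk} = 0$. Missing values are handled by pairwise deletion
($\delta_{ijk} = 0$), so no imputation is ever performed. Which binary
variables are asymmetric is declared in the variable specification, never
inferred from data. A herd pair sharing no observed comparable variable is
an error naming the pair, not a silent `NA`.

### The four clustering strategies

* **AHC** — Ward agglomerative clustering. We use the `ward.D2`
  (squared-dissimilarity Lance–Williams) variant, the appropriate form when
  the input is a dissimilarity rather than squared Euclidean distances; the
  variant is recorded in the tree object.
* **PAM** — partitioning around medoids (BUILD seeding + SWAP descent),
  minimising total dissimilarity to the nearest medoid. Deterministic.
* **FZC** — fuzzy clustering of the dissimilarity matrix minimising the
  Kaufman–Rousseeuw objective
  $\sum_v \frac{\sum_{i,j} u_{iv}^r u_{jv}^r d(i,j)}{2\sum_j u_{jv}^r}$
  with membership exponent $r$. The default $r = 1.1$ is a near-crisp
  setting appropriate for allocation decisions; memberships row-sum to 1
  and the crisp partition is each herd's argmax membership with ties to the
  lowest cluster index.
* **CoVAHC** — clustering of variables followed by herd AHC. Variables are
  agglomerated so that each merge loses the least *homogeneity*
  $$H(\mathcal C) = \sum_{\text{quantitative } k} r^2(x_k, f)
    + \sum_{\text{qualitative } k} \eta^2(f \mid x_k),$$
  where $f$ is the cluster's *synthetic variable*: the first principal
  component of the mixed-data expansion (standardized quantitative columns;
  centered level indicators scaled by the inverse square root of the level
  frequency — the PCAmix/FAMD convention). $H$ equals the leading
  eigenvalue of that expansion and is attained by $f$, which is what makes
  the greedy merge well defined. Herds are then Ward-clustered on Euclidean
  distances between synthetic-score profiles. The synthetic variable's sign
  is fixed (nonnegative loading on the first expanded column) purely for
  reproducibility.

The number of variable clusters kept for CoVAHC defaults to the partition
just before the single merge that loses the most homogeneity
(`choose_n_var_clusters()`), overridable by the caller — survey data rarely
dictate a unique choice, and the merge-loss profile is returned so the
choice can be inspected.

### Model selection by average silhouette width

`asw_sweep()` scores every (method, k) cell for k = 2…10 by the average
silhouette width (ASW), with per-herd widths
$s(i) = (b(i) - a(i)) / \max(a(i), b(i))$ and the convention $s(i) = 0$ for
singleton clusters; k = 1 and k = n give all-zero reports with a warning,
since cohesion vs separation is undefined there. Failed cells are recorded
as missing rather than aborting the sweep. The selected configuration is
the ASW argmax with ties to the smaller k (parsimony).

One geometry question is genuinely open: silhouettes for CoVAHC can be
computed in the synthetic-score space its AHC step uses, or on the Gower
matrix shared by the other three methods. For *model selection* the sweep
defaults to the Gower geometry, because ASW values entering one argmax must
be computed on a common dissimilarity to be comparable across methods —
Euclidean distances between synthetic scores live on a different scale
than Gower values in [0, 1]. The synthetic-space silhouette remains
available (`covahc_silhouette = "synthetic"`) as a within-method
diagnostic. Herds with negative silhouettes are reported by
`misclassification_report()` as potential misallocations.

## Stage 2: trait comparison and genetic evaluation

### Trait models (models 1 and 2)

`fit_model1()` fits, per test-day trait,
`y ~ breed + year-season + lactation + herd cluster + Legendre(DIM, 3) +
calving age + (1 | animal)` by REML (lme4). The animal effect here is an
independent random effect without pedigree — the pedigree machinery belongs
to the genetic evaluation stage. The year-season blocks are Dec–Feb,
Mar–May, Jun–Aug and Sep–Nov, with December assigned to the following
winter block. Somatic cell counts enter as
$\mathrm{SCS} = \log_2(\mathrm{SCC}/100{,}000) + 3$.

`fit_model2()` fits the fertility design (breed, insemination month,
lactation, herd cluster, semen type, insemination age; crossed random
animal and service-sire effects). The calving-to-first-insemination
interval is Gaussian; first-insemination success is a logit model fitted by
penalized quasi-likelihood — a working-variate iteration around the same
weighted linear mixed solver. PQL is adequate for the marginal comparisons
made here but is known to shrink variance components for binary data with
small clusters; no Laplace/AGQ refinement is attempted. Service sires with
a single record are retained and shrunken, never dropped. Herd clusters
with all-0 or all-1 outcomes are flagged as complete separation.

`lsmeans_hc()` produces least-squares means over an equal-weight reference
grid of all fixed factors with covariates at their means (emmeans), plus
unadjusted pairwise Student tests at α = 0.05 displayed as letter groups —
matching the common presentation where levels sharing a letter do not
differ. A Tukey adjustment is available but off by default. The letter
display is computed by an insert-and-absorb pass over the estimate-ordered
pairwise p matrix, so it is transitively consistent with the tests by
construction.

Defaults that the data do not dictate: the DIM window is 5–365 days
(mapped to the Legendre interval [-1, 1]); calving age enters linearly and
uncentered. Both are arguments, and both are recorded in the model frame.

### Contemporary groups

`build_cg()` crosses herd or herd cluster with test date or calendar test
month (HTD, HCTD, HTM, HCTM). Groups below the minimum size (default 3
records, reflecting the rule of at least three records per CG) either drop
their records or merge into the nearest-dated group of the same herd unit;
the policy and every action are logged. Coarsening guarantees
#HCTD ≤ #HTD and #HCTM ≤ #HTM, and when every cluster is a singleton herd
the cluster schemes coincide exactly with the herd schemes — both
identities are tested.

### The animal model

`animal_model()` solves Henderson's mixed-model equations for the
repeatability test-day model
`y = fixed (intercept, CG, breed, year-season, lactation, Legendre DIM,
calving age) + a + pe + e` with $\mathrm{Var}(a) = A\sigma^2_a$ from the
pedigree, a permanent-environment effect per cow and residual. $A^{-1}$ is
built directly by Henderson's rules with inbreeding coefficients from the
Meuwissen–Luo recursion; the dense tabular construction of $A$ exists
separately (`make_A()`) and serves as an independent cross-check
($A^{-1}A = I$ in the tests). Aliased fixed-effect columns are detected by
pivoted Cholesky of $X'X$ and dropped with a report, never silently.

Prediction error variances come from the animal block of the inverse
coefficient matrix, obtained from the sparse Cholesky factor. This direct
approach is exact and adequate at desk scale (up to roughly $10^4$
equations); it is the package's stated scalability boundary. Reliability is
$r^2 = 1 - \mathrm{PEV}/\sigma^2_a$ by default; an option divides by
$(1 + F_i)\sigma^2_a$ instead, since conventions differ and the choice
matters only for inbred animals.

### EM-REML

`em_reml()` estimates $(\sigma^2_a, \sigma^2_{pe}, \sigma^2_e)$ by
expectation-maximisation REML with the classical updates (quadratic forms
plus traces of inverse blocks against $A^{-1}$ and the identity), so the
restricted likelihood is nondecreasing at every accepted iterate — the
history is returned so this can be verified. Plain EM approaches the
optimum in very small steps on repeatability data (the additive and
permanent-environment components are separated only through between-family
information); the solver therefore interleaves squared-extrapolation
(SQUAREM-type) cycles: two EM steps propose an extrapolated candidate that
is accepted only if it keeps all components positive and does not lower
the restricted likelihood, otherwise the plain EM result is kept. The
monotonicity guarantee is preserved and the step count typically drops by
an order of magnitude. Components collapsing toward zero are pinned at a
small floor (10⁻⁶ of the phenotypic variance) with a warning. Standard
errors of the components and of $h^2$ (delta method) come from the
numerically differentiated observed information of the restricted
likelihood.

`compare_cg_models()` runs the four CG schemes side by side, re-estimating
variance components per scheme by default (heritability legitimately
differs across CG definitions, so re-estimation is the meaningful
comparison), and reports mean (SD) reliability for the whole population,
for animals with records, and for sires with at least one recorded
daughter — "whole population" is ambiguous in field reports, so both
summaries are always present.

## The synthetic-data generators

The generators define the study conditions for everything the package
verifies about itself.

* `simulate_survey()` defaults to 30 herds in 4 clusters of sizes
  13/5/1/11 with 23 quantitative and 83 qualitative analysis variables,
  plus 11 planted removable columns (constants, duplicates, dominant
  levels) so the raw instrument has 117 columns — mirroring the shape of a
  real on-farm survey campaign. `separation` scales cluster mean shifts
  (in units of the within-cluster SD) and tilts qualitative level
  probabilities toward a cluster-preferred level with weight
  `separation / (1 + separation)`. The planted-recovery checks use
  separation 9 as their "strong separation" condition, i.e. roughly 90 %
  of qualitative answers on the preferred level — structure a field
  researcher would call unambiguous. One planted cluster is a singleton
  herd; silhouette-based selection of the planted k is only reliable once
  separation is strong, because a singleton contributes s = 0 and merging
  it is cheap at moderate separation.
* `simulate_pedigree()` draws founder breeding values from
  $N(0, \sigma^2_a)$ and offspring as parent average plus Mendelian
  sampling. The parameter-recovery checks use 50 paternal half-sib
  families of 20 recorded daughters each with dams unknown — a realistic
  progeny-test structure in which $\sigma^2_a$ and $\sigma^2_{pe}$ are
  separable.
* `simulate_test_days()` inverts the test-day model: monthly recording
  dates (the 15th) shared by all herds, a third-order Legendre lactation
  curve, and — critically — a **cluster-shared test-date environment**
  plus a smaller constant herd-level shift. That shared environment is the
  explicit mechanism by which herd-cluster CGs beat single-herd CGs when
  herds are sparse; it is a modelling assumption made visible and
  configurable, not an empirical claim.
* `simulate_fertility()` inverts the fertility design with iid animal and
  service-sire effects, Gaussian CFI and Bernoulli-logit SFI.

What the generators deliberately do not emulate: real response
distributions of farm surveys (multimodality, answer styles), culling and
selection (records missing not at random), heterogeneous residual
variances across lactation stages, and genetic trend. Passing the planted
recovery and parameter recovery checks therefore demonstrates correctness
of the machinery under the stated model, not robustness to those
real-data features.

## Problem sizes and numerical choices

The self-checks run at desk scale chosen to make their Monte-Carlo answers
stable: 50 survey seeds for planted-k selection; 20 seeds × (1000 cows ×
5 records, 50 sires) for EM-REML recovery of $h^2 = 0.30$, repeatability
0.50; 20 seeds × (300 cows in 40 herds, 4 clusters) with cluster-shared
environments for the HCTD-vs-HTD reliability direction — the 40 sparse
herds produce a median herd-test-day occupancy of about 3–4 records, the
regime the method targets. EM-REML convergence is relative component
change below 1e-4 per EM step (tolerance and iteration cap are arguments).
Ties are broken deterministically everywhere: lowest index in merges,
argmax memberships and ASW selection (smaller k first). All generators
take explicit seeds, and the pipeline is a pure function of (inputs,
config, seed).

## Known limitations

* PEV by direct inverse-block extraction bounds the feasible system size;
  national-scale evaluations need iterative solvers and PEV approximations
  that are out of scope here.
* PQL for binary fertility traits underestimates variance components when
  clusters are small; comparisons of herd-cluster least-squares means are
  less affected than the variance components themselves.
* The fuzzy solver reports the Kaufman–Rousseeuw objective; silhouettes
  for it are computed on the crisp argmax partition, not on memberships.
* Editing thresholds, the DIM window and the minimum CG size are
  conventions with sensible defaults, not estimated quantities; all are
  arguments and all decisions are logged.
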