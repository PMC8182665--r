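# herdclust

Herd clustering on mixed social–ecological survey data, and herd-cluster
contemporary groups in dairy genetic evaluation.

## The problem

Local cattle breeds are mostly kept in small family herds. Genetic
evaluations compare each cow against her contemporary group (CG) —
classically the records made in the same herd on the same test day. With a
handful of cows per herd, most herd-test-day groups hold one or two
records, so little environmental variance is absorbed and the reliability
of estimated breeding values (EBVs) suffers. `herdclust` is for
quantitative geneticists and breeding organisations working with such
populations. It implements a two-stage analysis:

1. **Cluster the herds.** Farms are described by a mixed-type survey
   (quantitative, nominal, ordinal, symmetric and asymmetric binary
   variables). After variable editing, herd dissimilarities follow Gower:

   d(i,j) = Σₖ wₖ δᵢⱼₖ dᵢⱼₖ / Σₖ wₖ δᵢⱼₖ,

   with range-normalised differences for quantitative variables, mismatch
   for nominal/symmetric binary, rank-normalised ordinal scores, and
   asymmetric binary variables whose joint absences are excluded
   (δᵢⱼₖ = 0). Four clustering strategies compete: Ward agglomerative
   clustering (ward.D2), partitioning around medoids, fuzzy clustering of
   the dissimilarity matrix (Kaufman–Rousseeuw objective, membership
   exponent r = 1.1 by default), and clustering of variables followed by
   Ward clustering of the herds on the resulting synthetic variables
   (CoVAHC). The winning configuration maximises the average silhouette
   width, ASW = mean over herds of (b−a)/max(a,b), over methods and
   k = 2…10.

2. **Evaluate genetically with herd-cluster CGs.** A pedigree-based
   repeatability test-day animal model (Henderson mixed-model equations;
   A⁻¹ by Henderson's rules with Meuwissen–Luo inbreeding; EM-REML
   variance components; PEV-based reliabilities r² = 1 − PEV/σ²ₐ) is run
   under four CG schemes — herd × test day (HTD), herd cluster × test day
   (HCTD), and their test-month analogues (HTM, HCTM) — and the schemes
   are compared on CG occupancy, heritability and mean EBV reliability.

Seed-deterministic generators (`simulate_survey()`, `simulate_pedigree()`,
`simulate_test_days()`, `simulate_fertility()`) emulate all inputs with
planted cluster structure and known variance components, so every claim
the package makes about itself is checked against planted truth.

## Worked example

Simulate a survey of 30 herds in 4 planted clusters (one of them a single
large farm), 300 recorded cows in 40 sparse herds with a cluster-shared
test-date environment, then run the full pipeline:

```r
library(herdclust)

sim  <- simulate_survey(separation = 9, seed = 1)
ps   <- simulate_pedigree(n_sires = 15, n_dams = 0, n_cows = 300,
                          sigma2_a = 3, seed = 1)
part <- herd_partition(sim$labels)
td   <- simulate_test_days(ps, part, records_per_cow = 5,
                           sigma2_pe = 2, sigma2_e = 5,
                           cluster_env_sd = 1.5, herd_env_sd = 0.3, seed = 1)

rep <- run_full_pipeline(sim$survey, td$records, ps$pedigree,
                         k_range = 2:10, vc = variance_components(3, 2, 5),
                         schemes = c("HTD", "HCTD"), seed = 1)
print(rep)
```

```
== Herd clustering / genetic evaluation pipeline ==
23 variables removed by editing
ASW sweep (rows: methods, cols: k):
           2     3     4     5     6     7     8      9     10
ahc    0.533 0.724 0.743 0.533 0.246 0.206 0.201  0.101  0.105
pam    0.497 0.724 0.743 0.503 0.494 0.485 0.240  0.242  0.213
fzc    0.529 0.724 0.406 0.452 0.000 0.000 0.000  0.014  0.000
covahc 0.533 0.724 0.743 0.623 0.388 0.049 0.007 -0.056 -0.055
Best: ahc with k = 4 (ASW = 0.743)

LSM for Mkg by herd cluster:
Least-squares means (levels sharing a letter do not differ):
 level estimate     se  df letters
     1    24.18 0.2126 Inf       b
     2    23.31 0.3607 Inf       a
     3    23.49 0.7071 Inf      ab
     4    23.66 0.2414 Inf      ab

Contemporary-group scheme comparison:
 scheme n_cg mean_cg_size n_records  h2 h2_se rel_all rel_all_sd rel_records
    HTD  275        4.585      1261 0.3    NA  0.4471    0.08169      0.4508
   HCTD   59       25.254      1490 0.3    NA  0.5235    0.03853      0.5159
 rel_sires rel_sires_sd
    0.6294      0.05293
    0.6755      0.04634
HTD_vs_HCTD: CGs -216, h2 +0.000, reliability (all) +0.076, (sires) +0.046
```

Reading the output: the ASW sweep recovers the planted k = 4 (several
methods tie at ASW 0.743 — they found the same partition; ties resolve to
the first method listed). The least-squares means compare milk yield
across the selected herd clusters with letter groups from unadjusted
pairwise t tests at α = 0.05. The CG comparison shows the mechanism of
interest: pooling herds into cluster test-day groups cuts 275 CGs to 59,
raises mean occupancy from 4.6 to 25.3 records, keeps 229 records that the
minimum-3-records rule would otherwise drop, and lifts mean EBV
reliability by +0.076 overall and +0.046 for sires with daughter records —
the direction the herd-cluster strategy is designed to produce when herds
are sparse and the environment is shared at cluster level.

Variance components can also be estimated rather than supplied: pass
`vc = NULL` (the default) and each scheme re-estimates σ²ₐ, σ²ₚₑ, σ²ₑ by
EM-REML, reporting heritability with a standard error from the observed
information.

## Documentation

The methods vignette
(`vignettes/herd-clustering-and-genetic-evaluation.Rmd`) describes the
models, conventions, numerical choices and the limits of what the
synthetic-data checks demonstrate.
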