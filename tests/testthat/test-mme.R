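test_that("founders with one record each shrink EBVs by the closed form", {
  set.seed(1)
  n <- 40
  ids <- sprintf("a%02d", seq_len(n))
  ped <- pedigree_table(ids, rep(NA, n), rep(NA, n))
  vc <- variance_components(3, 2, 5)
  y <- rnorm(n, 10, sqrt(10))
  rec <- data.frame(animal = ids, herd = "h1",
                    test_date = as.Date("2020-01-15"), y = y)
  fit <- animal_model(rec, ped, cg = NULL, vc = vc, trait = "y")
  expect_equal(unname(fit$ebv),
               vc$h2 * (y - mean(y)), tolerance = 1e-10)
  expect_true(all(fit$reliability >= 0 & fit$reliability < 1))
  # EBVs sum to ~0 under the full-rank fixed design
  expect_lt(abs(sum(fit$ebv)), 1e-8)
})

test_that("phenotypes equal to fixed effects give zero EBVs", {
  ps <- simulate_pedigree(n_sires = 5, n_cows = 60, sigma2_a = 0, seed = 2)
  part <- toy_partition(6, 2)
  td <- simulate_test_days(ps, part, records_per_cow = 3,
                           sigma2_pe = 0, sigma2_e = 0,
                           cluster_env_sd = 0, herd_env_sd = 0, seed = 2)
  cg <- build_cg(td$records, part, "HCTD", min_size = 1)
  fit <- animal_model(td$records, ps$pedigree, cg,
                      vc = variance_components(1, 1, 1), trait = "Mkg")
  expect_lt(max(abs(fit$ebv)), 1e-6)
})

test_that("zero residual repeated records differ only through the DIM curve", {
  ps <- simulate_pedigree(n_sires = 3, n_cows = 10, sigma2_a = 1, seed = 3)
  part <- toy_partition(4, 2)
  td <- simulate_test_days(ps, part, records_per_cow = 4,
                           sigma2_pe = 0, sigma2_e = 0,
                           cluster_env_sd = 0, herd_env_sd = 0, seed = 3)
  P <- legendre_dim(td$records$dim)
  curve <- drop(P %*% c(0, -1.5, 0.6, -0.2))
  adj <- td$records$Mkg - curve
  spread <- tapply(adj, td$records$animal, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-10)
  # exact record count: cows x records per cow
  expect_equal(nrow(td$records), 10 * 4)
})

test_that("MME solutions are invariant to record order and CG relabeling", {
  ps <- simulate_pedigree(n_sires = 6, n_cows = 60, seed = 4)
  part <- toy_partition(8, 2)
  td <- simulate_test_days(ps, part, seed = 4)
  vc <- variance_components(2, 1, 4)
  cg <- build_cg(td$records, part, "HCTD", min_size = 1)
  fit <- animal_model(td$records, ps$pedigree, cg, vc = vc, trait = "Mkg")
  perm <- sample(nrow(td$records))
  rec2 <- td$records[perm, ]
  cg2 <- build_cg(rec2, part, "HCTD", min_size = 1)
  fit2 <- animal_model(rec2, ps$pedigree, cg2, vc = vc, trait = "Mkg")
  expect_equal(fit$ebv, fit2$ebv, tolerance = 1e-8)
  expect_equal(fit$pev, fit2$pev, tolerance = 1e-8)
})

test_that("EBV accuracy tracks its own reported reliability in simulation", {
  ps <- simulate_pedigree(n_sires = 10, n_dams = 100, n_cows = 200,
                          sigma2_a = 3, seed = 5)
  part <- toy_partition(10, 2)
  td <- simulate_test_days(ps, part, records_per_cow = 5,
                           sigma2_pe = 2, sigma2_e = 5,
                           cluster_env_sd = 0, herd_env_sd = 0, seed = 5)
  vc <- variance_components(3, 2, 5)
  fit <- animal_model(td$records, ps$pedigree, cg = NULL, vc = vc,
                      trait = "Mkg")
  cows <- ps$cows
  r <- cor(fit$ebv[cows], ps$bv[cows])
  expected <- sqrt(mean(fit$reliability[cows]))
  # correlation with true BV close to sqrt(mean reliability)
  expect_lt(abs(r - expected), 0.12)
})

test_that("aliased fixed-effect columns are reported, not silently absorbed", {
  set.seed(6)
  ids <- sprintf("a%02d", 1:30)
  ped <- pedigree_table(ids, rep(NA, 30), rep(NA, 30))
  rec <- data.frame(animal = ids,
                    herd = rep(c("h1", "h2"), each = 15),
                    test_date = as.Date("2020-06-15"),
                    breed = rep(c("DSN", "HF"), each = 15),  # aliased with CG
                    y = rnorm(30, 10))
  part <- herd_partition(setNames(1:2, c("h1", "h2")))
  cg <- build_cg(rec, part, "HCTD", min_size = 1)
  fit <- animal_model(rec, ped, cg, vc = variance_components(1, 1, 1),
                      trait = "y")
  expect_gt(length(fit$aliased), 0)
})
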