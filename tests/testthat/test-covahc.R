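# fixtures for the clustering-of-variables machinery

three_var_mixed <- function(seed = 6, n = 12) {
  set.seed(seed)
  vals <- data.frame(q1 = rnorm(n),
                     q2 = rnorm(n),
                     f1 = sample(c("a", "b", "c"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  specs <- data.frame(name = c("q1", "q2", "f1"),
                      vtype = c("quantitative", "quantitative", "nominal"),
                      stringsAsFactors = FALSE)
  typed_survey(vals, specs)
}

test_that("synthetic variable of one quantitative column is that column", {
  s <- three_var_mixed()
  f <- synthetic_variable(s, "q1")
  z <- (s$values$q1 - mean(s$values$q1))
  expect_equal(abs(cor(as.numeric(f), z)), 1, tolerance = 1e-12)
  expect_equal(mean(f), 0, tolerance = 1e-12)
  expect_equal(homogeneity(s, "q1"), 1, tolerance = 1e-12)
})

test_that("homogeneity equals direct r2/eta2 computation and leading eigenvalue", {
  s <- three_var_mixed()
  vars <- c("q1", "q2", "f1")
  f <- synthetic_variable(s, vars)
  # direct oracle: r2 for quantitative, one-way ANOVA eta2 for qualitative
  r2 <- cor(s$values$q1, as.numeric(f))^2 + cor(s$values$q2, as.numeric(f))^2
  aovfit <- stats::aov(as.numeric(f) ~ factor(s$values$f1))
  ss <- summary(aovfit)[[1]]$"Sum Sq"
  eta2 <- ss[1] / sum(ss)
  expect_equal(homogeneity(s, vars), r2 + eta2, tolerance = 1e-10)
  expect_equal(homogeneity(s, vars), attr(f, "eigenvalue"), tolerance = 1e-10)
})

test_that("qualitative variable perfectly separating scores gives eta2 = 1", {
  vals <- data.frame(f1 = rep(c("a", "b"), each = 4),
                     q1 = c(1, 1.1, 0.9, 1, -1, -1.1, -0.9, -1),
                     stringsAsFactors = FALSE)
  specs <- data.frame(name = c("f1", "q1"),
                      vtype = c("nominal", "quantitative"))
  s <- typed_survey(vals, specs)
  f <- rep(c(1, -1), each = 4)    # scores constant within level
  H <- homogeneity(s, "f1", synthetic = f)
  expect_equal(H, 1, tolerance = 1e-12)
})

test_that("perfectly correlated quantitative pair has homogeneity 2", {
  set.seed(10)
  x <- rnorm(15)
  vals <- data.frame(q1 = x, q2 = 2 * x + 3)
  specs <- data.frame(name = c("q1", "q2"), vtype = "quantitative")
  s <- typed_survey(vals, specs)
  expect_equal(homogeneity(s, c("q1", "q2")), 2, tolerance = 1e-10)
})

test_that("first-PC scores match an explicit SVD of the documented matrix", {
  s <- three_var_mixed(seed = 17)
  M <- herdclust:::mixed_pca_matrix(s, c("q1", "q2", "f1"))
  sv <- svd(M)
  ref <- M %*% sv$v[, 1]
  ref <- sign(sv$v[1, 1]) * ref
  f <- synthetic_variable(s, c("q1", "q2", "f1"))
  expect_equal(as.numeric(f), as.numeric(ref - mean(ref)), tolerance = 1e-10)
})

test_that("variable clustering merges duplicated variables first", {
  set.seed(12)
  x <- rnorm(20); y <- rnorm(20)
  vals <- data.frame(a = x, b = x + rnorm(20, 0, 1e-6), c = y)
  specs <- data.frame(name = c("a", "b", "c"), vtype = "quantitative")
  tree <- cluster_of_variables(typed_survey(vals, specs))
  expect_equal(sort(tree$merges[1, ]), c(-2, -1))
  expect_equal(tree$total_H[1], 3)     # start partition: each variable H = 1
  groups <- cut_cov_tree(tree, 2)
  expect_true(list(c("a", "b")) %in% groups || any(
    vapply(groups, function(g) setequal(g, c("a", "b")), TRUE)))
})

test_that("merging never increases total homogeneity", {
  for (seed in 1:5) {
    s <- random_survey(n = 12, n_quant = 4, n_nom = 3, n_asym = 1, seed = seed)
    tree <- cluster_of_variables(s)
    expect_true(all(tree$losses > -1e-8))
    expect_true(all(diff(tree$total_H) < 1e-8))
  }
})

test_that("planted two-block variable structure is recovered at the 2-cluster cut", {
  set.seed(30)
  n <- 25
  f1 <- rnorm(n); f2 <- rnorm(n)
  vals <- data.frame(a1 = f1 + rnorm(n, 0, .2), a2 = -f1 + rnorm(n, 0, .2),
                     a3 = f1 + rnorm(n, 0, .2),
                     b1 = f2 + rnorm(n, 0, .2), b2 = f2 + rnorm(n, 0, .2))
  specs <- data.frame(name = names(vals), vtype = "quantitative")
  tree <- cluster_of_variables(typed_survey(vals, specs))
  groups <- cut_cov_tree(tree, 2)
  expect_true(any(vapply(groups, function(g) setequal(g, c("a1", "a2", "a3")),
                         TRUE)))
})

test_that("covahc recovers a planted herd factor and honours k = n", {
  sim <- simulate_survey(n_clusters = 3, herds_per_cluster = c(7, 7, 7),
                         n_quantitative = 6, n_qualitative = 10,
                         separation = 6, plant_removable = FALSE, seed = 44)
  p <- covahc(sim$survey, k = 3)
  tab <- table(p$labels, sim$labels)
  expect_true(all(rowSums(tab > 0) == 1))   # pure clusters up to relabeling
  pn <- covahc(sim$survey, k = 21)
  expect_equal(pn$k, 21)
})
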