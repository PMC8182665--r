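test_that("silhouette matches the brute-force oracle on random instances", {
  set.seed(14)
  for (rep in 1:30) {
    n <- sample(6:30, 1)
    k <- sample(2:(n - 1), 1)
    D <- as_herd_dissim(as.matrix(dist(matrix(rnorm(2 * n), n))))
    lab <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    rep_s <- silhouette_report(D, herd_partition(setNames(lab, rownames(D))))
    expect_equal(rep_s$widths$s, silhouette_oracle(D, lab), tolerance = 1e-10)
    expect_true(all(rep_s$widths$s >= -1 & rep_s$widths$s <= 1))
    expect_equal(rep_s$asw, mean(rep_s$widths$s))
  }
})

test_that("identical-herd clusters give ASW 1; equidistant herds give s = 0", {
  x <- c(0, 0, 0, 3, 3, 3)
  D <- as_herd_dissim(as.matrix(dist(x)))
  r <- silhouette_report(D, herd_partition(
    setNames(c(1, 1, 1, 2, 2, 2), rownames(D))))
  expect_equal(r$asw, 1)
  # herd equidistant between its own and the other cluster
  D2 <- matrix(c(0, 1, 1,
                 1, 0, 1,
                 1, 1, 0), 3)
  r2 <- silhouette_report(as_herd_dissim(D2), herd_partition(
    setNames(c(1, 1, 2), paste0("h", 1:3))))
  expect_equal(r2$widths$s[1], 0)   # a(1) = b(1) = 1
})

test_that("k = 1 and k = n return all-zero silhouettes with a warning", {
  D <- as_herd_dissim(as.matrix(dist(1:5)))
  expect_warning(r1 <- silhouette_report(D, rep(1, 5)), "k = 1 or k = n")
  expect_equal(r1$widths$s, rep(0, 5))
  expect_warning(rn <- silhouette_report(D, 1:5), "k = 1 or k = n")
  expect_equal(rn$asw, 0)
  # singleton clusters inside a valid partition also get s = 0
  rs <- silhouette_report(D, c(1, 1, 2, 2, 3))
  expect_equal(rs$widths$s[5], 0)
})

test_that("ASW is invariant to relabeling and uniform scaling of D", {
  set.seed(15)
  D <- as.matrix(dist(rnorm(12)))
  lab <- rep(1:3, each = 4)
  a1 <- silhouette_report(as_herd_dissim(D), lab)$asw
  a2 <- silhouette_report(as_herd_dissim(5 * D), lab)$asw
  a3 <- silhouette_report(as_herd_dissim(D), c(2, 3, 1)[lab])$asw
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("misclassification report lists only strictly negative widths", {
  # two tight groups with one herd planted in the wrong cluster
  x <- c(0, .1, .2, 5, 5.1, 5.2)
  D <- as_herd_dissim(as.matrix(dist(x)))
  lab <- c(1, 1, 2, 2, 2, 2)          # herd 3 swapped into the far cluster
  r <- silhouette_report(D, herd_partition(setNames(lab, rownames(D))))
  mis <- misclassification_report(r)
  expect_true("3" %in% mis$herd_id || "h3" %in% mis$herd_id ||
                any(r$widths$s[3] == mis$s))
  expect_true(all(mis$s < 0))
  expect_equal(order(mis$s), seq_len(nrow(mis)))
  # perfectly separated -> empty; all-zero -> empty
  good <- silhouette_report(D, herd_partition(
    setNames(c(1, 1, 1, 2, 2, 2), rownames(D))))
  expect_equal(nrow(misclassification_report(good)), 0)
  suppressWarnings(zero <- silhouette_report(D, rep(1, 6)))
  expect_equal(nrow(misclassification_report(zero)), 0)
})

test_that("duplicate-herd survey with 2 planted groups has ASW 1 at k = 2", {
  vals <- data.frame(
    q = c(1, 1, 1, 4, 4, 4),
    m = c("a", "a", "a", "b", "b", "b"),
    stringsAsFactors = FALSE)
  specs <- data.frame(name = c("q", "m"),
                      vtype = c("quantitative", "nominal"))
  s <- typed_survey(vals, specs)
  D <- gower_matrix(s)
  for (p in list(cut_tree(ahc_ward(D), 2), pam_cluster(D, 2))) {
    expect_equal(silhouette_report(D, p)$asw, 1)
  }
})

test_that("asw_sweep returns a full table with values in [-1, 1] and honours ties", {
  sim <- simulate_survey(n_clusters = 2, herds_per_cluster = c(6, 6),
                         n_quantitative = 4, n_qualitative = 6,
                         separation = 5, plant_removable = FALSE, seed = 3)
  sw <- asw_sweep(sim$survey, k_range = 2:5)
  expect_true(all(sw$table >= -1 & sw$table <= 1, na.rm = TRUE))
  expect_equal(dim(sw$table), c(4, 4))
  expect_equal(sw$best$k, 2)
  # k-range restricted to a single value yields a one-column table
  sw1 <- asw_sweep(sim$survey, methods = c("ahc", "pam"), k_range = 2)
  expect_equal(ncol(sw1$table), 1)
})
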