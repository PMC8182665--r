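test_that("identical rows are at distance zero, fully discordant rows at one", {
  vals <- data.frame(a = c("x", "x", "y"), b = c("u", "u", "v"),
                     stringsAsFactors = FALSE)
  specs <- data.frame(name = c("a", "b"), vtype = "nominal")
  D <- gower_matrix(typed_survey(vals, specs))
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)
  expect_equal(diag(unclass(D)), rep(0, 3), ignore_attr = TRUE)
})

test_that("hand-computed 4-herd mixed example matches", {
  s <- tiny_mixed_survey()
  D <- gower_matrix(s)
  # size range 30; housing mismatch 0/1; pasture asym binary (0,0) excluded
  d12 <- ((10 / 30) + 1 + 1) / 3
  d13 <- ((20 / 30) + 1 + 0) / 3
  d14 <- ((30 / 30) + 0 + 1) / 3
  d24 <- ((20 / 30) + 1) / 2          # pasture jointly absent -> 2 variables
  d34 <- ((10 / 30) + 1 + 1) / 3
  d23 <- ((10 / 30) + 0 + 1) / 3
  expect_equal(D["h1", "h2"], d12)
  expect_equal(D["h1", "h3"], d13)
  expect_equal(D["h1", "h4"], d14)
  expect_equal(D["h2", "h4"], d24)
  expect_equal(D["h3", "h4"], d34)
  expect_equal(D["h2", "h3"], d23)
})

test_that("gower_matrix matches the naive double-loop oracle on random surveys", {
  for (seed in 1:40) {
    s <- random_survey(n = sample(4:12, 1), missing_rate = 0.1, seed = seed)
    D <- tryCatch(gower_matrix(s), error = function(e) NULL)
    if (is.null(D)) next   # a pair may share no observed variable
    O <- gower_oracle(s)
    expect_equal(as.matrix(D), O, tolerance = 1e-12)
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(as.matrix(D), t(as.matrix(D)))
  }
})

test_that("gower_matrix agrees with cluster::daisy on complete mixed data", {
  set.seed(9)
  s <- random_survey(n = 15, missing_rate = 0, seed = 9)
  D <- gower_matrix(s)
  df <- s$values
  df$m1 <- factor(df$m1); df$m2 <- factor(df$m2); df$m3 <- factor(df$m3)
  dd <- cluster::daisy(df, metric = "gower",
                       type = list(asymm = c("b1", "b2")))
  expect_equal(as.matrix(D), as.matrix(dd), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("ordinal variables enter via rank normalization", {
  vals <- data.frame(o = c("low", "mid", "high", "low"),
                     stringsAsFactors = FALSE)
  specs <- data.frame(name = "o", vtype = "ordinal",
                      levels = "low|mid|high")
  D <- gower_matrix(typed_survey(vals, specs))
  expect_equal(D[1, 2], 0.5)
  expect_equal(D[1, 3], 1)
  expect_equal(D[1, 4], 0)
})

test_that("a pair with no comparable variable raises a named error", {
  vals <- data.frame(b1 = c(0, 0), b2 = c(0, 0))
  specs <- data.frame(name = c("b1", "b2"), vtype = "binary_asymmetric")
  expect_error(gower_matrix(typed_survey(vals, specs, c("hA", "hB"))),
               "no comparable variable.*hA.*hB")
})

test_that("removing a variable on which two herds agree never increases distance", {
  for (seed in 1:10) {
    s <- random_survey(n = 8, seed = seed)
    D <- gower_matrix(s)
    # find a pair agreeing on some nominal variable
    for (v in c("m1", "m2", "m3")) {
      agree <- which(outer(s$values[[v]], s$values[[v]], "==") &
                       upper.tri(diag(8)), arr.ind = TRUE)
      if (!nrow(agree)) next
      keep <- setdiff(s$specs$name, v)
      s2 <- typed_survey(s$values[keep],
                         s$specs[s$specs$name != v, , drop = FALSE],
                         s$herd_ids)
      D2 <- gower_matrix(s2)
      i <- agree[1, 1]; j <- agree[1, 2]
      expect_gte(D2[i, j] + 1e-12, D[i, j])
    }
  }
})

test_that("quantitative-only surveys equal the range-normalized Manhattan mean", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    p <- sample(2:5, 1)
    vals <- as.data.frame(matrix(rnorm(n * p), n))
    names(vals) <- paste0("q", seq_len(p))
    specs <- data.frame(name = names(vals), vtype = "quantitative")
    D <- gower_matrix(typed_survey(vals, specs))
    rngs <- vapply(vals, function(x) diff(range(x)), 0)
    O <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      O[i, j] <- mean(abs(unlist(vals[i, ]) - unlist(vals[j, ])) / rngs)
    }
    expect_equal(unname(as.matrix(D)), O, tolerance = 1e-12)
  }
})
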