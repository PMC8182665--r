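# small in-code fixtures and independent oracles shared across tests

# hand-sized mixed survey: 4 herds x 3 variables (quant, nominal, asym binary)
tiny_mixed_survey <- function() {
  vals <- data.frame(
    size = c(10, 20, 30, 40),
    housing = c("tie", "free", "free", "tie"),
    pasture = c(1, 0, 1, 0),
    stringsAsFactors = FALSE)
  specs <- data.frame(
    name = c("size", "housing", "pasture"),
    vtype = c("quantitative", "nominal", "binary_asymmetric"),
    stringsAsFactors = FALSE)
  typed_survey(vals, specs, paste0("h", 1:4))
}

# random mixed survey used by property tests
random_survey <- function(n = 10, n_quant = 3, n_nom = 3, n_asym = 2,
                          missing_rate = 0, seed = 1) {
  set.seed(seed)
  vals <- list()
  specs <- list()
  for (j in seq_len(n_quant)) {
    vals[[paste0("q", j)]] <- rnorm(n)
    specs[[length(specs) + 1]] <- data.frame(name = paste0("q", j),
                                             vtype = "quantitative")
  }
  for (j in seq_len(n_nom)) {
    vals[[paste0("m", j)]] <- sample(letters[1:3], n, replace = TRUE)
    specs[[length(specs) + 1]] <- data.frame(name = paste0("m", j),
                                             vtype = "nominal")
  }
  for (j in seq_len(n_asym)) {
    vals[[paste0("b", j)]] <- rbinom(n, 1, 0.5)
    specs[[length(specs) + 1]] <- data.frame(name = paste0("b", j),
                                             vtype = "binary_asymmetric")
  }
  df <- as.data.frame(vals, stringsAsFactors = FALSE)
  if (missing_rate > 0) {
    for (j in seq_along(df)) {
      df[[j]][runif(n) < missing_rate] <- NA
    }
  }
  typed_survey(df, do.call(rbind, specs))
}

# naive double-loop Gower oracle, written independently of gower_matrix
gower_oracle <- function(survey) {
  v <- survey$values
  sp <- survey$specs
  n <- nrow(v)
  rngs <- lapply(seq_len(nrow(sp)), function(j) {
    if (sp$vtype[j] == "quantitative") diff(range(v[[j]], na.rm = TRUE))
    else if (sp$vtype[j] == "ordinal") {
      lev <- strsplit(sp$levels[j], "|", fixed = TRUE)[[1]]
      r <- match(v[[j]], lev)
      diff(range(r, na.rm = TRUE))
    } else NA
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    num <- 0; den <- 0
    for (j in seq_len(nrow(sp))) {
      a <- v[[j]][i]; b <- v[[j]][k]
      if (is.na(a) || is.na(b)) next
      w <- sp$weight[j]
      if (sp$vtype[j] == "quantitative") {
        if (rngs[[j]] > 0) {
          num <- num + w * abs(a - b) / rngs[[j]]
        }
        den <- den + w
      } else if (sp$vtype[j] == "ordinal") {
        lev <- strsplit(sp$levels[j], "|", fixed = TRUE)[[1]]
        if (rngs[[j]] > 0) {
          num <- num + w * abs(match(a, lev) - match(b, lev)) / rngs[[j]]
        }
        den <- den + w
      } else if (sp$vtype[j] == "binary_asymmetric") {
        if (a == 0 && b == 0) next
        num <- num + w * (a != b)
        den <- den + w
      } else {
        num <- num + w * (a != b)
        den <- den + w
      }
    }
    D[i, k] <- num / den
  }
  dimnames(D) <- list(survey$herd_ids, survey$herd_ids)
  D
}

# brute-force silhouette oracle (double loop over herds and clusters)
silhouette_oracle <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# exhaustive PAM oracle: best medoid set over all size-k subsets
pam_oracle <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  best <- Inf
  for (set in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(D[, set, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# naive O(n^3) Ward (ward.D2) oracle via explicit Lance-Williams updates
ward_oracle <- function(D) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  d <- D2
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bv <- Inf
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      if (active[i] && active[j] && d[i, j] < bv) {
        bv <- d[i, j]; best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bv)
    ni <- sizes[i]; nj <- sizes[j]
    for (h in seq_len(n)) {
      if (!active[h] || h == i || h == j) next
      nh <- sizes[h]
      d[i, h] <- d[h, i] <-
        ((ni + nh) * d[i, h] + (nj + nh) * d[j, h] - nh * d[i, j]) /
        (ni + nj + nh)
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
  }
  heights
}

# default herd partition used by the genetic-evaluation fixtures
toy_partition <- function(n_herds = 12, k = 3) {
  herd_partition(setNames(rep(seq_len(k), length.out = n_herds),
                          sprintf("h%02d", seq_len(n_herds))))
}
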