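#' Numeric expansion of mixed survey columns for principal components
#'
#' Quantitative columns are standardized to unit population variance;
#' qualitative columns are expanded to centered level indicators scaled by
#' the inverse square root of the level frequency (the PCAmix / factor
#' analysis of mixed data convention). With this scaling the leading
#' eigenvalue of the column covariance equals the cluster homogeneity
#' (sum of squared correlations with quantitative members plus correlation
#' ratios with qualitative members).
#'
#' @param survey a [typed_survey()].
#' @param vars variable names to expand (default all).
#' @return numeric matrix (herds x expanded columns) with an attribute
#'   `first_col` giving the first expanded column of the first variable.
#' @keywords internal
mixed_pca_matrix <- function(survey, vars = survey$specs$name) {
  vals <- survey$values
  n <- nrow(vals)
  if (n < 3) stop("mixed PCA needs >= 3 herds")
  cols <- list()
  for (nm in vars) {
    sp <- survey$specs[survey$specs$name == nm, , drop = FALSE]
    v <- vals[[nm]]
    if (anyNA(v)) stop("mixed PCA requires complete data (variable '", nm, "')")
    if (sp$vtype == "quantitative") {
      s <- stats::sd(v) * sqrt((n - 1) / n)    # population sd
      if (s == 0) stop("constant variable '", nm, "' in mixed PCA")
      cols[[nm]] <- matrix((v - mean(v)) / s, ncol = 1,
                           dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) stop("constant variable '", nm, "' in mixed PCA")
      G <- stats::model.matrix(~ f - 1)
      p <- colMeans(G)
      Gc <- sweep(G, 2, p)                      # center indicators
      Gs <- sweep(Gc, 2, sqrt(p), "/")          # 1/sqrt(level frequency)
      colnames(Gs) <- paste(nm, levels(f), sep = "=")
      cols[[nm]] <- Gs
    }
  }
  M <- do.call(cbind, cols)
  attr(M, "first_col") <- 1L
  M
}

#' Synthetic variable of a cluster of variables
#'
#' First principal component (scores) of the mixed-data expansion of the
#' member variables. Scores are centered; the sign is fixed so the loading
#' on the first expanded column is nonnegative.
#'
#' @param survey a [typed_survey()].
#' @param vars member variable names.
#' @return numeric vector of per-herd scores (mean 0), with attribute
#'   `eigenvalue` = leading eigenvalue of the mixed covariance = cluster
#'   homogeneity.
#' @export
synthetic_variable <- function(survey, vars = survey$specs$name) {
  M <- mixed_pca_matrix(survey, vars)
  sv <- svd(M, nu = 1, nv = 1)
  v1 <- sv$v[, 1]
  if (v1[1] < 0) v1 <- -v1
  scores <- drop(M %*% v1)
  scores <- scores - mean(scores)
  attr(scores, "eigenvalue") <- sv$d[1]^2 / nrow(M)
  scores
}

#' Homogeneity of a cluster of variables
#'
#' \deqn{H = \sum_{\mathrm{quantitative}} r^2(x_k, f) +
#'          \sum_{\mathrm{qualitative}} \eta^2(f \mid x_k)}
#' where \eqn{f} are the synthetic scores and \eqn{\eta^2} is the
#' between-level share of the score variance. H is bounded by the number of
#' member variables and equals it when all members are perfectly related to
#' the synthetic variable.
#'
#' @param survey a [typed_survey()].
#' @param vars member variable names.
#' @param synthetic per-herd synthetic scores (default: computed by
#'   [synthetic_variable()]).
#' @return the homogeneity H.
#' @export
homogeneity <- function(survey, vars = survey$specs$name,
                        synthetic = synthetic_variable(survey, vars)) {
  f <- as.numeric(synthetic)
  if (stats::sd(f) == 0) stop("constant synthetic variable")
  H <- 0
  for (nm in vars) {
    sp <- survey$specs[survey$specs$name == nm, , drop = FALSE]
    v <- survey$values[[nm]]
    if (sp$vtype == "quantitative") {
      H <- H + stats::cor(v, f)^2
    } else {
      g <- factor(v)
      gm <- tapply(f, g, mean)
      ss_b <- sum(tabulate(g) * (gm - mean(f))^2)
      ss_t <- sum((f - mean(f))^2)
      H <- H + ss_b / ss_t
    }
  }
  unname(H)
}

#' Agglomerative clustering of variables
#'
#' Starts from singleton variable clusters (each with homogeneity 1) and at
#' each step merges the pair of clusters whose merge loses the least
#' homogeneity, `H(A) + H(B) - H(A united B)`; ties go to the lowest cluster
#' indices. The homogeneity of a cluster is the leading eigenvalue of the
#' mixed-data expansion of its members, attained by the cluster's synthetic
#' variable.
#'
#' @param survey a [typed_survey()] with complete data.
#' @return object of class `cov_tree`: `merges` (hclust-style signed merge
#'   matrix over variables), `losses` (homogeneity loss per merge),
#'   `var_names`, `total_H` (aggregated homogeneity after 0..p-1 merges,
#'   starting at p).
#' @export
cluster_of_variables <- function(survey) {
  stopifnot(inherits(survey, "typed_survey"))
  p <- nrow(survey$specs)
  if (p < 2) stop("need >= 2 variables")
  nms <- survey$specs$name
  n <- nrow(survey$values)
  # precompute per-variable numeric expansions once; merges only cbind them
  blocks <- lapply(nms, function(nm) mixed_pca_matrix(survey, nm))
  eig1 <- function(ix) {
    M <- do.call(cbind, blocks[ix])
    svd(M, nu = 0, nv = 0)$d[1]^2 / n
  }
  # active clusters: list of member index vectors; id: hclust convention
  members <- as.list(seq_len(p))
  ids <- -seq_len(p)                      # negative = singleton leaf
  H <- rep(1, p)                          # singleton homogeneity is 1
  cost <- matrix(Inf, p, p)
  merged_H <- matrix(NA_real_, p, p)
  pair_H <- function(a, b) eig1(c(members[[a]], members[[b]]))
  for (a in seq_len(p - 1)) for (b in seq((a + 1), p)) {
    merged_H[a, b] <- pair_H(a, b)
    cost[a, b] <- H[a] + H[b] - merged_H[a, b]
  }
  merges <- matrix(0L, p - 1, 2)
  losses <- numeric(p - 1)
  active <- rep(TRUE, p)
  for (step in seq_len(p - 1)) {
    idx <- which(cost == min(cost), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    a <- idx[1]; b <- idx[2]
    merges[step, ] <- c(ids[a], ids[b])
    losses[step] <- cost[a, b]
    members[[a]] <- c(members[[a]], members[[b]])
    H[a] <- merged_H[a, b]
    ids[a] <- step
    active[b] <- FALSE
    cost[b, ] <- Inf; cost[, b] <- Inf
    for (o in which(active)) {
      if (o == a) next
      lo <- min(o, a); hi <- max(o, a)
      merged_H[lo, hi] <- pair_H(lo, hi)
      cost[lo, hi] <- H[lo] + H[hi] - merged_H[lo, hi]
    }
  }
  structure(list(merges = merges, losses = losses, var_names = nms,
                 total_H = p - cumsum(c(0, losses))),
            class = "cov_tree")
}

#' @export
print.cov_tree <- function(x, ...) {
  p <- length(x$var_names)
  cat("Clustering of", p, "variables;",
      "total homogeneity", p, "->", signif(x$total_H[p], 4), "\n")
  invisible(x)
}

#' Cut a variable-cluster tree into q clusters of variables
#'
#' @param tree a `cov_tree` from [cluster_of_variables()].
#' @param q number of variable clusters.
#' @return list of character vectors of member variable names.
#' @export
cut_cov_tree <- function(tree, q) {
  p <- length(tree$var_names)
  if (q < 1 || q > p) stop("q must be in 1..", p)
  groups <- as.list(seq_len(p))           # keyed by leaf/merge id
  names(groups) <- as.character(-seq_len(p))
  for (step in seq_len(p - q)) {
    m <- tree$merges[step, ]
    groups[[as.character(step)]] <-
      c(groups[[as.character(m[1])]], groups[[as.character(m[2])]])
    groups[[as.character(m[1])]] <- NULL
    groups[[as.character(m[2])]] <- NULL
  }
  lapply(unname(groups), function(ix) tree$var_names[sort(ix)])
}

#' Synthetic-score matrix for a variable partition
#'
#' @param survey a [typed_survey()].
#' @param groups list of variable-name vectors (from [cut_cov_tree()]).
#' @return herds x clusters matrix of synthetic scores.
#' @export
synthetic_scores <- function(survey, groups) {
  S <- vapply(groups, function(g) as.numeric(synthetic_variable(survey, g)),
              numeric(length(survey$herd_ids)))
  rownames(S) <- survey$herd_ids
  colnames(S) <- paste0("SV", seq_along(groups))
  S
}

#' Default number of variable clusters: largest homogeneity drop
#'
#' Picks the partition just before the single merge that loses the most
#' aggregated homogeneity (bounded to at least 2 variable clusters).
#'
#' @param tree a `cov_tree`.
#' @return integer number of variable clusters.
#' @export
choose_n_var_clusters <- function(tree) {
  p <- length(tree$var_names)
  step <- which.max(tree$losses)          # merge with the largest loss
  max(2L, p - step + 1L)                  # partition before that merge
}

#' Clustering of variables combined with herd AHC (CoVAHC)
#'
#' Clusters the variables, summarises each variable cluster by its synthetic
#' variable, and Ward-clusters the herds on Euclidean distances between
#' synthetic-score profiles.
#'
#' @param survey a [typed_survey()].
#' @param k number of herd clusters.
#' @param n_var_clusters number of variable clusters; default chosen by
#'   [choose_n_var_clusters()].
#' @param tree optional precomputed [cluster_of_variables()] result.
#' @return a [herd_partition()] with extra fields `scores` (herds x
#'   variable-clusters synthetic scores), `groups`, `tree`.
#' @export
covahc <- function(survey, k, n_var_clusters = NULL, tree = NULL) {
  if (is.null(tree)) tree <- cluster_of_variables(survey)
  if (is.null(n_var_clusters)) n_var_clusters <- choose_n_var_clusters(tree)
  groups <- cut_cov_tree(tree, n_var_clusters)
  S <- synthetic_scores(survey, groups)
  hc <- stats::hclust(stats::dist(S), method = "ward.D2")
  part <- herd_partition(stats::cutree(hc, k = k), method = "covahc",
                         scores = S, groups = groups, tree = tree)
  part
}
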