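#' Hard partition of herds
#'
#' @param labels integer (or coercible) cluster labels named by herd id.
#' @param method character tag for the producing algorithm.
#' @param ... extra fields stored on the object (medoids, objective, ...).
#' @return object of class `herd_partition` with fields `herd_ids`,
#'   `labels` (named integers 1..k), `k`, `method`.
#' @export
herd_partition <- function(labels, method = "manual", ...) {
  if (is.null(names(labels))) names(labels) <- paste0("herd", seq_along(labels))
  lab <- as.integer(factor(labels))          # compress to 1..k, all nonempty
  names(lab) <- names(labels)
  structure(c(list(herd_ids = names(lab), labels = lab,
                   k = length(unique(lab)), method = method),
              list(...)),
            class = "herd_partition")
}

#' @export
print.herd_partition <- function(x, ...) {
  cat("Herd partition (", x$method, "): ", length(x$labels), " herds in ",
      x$k, " clusters (sizes ", paste(table(x$labels), collapse = "/"),
      ")\n", sep = "")
  invisible(x)
}

#' Ward agglomerative hierarchical clustering
#'
#' Ward clustering on a precomputed dissimilarity using the squared
#' Lance-Williams update (`ward.D2` convention, the variant appropriate for
#' non-squared dissimilarity inputs).
#'
#' @param D a `herd_dissim` or symmetric dissimilarity matrix.
#' @return an `hclust` merge tree (heights on the dissimilarity scale).
#' @export
ahc_ward <- function(D) {
  D <- dissim_matrix(D)
  if (nrow(D) < 2) stop("need at least two herds to cluster")
  stats::hclust(stats::as.dist(D), method = "ward.D2")
}

#' Cut a merge tree into k clusters
#'
#' @param tree an `hclust` object.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return a [herd_partition()].
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  herd_partition(stats::cutree(tree, k = k), method = "ahc")
}

#' Partitioning around medoids
#'
#' Kaufman-Rousseeuw PAM (BUILD seeding then SWAP descent) minimising the
#' total dissimilarity of each herd to its nearest medoid.
#'
#' @param D a `herd_dissim` or symmetric dissimilarity matrix.
#' @param k number of clusters, 1 <= k < n.
#' @return a [herd_partition()] with extra fields `medoids` (herd ids) and
#'   `objective` (total dissimilarity to nearest medoids).
#' @export
pam_cluster <- function(D, k) {
  D <- dissim_matrix(D)
  n <- nrow(D)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  med <- fit$medoids
  lab <- fit$clustering
  obj <- sum(apply(D[, match(med, colnames(D)), drop = FALSE], 1, min))
  herd_partition(lab, method = "pam", medoids = med, objective = obj)
}

#' Fuzzy clustering of a dissimilarity matrix
#'
#' Minimises the Kaufman-Rousseeuw fuzzy objective
#' \deqn{\sum_v \frac{\sum_{i,j} u_{iv}^r u_{jv}^r d(i,j)}{2 \sum_j u_{jv}^r}}
#' over membership matrices with unit row sums. The crisp partition takes
#' each herd's argmax membership (ties to the lowest cluster index). The
#' solver is deterministic; `seed` is accepted for interface stability and
#' ignored.
#'
#' @param D dissimilarity matrix.
#' @param k number of clusters (< n).
#' @param r membership (fuzziness) exponent, > 1. Default 1.1, the
#'   near-crisp setting used for herd allocation.
#' @param seed unused (the solver is deterministic).
#' @param maxit maximum solver iterations.
#' @return list of class `fuzzy_fit`: `membership` (n x k, rows sum to 1),
#'   `r`, `objective`, `converged`, and `partition` (a [herd_partition()]).
#' @export
fuzzy_cluster <- function(D, k, r = 1.1, seed = NULL, maxit = 2000) {
  D <- dissim_matrix(D)
  n <- nrow(D)
  if (k >= n) stop("k must be < number of herds")
  if (k > n / 2 - 1) {
    stop("the fuzzy solver requires k <= n/2 - 1 (here k <= ",
         floor(n / 2 - 1), ")")
  }
  if (r <= 1) stop("membership exponent r must be > 1")
  warn <- FALSE
  fit <- withCallingHandlers(
    cluster::fanny(stats::as.dist(D), k = k, memb.exp = r, maxit = maxit,
                   cluster.only = FALSE, keep.diss = FALSE, keep.data = FALSE),
    warning = function(w) {
      warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  U <- fit$membership
  rownames(U) <- rownames(D)
  crisp <- apply(U, 1, which.max)   # which.max: ties to lowest index
  names(crisp) <- rownames(D)
  structure(list(membership = U, r = r,
                 objective = unname(fit$objective["objective"]),
                 converged = fit$convergence["converged"] == 1 && !warn,
                 partition = herd_partition(crisp, method = "fzc")),
            class = "fuzzy_fit")
}

#' Evaluate the Kaufman-Rousseeuw fuzzy clustering objective
#'
#' @param U membership matrix (rows sum to 1).
#' @param D dissimilarity matrix.
#' @param r membership exponent.
#' @return the objective value.
#' @export
fuzzy_objective <- function(U, D, r) {
  D <- dissim_matrix(D)
  Ur <- U^r
  sum(vapply(seq_len(ncol(U)), function(v) {
    u <- Ur[, v]
    sum(outer(u, u) * D) / (2 * sum(u))
  }, 0))
}

#' @export
print.fuzzy_fit <- function(x, ...) {
  cat("Fuzzy clustering: k =", ncol(x$membership), ", r =", x$r,
      ", objective =", signif(x$objective, 6),
      if (!x$converged) "(not converged)" else "", "\n")
  print(x$partition)
  invisible(x)
}
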