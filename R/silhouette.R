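#' Silhouette report for a herd partition
#'
#' Rousseeuw silhouettes: for herd i with within-cluster mean dissimilarity
#' a(i) (self excluded) and b(i) the smallest mean dissimilarity to another
#' cluster, s(i) = (b(i) - a(i)) / max(a(i), b(i)); herds in singleton
#' clusters get s(i) = 0. With k = 1 or k = n every s(i) is 0 (with a
#' warning): cohesion vs separation is undefined there.
#'
#' @param D dissimilarity matrix (`herd_dissim`, `dist` or plain matrix).
#' @param partition a [herd_partition()] (or bare label vector).
#' @return object of class `silhouette_report`: data.frame `widths`
#'   (herd_id, cluster, neighbor, s), `cluster_means`, `asw`.
#' @export
silhouette_report <- function(D, partition) {
  D <- dissim_matrix(D)
  lab <- if (inherits(partition, "herd_partition")) partition$labels
         else as.integer(factor(partition))
  n <- nrow(D)
  ids <- rownames(D)
  if (length(lab) != n) stop("partition does not match dissimilarity size")
  k <- length(unique(lab))
  if (k == 1 || k == n) {
    warning("silhouettes undefined for k = 1 or k = n; returning all zeros")
    w <- data.frame(herd_id = ids, cluster = lab, neighbor = NA_integer_,
                    s = 0, stringsAsFactors = FALSE)
  } else {
    sil <- cluster::silhouette(lab, dmatrix = D)
    w <- data.frame(herd_id = ids, cluster = as.integer(sil[, "cluster"]),
                    neighbor = as.integer(sil[, "neighbor"]),
                    s = as.numeric(sil[, "sil_width"]),
                    stringsAsFactors = FALSE)
  }
  cm <- tapply(w$s, w$cluster, mean)
  structure(list(widths = w,
                 cluster_means = data.frame(cluster = as.integer(names(cm)),
                                            mean_s = as.numeric(cm)),
                 asw = mean(w$s)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat("Silhouette report: ASW =", sprintf("%.3f", x$asw), "over",
      nrow(x$widths), "herds\n")
  print(x$cluster_means, row.names = FALSE)
  invisible(x)
}

#' Herds with negative silhouettes (potential misclassifications)
#'
#' @param report a [silhouette_report()].
#' @return data.frame of herds with s(i) < 0, sorted ascending by s(i).
#' @export
misclassification_report <- function(report) {
  stopifnot(inherits(report, "silhouette_report"))
  w <- report$widths[report$widths$s < 0, , drop = FALSE]
  w <- w[order(w$s), , drop = FALSE]
  rownames(w) <- NULL
  w
}

#' Average-silhouette-width sweep over methods and cluster numbers
#'
#' Runs the requested clustering methods for every k in `k_range` and scores
#' each configuration by the average silhouette width. AHC, PAM and fuzzy
#' clustering are run and scored on the Gower dissimilarity of the survey;
#' CoVAHC is run on synthetic-variable scores; its silhouettes are scored,
#' by default, on the same Gower matrix as the other methods so that the
#' ASW values entering the selection share one geometry (set
#' `covahc_silhouette = "synthetic"` to score it on Euclidean distances in
#' its own score space as a within-method diagnostic; the sweep records
#' which was used).
#' The best configuration is the argmax of ASW, ties going to the smaller k.
#'
#' @param survey an edited [typed_survey()].
#' @param methods subset of `c("ahc", "pam", "fzc", "covahc")`.
#' @param k_range integer vector of cluster numbers (default 2:10, truncated
#'   to at most n - 1).
#' @param r fuzziness exponent for `fzc`.
#' @param covahc_silhouette `"gower"` (default) or `"synthetic"`.
#' @param n_var_clusters forwarded to [covahc()].
#' @param seed unused (all methods deterministic); kept for interface
#'   stability.
#' @return object of class `asw_sweep`: `table` (method x k ASW matrix, NA
#'   for failed cells), `best` (method, k, asw, partition), `partitions`
#'   (nested list), `D` (the Gower matrix), `covahc_silhouette`.
#' @export
asw_sweep <- function(survey, methods = c("ahc", "pam", "fzc", "covahc"),
                      k_range = 2:10, r = 1.1,
                      covahc_silhouette = c("gower", "synthetic"),
                      n_var_clusters = NULL, seed = NULL) {
  covahc_silhouette <- match.arg(covahc_silhouette)
  methods <- match.arg(methods, several.ok = TRUE)
  n <- length(survey$herd_ids)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("no admissible k in k_range")
  D <- gower_matrix(survey)
  tree <- if ("ahc" %in% methods) ahc_ward(D)
  cov_tree <- if ("covahc" %in% methods) {
    tryCatch(cluster_of_variables(survey), error = function(e) e)
  }
  tab <- matrix(NA_real_, length(methods), length(k_range),
                dimnames = list(methods, k_range))
  parts <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    parts[[m]] <- stats::setNames(vector("list", length(k_range)),
                                  as.character(k_range))
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      cell <- tryCatch({
        p <- switch(m,
          ahc = cut_tree(tree, k),
          pam = pam_cluster(D, k),
          fzc = fuzzy_cluster(D, k, r = r)$partition,
          covahc = {
            if (inherits(cov_tree, "error")) stop(cov_tree)
            covahc(survey, k, n_var_clusters = n_var_clusters,
                   tree = cov_tree)
          })
        Ds <- if (m == "covahc" && covahc_silhouette == "synthetic") {
          as.matrix(stats::dist(p$scores))
        } else D
        # a collapsed partition (k effectively 1) scores 0 by convention
        list(p = p, asw = suppressWarnings(silhouette_report(Ds, p)$asw))
      }, error = function(e) NULL)
      if (!is.null(cell)) {
        tab[m, ki] <- cell$asw
        parts[[m]][[ki]] <- cell$p
      }
    }
  }
  if (all(is.na(tab))) stop("every sweep cell failed")
  # argmax ASW; ties -> smaller k, then method order as listed
  best_val <- max(tab, na.rm = TRUE)
  cand <- which(!is.na(tab) & tab >= best_val - 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE][1, ]
  bm <- methods[cand[1]]; bk <- k_range[cand[2]]
  structure(list(table = tab,
                 best = list(method = bm, k = bk, asw = tab[cand[1], cand[2]],
                             partition = parts[[bm]][[as.character(bk)]]),
                 partitions = parts, D = D,
                 covahc_silhouette = covahc_silhouette),
            class = "asw_sweep")
}

#' @export
print.asw_sweep <- function(x, ...) {
  cat("ASW sweep (rows: methods, cols: k):\n")
  print(round(x$table, 3))
  cat("Best: ", x$best$method, " with k = ", x$best$k,
      " (ASW = ", sprintf("%.3f", x$best$asw), ")\n", sep = "")
  invisible(x)
}
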