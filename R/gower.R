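#' Gower dissimilarity for mixed-type herd surveys
#'
#' Computes the Gower dissimilarity with the usual extension to asymmetric
#' binary variables and missing values:
#' \deqn{d(i,j) = \frac{\sum_k w_k \delta_{ijk} d_{ijk}}{\sum_k w_k \delta_{ijk}}}
#' where per variable \eqn{k}: quantitative contributions are
#' \eqn{|x_{ik}-x_{jk}|/\mathrm{range}_k}; nominal and symmetric binary
#' contributions are 0 on agreement and 1 otherwise; ordinal levels are
#' mapped to ranks, normalised to \eqn{(r-1)/(R-1)} and then treated as
#' quantitative; asymmetric binary variables contribute only when at least
#' one herd shows the attribute (joint absences get \eqn{\delta_{ijk}=0}).
#' \eqn{\delta_{ijk}=0} also whenever either value is missing.
#'
#' @param survey a [typed_survey()] (typically after [edit_variables()]).
#' @return a `herd_dissim` object: a symmetric numeric matrix with zero
#'   diagonal, entries in \[0, 1\] and herd ids as dimnames.
#' @export
gower_matrix <- function(survey) {
  stopifnot(inherits(survey, "typed_survey"))
  n <- length(survey$herd_ids)
  if (n < 2) stop("need at least two herds")
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (j in seq_len(nrow(survey$specs))) {
    sp <- survey$specs[j, , drop = FALSE]
    w <- sp$weight
    if (w == 0) next
    v <- survey$values[[sp$name]]
    cc <- gower_contrib(v, sp)
    num <- num + w * cc$delta * cc$d
    den <- den + w * cc$delta
  }
  if (any(den[upper.tri(den)] == 0)) {
    idx <- which(den == 0 & upper.tri(den), arr.ind = TRUE)[1, ]
    stop("no comparable variable for herd pair (",
         survey$herd_ids[idx[1]], ", ", survey$herd_ids[idx[2]], ")")
  }
  D <- num / den
  diag(D) <- 0
  dimnames(D) <- list(survey$herd_ids, survey$herd_ids)
  as_herd_dissim(D, method = "gower")
}

# per-variable contribution matrices d_ijk and comparability weights delta_ijk
gower_contrib <- function(v, sp) {
  n <- length(v)
  obs <- !is.na(v)
  delta <- outer(obs, obs, "&") * 1
  d <- matrix(0, n, n)
  vt <- sp$vtype
  if (vt %in% c("quantitative", "ordinal")) {
    x <- if (vt == "ordinal") {
      lev <- spec_levels(sp)
      r <- match(as.character(v), lev)
      if (any(is.na(r) & obs)) {
        stop("undeclared ordinal level in '", sp$name, "'")
      }
      (r - 1) / (length(lev) - 1)
    } else as.numeric(v)
    rng <- diff(range(x, na.rm = TRUE))
    if (is.finite(rng) && rng > 0) {
      d <- abs(outer(x, x, "-")) / rng
    }
    d[is.na(d)] <- 0
  } else if (vt %in% c("nominal", "binary_symmetric")) {
    ch <- as.character(v)
    d <- outer(ch, ch, "!=") * 1
    d[is.na(d)] <- 0
  } else if (vt == "binary_asymmetric") {
    x <- as.numeric(v)
    pres <- outer(x, x, "+")            # 0 = joint absence
    joint_absent <- !is.na(pres) & pres == 0
    delta[joint_absent] <- 0
    d <- outer(x, x, "!=") * 1
    d[is.na(d)] <- 0
  } else stop("unknown variable type: ", vt)
  list(d = d, delta = delta)
}

#' Mark a square matrix as a herd dissimilarity
#'
#' @param D symmetric numeric matrix, zero diagonal, entries in \[0, 1\]
#'   (quantitative-only inputs can exceed 1 for non-Gower metrics; only
#'   symmetry and the zero diagonal are enforced here).
#' @param method character tag recording how `D` was obtained.
#' @return `D` with class `herd_dissim`.
#' @export
as_herd_dissim <- function(D, method = "unknown") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  if (max(abs(D - t(D))) > 1e-10) stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("herd", seq_len(nrow(D))),
                        paste0("herd", seq_len(nrow(D))))
  }
  structure(D, class = c("herd_dissim", "matrix"), method = method)
}

#' @export
as.matrix.herd_dissim <- function(x, ...) unclass_dissim(x)

#' @export
print.herd_dissim <- function(x, ...) {
  cat("Herd dissimilarity (", attr(x, "method"), "), ",
      nrow(x), " herds; range [", sprintf("%.3f", min(x[upper.tri(x)])),
      ", ", sprintf("%.3f", max(x[upper.tri(x)])), "]\n", sep = "")
  invisible(x)
}

dissim_matrix <- function(D) {
  if (inherits(D, "herd_dissim")) {
    unclass_dissim(D)
  } else if (inherits(D, "dist")) {
    as.matrix(D)
  } else as.matrix(D)
}

unclass_dissim <- function(D) {
  attr(D, "method") <- NULL
  class(D) <- NULL
  D
}
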