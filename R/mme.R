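#' Variance components of the repeatability animal model
#'
#' @param sigma2_a additive genetic variance.
#' @param sigma2_pe permanent environmental variance.
#' @param sigma2_e residual variance.
#' @return object of class `variance_components` with derived `h2`
#'   (heritability) and `repeatability`.
#' @export
variance_components <- function(sigma2_a, sigma2_pe, sigma2_e) {
  if (any(c(sigma2_a, sigma2_pe, sigma2_e) < 0)) {
    stop("variance components must be nonnegative")
  }
  tot <- sigma2_a + sigma2_pe + sigma2_e
  structure(list(sigma2_a = sigma2_a, sigma2_pe = sigma2_pe,
                 sigma2_e = sigma2_e,
                 h2 = sigma2_a / tot,
                 repeatability = (sigma2_a + sigma2_pe) / tot),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components: sigma2_a = %.4g, sigma2_pe = %.4g, sigma2_e = %.4g\n",
    x$sigma2_a, x$sigma2_pe, x$sigma2_e))
  cat(sprintf("  h2 = %.3f, repeatability = %.3f\n", x$h2, x$repeatability))
  invisible(x)
}

# Assemble the sparse mixed-model design shared by animal_model and em_reml.
# Fixed part: intercept + cg + any of breed/ys/lact/Legendre-DIM/ca present
# in the records (factors with a single observed level are skipped).
# Aliased fixed columns are detected by pivoted Cholesky of X'X and dropped.
build_mme_design <- function(records, pedigree, cg, trait = "y",
                             dim_window = c(5, 365)) {
  stopifnot(inherits(pedigree, "pedigree"))
  if (!trait %in% names(records)) stop("trait column '", trait, "' missing")
  keep <- if (inherits(cg, "cg_assignment")) !is.na(cg$cg) else
    rep(TRUE, nrow(records))
  rec <- records[keep, , drop = FALSE]
  y <- as.numeric(rec[[trait]])
  n <- length(y)
  df <- data.frame(row = seq_len(n))
  terms <- character(0)
  if (inherits(cg, "cg_assignment")) {
    df$cg <- droplevels(cg$cg[keep])
    if (nlevels(df$cg) > 1) terms <- c(terms, "cg")
  }
  for (f in c("breed", "lactation")) {
    if (f %in% names(rec)) {
      v <- droplevels(factor(rec[[f]]))
      if (nlevels(v) > 1) {
        df[[f]] <- v
        terms <- c(terms, f)
      }
    }
  }
  if ("calving_date" %in% names(rec)) {
    v <- droplevels(year_season(rec$calving_date))
    if (nlevels(v) > 1) {
      df$ys <- v
      terms <- c(terms, "ys")
    }
  }
  if ("dim" %in% names(rec)) {
    P <- legendre_dim(rec$dim, order = 3, window = dim_window)
    df$leg1 <- P[, 2]; df$leg2 <- P[, 3]; df$leg3 <- P[, 4]
    terms <- c(terms, "leg1", "leg2", "leg3")
  }
  if ("calving_age" %in% names(rec)) {
    ca <- as.numeric(rec$calving_age)
    if (stats::sd(ca) > 0) {
      df$ca <- ca
      terms <- c(terms, "ca")
    }
  }
  form <- stats::as.formula(paste("~", paste(c("1", terms), collapse = " + ")))
  X <- Matrix::sparse.model.matrix(form, df)
  # rank detection via pivoted dense Cholesky of X'X (p x p, p modest)
  XtX <- as.matrix(Matrix::crossprod(X))
  ch <- suppressWarnings(chol(XtX, pivot = TRUE))
  r <- attr(ch, "rank")
  piv <- attr(ch, "pivot")
  aliased <- colnames(X)[piv[-seq_len(r)]]
  if (length(aliased)) X <- X[, piv[seq_len(r)], drop = FALSE]
  anim <- factor(as.character(rec$animal), levels = pedigree$animal)
  if (anyNA(anim)) stop("records contain animals absent from the pedigree")
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(anim),
                             x = 1, dims = c(n, nrow(pedigree)))
  colnames(Za) <- pedigree$animal
  cow <- droplevels(anim)
  Zp <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(cow),
                             x = 1, dims = c(n, nlevels(cow)))
  colnames(Zp) <- levels(cow)
  W <- cbind(X, Za, Zp)
  list(y = y, X = X, W = W, WtW = Matrix::crossprod(W),
       Wty = as.numeric(Matrix::crossprod(W, y)),
       n = n, p = ncol(X), q_a = nrow(pedigree), q_p = nlevels(cow),
       rank_X = r, aliased = aliased,
       a_idx = ncol(X) + seq_len(nrow(pedigree)),
       p_idx = ncol(X) + nrow(pedigree) + seq_len(nlevels(cow)),
       animals = pedigree$animal, cows = levels(cow),
       keep = which(keep))
}

# coefficient matrix in lambda form: W'W + lambda_a Ainv (+) lambda_pe I
mme_coef <- function(design, Ainv, vc) {
  la <- vc$sigma2_e / vc$sigma2_a
  lp <- vc$sigma2_e / vc$sigma2_pe
  G <- Matrix::bdiag(Matrix::Matrix(0, design$p, design$p),
                     la * Ainv,
                     lp * Matrix::Diagonal(design$q_p))
  Matrix::forceSymmetric(design$WtW + G)
}

#' Pedigree-based repeatability test-day animal model (BLUP)
#'
#' Fits the Henderson mixed-model equations of the repeatability animal
#' model: trait = fixed effects (intercept, contemporary group, and any of
#' breed, year-season of calving, lactation, third-order Legendre DIM
#' regression, calving age present in the records) + random additive genetic
#' effect with pedigree covariance A sigma2_a + random permanent
#' environmental effect per cow + residual. Variance components are either
#' supplied or estimated by [em_reml()] first. Prediction error variances
#' come from the corresponding diagonal block of the inverse coefficient
#' matrix (computed directly; adequate at desk scale, up to roughly 10^4
#' equations).
#'
#' @param records test-day records (see [build_mme_design()] internals for
#'   recognised columns); rows whose CG was dropped are excluded.
#' @param pedigree a [pedigree_table()].
#' @param cg a [build_cg()] assignment (or NULL for no CG effect).
#' @param vc a [variance_components()] object, or NULL to estimate by
#'   EM-REML.
#' @param trait trait column name.
#' @param dim_window DIM window for the Legendre basis.
#' @param reliability_inbreeding if TRUE use r2 = 1 - PEV/((1 + F) sigma2_a).
#' @param ... passed to [em_reml()] when `vc` is NULL.
#' @return object of class `animal_model` with fixed-effect solutions,
#'   `ebv`, `pe`, `pev`, `reliability`, `vc`, `logLik`, `aliased`.
#' @export
animal_model <- function(records, pedigree, cg = NULL, vc = NULL,
                         trait = "y", dim_window = c(5, 365),
                         reliability_inbreeding = FALSE, ...) {
  Ainv <- a_inverse(pedigree)
  if (is.null(vc)) {
    vc <- em_reml(records, pedigree, cg, trait = trait,
                  dim_window = dim_window, ...)$vc
  }
  stopifnot(inherits(vc, "variance_components"))
  design <- build_mme_design(records, pedigree, cg, trait, dim_window)
  C <- mme_coef(design, Ainv, vc)
  Ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(Ch, design$Wty, system = "A"))
  # PEV: animal block of sigma2_e * C^-1
  Ea <- Matrix::sparseMatrix(i = design$a_idx, j = seq_len(design$q_a),
                             x = 1, dims = c(nrow(C), design$q_a))
  Cinv_a <- Matrix::solve(Ch, Ea, system = "A")
  pev <- vc$sigma2_e * as.numeric(Matrix::diag(Cinv_a[design$a_idx, ]))
  denom <- vc$sigma2_a
  if (reliability_inbreeding) {
    denom <- denom * (1 + attr(Ainv, "inbreeding"))
  }
  rel <- pmin(pmax(1 - pev / denom, 0), 1 - 1e-12)
  fixed <- stats::setNames(sol[seq_len(design$p)], colnames(design$X))
  ebv <- stats::setNames(sol[design$a_idx], design$animals)
  pe <- stats::setNames(sol[design$p_idx], design$cows)
  ll <- reml_loglik_from_fit(design, Ch, sol, Ainv, vc)
  structure(list(fixed = fixed, ebv = ebv, pe = pe,
                 pev = stats::setNames(pev, design$animals),
                 reliability = stats::setNames(rel, design$animals),
                 vc = vc, logLik = ll, aliased = design$aliased,
                 cg = cg, trait = trait, n_records = design$n,
                 rank_X = design$rank_X, design = design,
                 pedigree = pedigree),
            class = "animal_model")
}

# restricted log-likelihood (up to a constant) given a factorized system
reml_loglik_from_fit <- function(design, Ch, sol, Ainv, vc) {
  yPy <- (sum(design$y^2) - sum(sol * design$Wty)) / vc$sigma2_e
  ldetC <- 2 * chol_logdet(Ch) - nrow(design$WtW) * log(vc$sigma2_e)
  ldetAinv <- Matrix::determinant(Ainv, logarithm = TRUE)$modulus
  ldetG <- design$q_a * log(vc$sigma2_a) - ldetAinv +
    design$q_p * log(vc$sigma2_pe)
  ldetR <- design$n * log(vc$sigma2_e)
  -0.5 * as.numeric(ldetR + ldetG + ldetC + yPy)
}

#' @export
print.animal_model <- function(x, ...) {
  cat("Pedigree repeatability animal model for '", x$trait, "': ",
      x$n_records, " records, ", length(x$ebv), " animals",
      if (!is.null(x$cg)) paste0(", ", x$cg$n_cg, " ", x$cg$scheme, " CGs"),
      "\n", sep = "")
  print(x$vc)
  cat(sprintf("Mean reliability: %.3f (all animals)\n", mean(x$reliability)))
  if (length(x$aliased)) {
    cat("Aliased fixed-effect columns dropped:",
        paste(x$aliased, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  rec_animals <- object$design$cows
  s <- list(vc = object$vc,
            n_records = object$n_records,
            n_animals = length(object$ebv),
            reliability_all = c(mean = mean(object$reliability),
                                sd = stats::sd(object$reliability)),
            reliability_with_records =
              c(mean = mean(object$reliability[rec_animals]),
                sd = stats::sd(object$reliability[rec_animals])),
            logLik = object$logLik)
  sires <- sires_with_daughter_records(object$pedigree, rec_animals)
  if (length(sires)) {
    s$reliability_sires <- c(mean = mean(object$reliability[sires]),
                             sd = stats::sd(object$reliability[sires]))
    s$sires <- sires
  }
  class(s) <- "summary.animal_model"
  s
}

#' @export
print.summary.animal_model <- function(x, ...) {
  print(x$vc)
  cat(sprintf("Records: %d; animals: %d\n", x$n_records, x$n_animals))
  cat(sprintf("Reliability (all): %.3f (SD %.3f)\n",
              x$reliability_all["mean"], x$reliability_all["sd"]))
  cat(sprintf("Reliability (with records): %.3f (SD %.3f)\n",
              x$reliability_with_records["mean"],
              x$reliability_with_records["sd"]))
  if (!is.null(x$reliability_sires)) {
    cat(sprintf("Reliability (sires with daughter records): %.3f (SD %.3f)\n",
                x$reliability_sires["mean"], x$reliability_sires["sd"]))
  }
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) object$fixed

#' Estimated breeding values of an animal model
#'
#' @param object an [animal_model()] fit.
#' @return named numeric vector of EBVs.
#' @export
ebv <- function(object) UseMethod("ebv")

#' @export
ebv.animal_model <- function(object) object$ebv

#' @export
fitted.animal_model <- function(object, ...) {
  d <- object$design
  as.numeric(d$W %*% c(object$fixed, object$ebv, object$pe))
}

#' @export
residuals.animal_model <- function(object, ...) {
  object$design$y - stats::fitted(object)
}

#' Sires with at least one daughter holding records
#'
#' @param pedigree a [pedigree_table()].
#' @param animals_with_records character ids of animals holding records.
#' @return character vector of sire ids.
#' @export
sires_with_daughter_records <- function(pedigree, animals_with_records) {
  sort(unique(stats::na.omit(
    pedigree$sire[pedigree$animal %in% animals_with_records])))
}
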