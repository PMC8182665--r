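#' EM-REML variance components for the repeatability animal model
#'
#' Expectation-maximisation REML for the three-component model (additive
#' genetic with pedigree covariance, permanent environment per cow,
#' residual). Per iteration the mixed-model equations are solved and the
#' required inverse blocks extracted from the sparse Cholesky factor; the
#' classical EM updates are
#' \deqn{\sigma^2_a \leftarrow (\hat a' A^{-1} \hat a +
#'       \sigma^2_e\,\mathrm{tr}(A^{-1} C^{aa}))/q_a}
#' \deqn{\sigma^2_{pe} \leftarrow (\hat p'\hat p +
#'       \sigma^2_e\,\mathrm{tr}(C^{pp}))/q_p}
#' \deqn{\sigma^2_e \leftarrow (y'y - \hat s' W'y)/(N - \mathrm{rank}(X))}
#' The restricted log-likelihood is recorded at every accepted iterate and
#' is nondecreasing. Because plain EM approaches the optimum in small steps,
#' the solver by default interleaves a squared-extrapolation (SQUAREM-type)
#' acceleration cycle: two EM steps propose an extrapolated candidate that
#' is accepted only if it does not lower the restricted likelihood and stays
#' positive, otherwise the plain EM result is kept — so the monotonicity
#' guarantee is preserved. A component collapsing toward zero is pinned at
#' `floor` times the phenotypic variance with a warning.
#'
#' @param records test-day records.
#' @param pedigree a [pedigree_table()].
#' @param cg a [build_cg()] assignment or NULL.
#' @param init starting [variance_components()]; default splits the
#'   phenotypic variance as 1/3 each.
#' @param tol relative-change convergence tolerance on the components
#'   (per underlying EM step).
#' @param max_iter maximum EM steps (accelerated cycles count their two
#'   internal EM steps).
#' @param trait trait column name.
#' @param dim_window DIM window for the Legendre basis.
#' @param floor lower bound for a component, as a share of phenotypic
#'   variance.
#' @param accelerate use the safeguarded squared-extrapolation cycles
#'   (default TRUE).
#' @param se if TRUE, compute standard errors of (sigma2_a, sigma2_pe,
#'   sigma2_e) and of h2 from the numerically differentiated observed
#'   information of the restricted likelihood.
#' @return list of class `em_reml`: `vc`, `history` (one row per accepted
#'   iterate: components and logLik), `converged`, `iterations`, and
#'   optionally `se` (named vector incl. `h2`).
#' @export
em_reml <- function(records, pedigree, cg = NULL, init = NULL,
                    tol = 1e-4, max_iter = 300, trait = "y",
                    dim_window = c(5, 365), floor = 1e-6,
                    accelerate = TRUE, se = FALSE) {
  design <- build_mme_design(records, pedigree, cg, trait, dim_window)
  Ainv <- a_inverse(pedigree)
  vy <- stats::var(design$y)
  if (is.null(init)) init <- variance_components(vy / 3, vy / 3, vy / 3)
  th <- c(init$sigma2_a, init$sigma2_pe, init$sigma2_e)
  lo <- floor * vy
  ldetAinv <- Matrix::determinant(Ainv, logarithm = TRUE)$modulus
  yy <- sum(design$y^2)
  a_idx <- design$a_idx; p_idx <- design$p_idx
  E <- Matrix::sparseMatrix(i = c(a_idx, p_idx),
                            j = seq_len(design$q_a + design$q_p),
                            x = 1,
                            dims = c(nrow(design$WtW),
                                     design$q_a + design$q_p))
  pinned <- FALSE
  # one EM step: returns the updated components and the loglik AT th
  em_step <- function(th) {
    vc <- variance_components(th[1], th[2], th[3])
    C <- mme_coef(design, Ainv, vc)
    Ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    sol <- as.numeric(Matrix::solve(Ch, design$Wty, system = "A"))
    ess <- yy - sum(sol * design$Wty)
    ll <- -0.5 * as.numeric(
      design$n * log(th[3]) +
        design$q_a * log(th[1]) - ldetAinv + design$q_p * log(th[2]) +
        2 * chol_logdet(Ch) - nrow(C) * log(th[3]) + ess / th[3])
    Cinv <- Matrix::solve(Ch, E, system = "A")
    tr_a <- sum(Ainv * Cinv[a_idx, seq_len(design$q_a)])
    tr_p <- sum(Matrix::diag(Cinv[p_idx, design$q_a + seq_len(design$q_p)]))
    ahat <- sol[a_idx]; phat <- sol[p_idx]
    new <- c(
      (sum(ahat * as.numeric(Ainv %*% ahat)) + th[3] * tr_a) / design$q_a,
      (sum(phat^2) + th[3] * tr_p) / design$q_p,
      ess / (design$n - design$rank_X))
    if (any(new < lo)) {
      pinned <<- TRUE
      new <- pmax(new, lo)
    }
    list(th = new, ll = ll)
  }
  ll_only <- function(th) reml_loglik_theta(th, design, Ainv, ldetAinv)
  hist <- list()
  push <- function(th, ll) hist[[length(hist) + 1]] <<- c(th, ll)
  converged <- FALSE
  n_steps <- 0
  while (n_steps < max_iter && !converged) {
    s1 <- em_step(th)
    n_steps <- n_steps + 1
    push(th, s1$ll)
    if (max(abs(s1$th - th) / pmax(th, lo)) < tol) {
      th <- s1$th
      converged <- TRUE
      break
    }
    if (!accelerate) {
      th <- s1$th
      next
    }
    s2 <- em_step(s1$th)
    n_steps <- n_steps + 1
    push(s1$th, s2$ll)
    if (max(abs(s2$th - s1$th) / pmax(s1$th, lo)) < tol) {
      th <- s2$th
      converged <- TRUE
      break
    }
    r <- s1$th - th
    v <- s2$th - s1$th - r
    if (sum(v^2) < 1e-30) {
      th <- s2$th
      next
    }
    alpha <- -sqrt(sum(r^2) / sum(v^2))
    cand <- th - 2 * alpha * r + alpha^2 * v
    if (all(cand > lo) && ll_only(cand) >= ll_only(s2$th) - 1e-10) {
      th <- cand
    } else {
      th <- s2$th
    }
  }
  if (pinned) {
    warning("a variance component hit the lower floor (", signif(lo, 3), ")")
  }
  if (!converged) {
    warning("EM-REML did not converge in ", max_iter, " steps; ",
            "returning the last iterate")
  }
  hist <- do.call(rbind, hist)
  colnames(hist) <- c("sigma2_a", "sigma2_pe", "sigma2_e", "logLik")
  vc <- variance_components(th[1], th[2], th[3])
  out <- list(vc = vc, history = as.data.frame(hist),
              converged = converged, iterations = n_steps)
  if (se) {
    out$se <- reml_se(design, Ainv, th, ldetAinv)
  }
  class(out) <- "em_reml"
  out
}

#' @export
print.em_reml <- function(x, ...) {
  cat("EM-REML:", x$iterations, "EM steps",
      if (!x$converged) "(not converged)", "\n")
  print(x$vc)
  if (!is.null(x$se)) {
    cat(sprintf("  SE(h2) = %.3g\n", x$se["h2"]))
  }
  invisible(x)
}

chol_logdet <- function(Ch) {
  # log|L| so that 2*chol_logdet = log|C|
  as.numeric(Matrix::determinant(Ch, logarithm = TRUE, sqrt = TRUE)$modulus)
}

# restricted log-likelihood as a function of theta = (s2a, s2pe, s2e);
# refactorizes the system (no traces), used for safeguards and numeric
# information
reml_loglik_theta <- function(theta, design, Ainv, ldetAinv) {
  vc <- variance_components(theta[1], theta[2], theta[3])
  C <- mme_coef(design, Ainv, vc)
  Ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(Ch, design$Wty, system = "A"))
  yPy <- (sum(design$y^2) - sum(sol * design$Wty)) / theta[3]
  ldetC <- 2 * chol_logdet(Ch) - nrow(C) * log(theta[3])
  -0.5 * as.numeric(design$n * log(theta[3]) +
                      design$q_a * log(theta[1]) - ldetAinv +
                      design$q_p * log(theta[2]) + ldetC + yPy)
}

# SEs of components and of h2 from the numerically differentiated observed
# information (central differences on the restricted log-likelihood)
reml_se <- function(design, Ainv, th, ldetAinv) {
  f <- function(x) reml_loglik_theta(x, design, Ainv, ldetAinv)
  h <- pmax(1e-4 * th, 1e-8)
  H <- matrix(0, 3, 3)
  f0 <- f(th)
  for (i in 1:3) {
    for (j in i:3) {
      if (i == j) {
        up <- th; up[i] <- th[i] + h[i]
        dn <- th; dn[i] <- th[i] - h[i]
        H[i, i] <- (f(up) - 2 * f0 + f(dn)) / h[i]^2
      } else {
        pp <- th; pp[i] <- th[i] + h[i]; pp[j] <- th[j] + h[j]
        pm <- th; pm[i] <- th[i] + h[i]; pm[j] <- th[j] - h[j]
        mp <- th; mp[i] <- th[i] - h[i]; mp[j] <- th[j] + h[j]
        mm <- th; mm[i] <- th[i] - h[i]; mm[j] <- th[j] - h[j]
        H[i, j] <- H[j, i] <- (f(pp) - f(pm) - f(mp) + f(mm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 3, 3))
  tot <- sum(th)
  # delta method for h2 = s2a / (s2a + s2pe + s2e)
  g <- c((tot - th[1]) / tot^2, -th[1] / tot^2, -th[1] / tot^2)
  se_h2 <- sqrt(drop(t(g) %*% V %*% g))
  c(sigma2_a = sqrt(V[1, 1]), sigma2_pe = sqrt(V[2, 2]),
    sigma2_e = sqrt(V[3, 3]), h2 = se_h2)
}
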