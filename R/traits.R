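#' Somatic cell score transformation
#'
#' SCS = log2(SCC / 100 000) + 3, the Ali-Shook log transform placing a
#' count of 100 000 cells/mL at score 3 and doubling counts one score apart.
#'
#' @param scc somatic cell count in cells/mL, strictly positive.
#' @return somatic cell score.
#' @export
scs_transform <- function(scc) {
  if (any(!is.na(scc) & scc <= 0)) stop("SCC must be positive")
  log2(scc / 1e5) + 3
}

#' Year-season of calving
#'
#' Four meteorological seasons: Dec-Feb, Mar-May, Jun-Aug, Sep-Nov.
#' December is assigned to the winter block that runs into the following
#' year.
#'
#' @param date calving date (`Date` or coercible).
#' @param with_year if TRUE, return "year-season" levels (December counted
#'   with the following year's winter); otherwise the plain season.
#' @return factor of season (or year-season) levels.
#' @export
year_season <- function(date, with_year = FALSE) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  season <- c("DecFeb", "DecFeb", "MarMay", "MarMay", "MarMay",
              "JunAug", "JunAug", "JunAug", "SepNov", "SepNov",
              "SepNov", "DecFeb")[m]
  if (!with_year) {
    return(factor(season, levels = c("DecFeb", "MarMay", "JunAug", "SepNov")))
  }
  yy <- ifelse(m == 12, y + 1L, y)
  factor(paste(yy, season, sep = "-"))
}

# model frame shared by the test-day trait model
model1_frame <- function(records, partition, trait, dim_window = c(5, 365)) {
  need <- c("animal", "herd", "breed", "calving_date", "lactation", "dim",
            "calving_age", trait)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  hc <- partition$labels[as.character(records$herd)]
  if (anyNA(hc)) stop("some herds in records carry no cluster label")
  P <- legendre_dim(records$dim, order = 3, window = dim_window)
  data.frame(y = records[[trait]],
             breed = factor(records$breed),
             ys = year_season(records$calving_date),
             lact = factor(records$lactation),
             hc = factor(hc),
             leg1 = P[, 2], leg2 = P[, 3], leg3 = P[, 4],
             ca = as.numeric(records$calving_age),
             animal = factor(records$animal))
}

#' Test-day trait model with herd-cluster fixed effect (model 1)
#'
#' Linear mixed model for a repeated test-day trait:
#' y = mu + breed + year-season + lactation + herd cluster
#'     + Legendre(DIM, order 3) + calving age + animal + e,
#' with an independent random animal effect (no pedigree; the pedigree-based
#' machinery lives in [animal_model()]). Fitted by REML via lme4.
#'
#' @param records data.frame of test-day records with columns `animal`,
#'   `herd`, `breed`, `calving_date`, `lactation`, `dim`, `calving_age` and
#'   the trait column.
#' @param partition a [herd_partition()] labelling every herd in `records`.
#' @param trait name of the trait column (e.g. `"Mkg"`, `"SCS"`).
#' @param dim_window DIM range mapped to the Legendre interval \[-1, 1\].
#' @return object of class `hc_trait_fit` wrapping the lme4 fit.
#' @export
fit_model1 <- function(records, partition, trait, dim_window = c(5, 365)) {
  df <- model1_frame(records, partition, trait, dim_window)
  fac <- active_factors(df, c("breed", "ys", "lact", "hc"))
  covs <- c("leg1", "leg2", "leg3",
            if (stats::sd(df$ca) > 0) "ca")
  form <- stats::as.formula(paste(
    "y ~", paste(c("1", fac, covs), collapse = " + "), "+ (1 | animal)"))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- lme4::lmer(form, data = df, REML = TRUE, control = ctrl)
  structure(list(fit = fit, trait = trait, model = "model1",
                 data = df, partition_method = partition$method),
            class = "hc_trait_fit")
}

# fixed factors with at least two observed levels; single-level factors are
# absorbed into the intercept with a warning
active_factors <- function(df, fac) {
  keep <- character(0)
  for (f in fac) {
    if (nlevels(droplevels(df[[f]])) >= 2) {
      keep <- c(keep, f)
    } else {
      warning("fixed factor '", f, "' has a single observed level; ",
              "it is absorbed into the intercept")
    }
  }
  keep
}

#' Fertility trait model with herd-cluster fixed effect (model 2)
#'
#' For the calving-to-first-insemination interval (CFI, days): linear mixed
#' model y = mu + breed + insemination month + lactation + herd cluster +
#' semen type + insemination age + animal + service sire + e with crossed
#' random animal and service-sire effects. For first-insemination success
#' (SFI, 0/1): the same design fitted as a logit-link model by penalized
#' quasi-likelihood, iterating weighted linear mixed fits on the working
#' variate (documented small-cluster bias; no Laplace/AGQ refinement).
#'
#' @param records data.frame with columns `animal`, `herd`, `breed`,
#'   `lactation`, `insem_month` (1-12), `semen` (fresh/frozen/natural),
#'   `service_sire`, `insem_age` and the trait column (`CFI` or `SFI`).
#' @param partition a [herd_partition()].
#' @param trait `"CFI"` or `"SFI"`.
#' @param max_iter,tol PQL iteration controls (SFI only).
#' @return object of class `hc_trait_fit`; for SFI the element `pql` holds
#'   the iteration history and `separation` flags clusters with all-0 or
#'   all-1 outcomes.
#' @export
fit_model2 <- function(records, partition, trait = c("CFI", "SFI"),
                       max_iter = 50, tol = 1e-6) {
  trait <- match.arg(trait)
  need <- c("animal", "herd", "breed", "lactation", "insem_month", "semen",
            "service_sire", "insem_age", trait)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  hc <- partition$labels[as.character(records$herd)]
  if (anyNA(hc)) stop("some herds in records carry no cluster label")
  df <- data.frame(y = records[[trait]],
                   breed = factor(records$breed),
                   mi = factor(records$insem_month, levels = 1:12),
                   lact = factor(records$lactation),
                   hc = factor(hc),
                   semen = factor(records$semen),
                   ca = as.numeric(records$insem_age),
                   animal = factor(records$animal),
                   sire = factor(records$service_sire))
  df$mi <- droplevels(df$mi)
  fac <- active_factors(df, c("breed", "mi", "lact", "hc", "semen"))
  covs <- if (stats::sd(df$ca) > 0) "ca"
  form <- stats::as.formula(paste(
    "y ~", paste(c("1", fac, covs), collapse = " + "),
    "+ (1 | animal) + (1 | sire)"))
  # cows with a single lactation record are common; keep the animal term
  # even when some grouping levels are singletons
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  if (trait == "CFI") {
    if (any(df$y <= 0, na.rm = TRUE)) stop("CFI must be positive")
    fit <- lme4::lmer(form, data = df, REML = TRUE, control = ctrl)
    return(structure(list(fit = fit, trait = trait, model = "model2",
                          data = df, partition_method = partition$method),
                     class = "hc_trait_fit"))
  }
  if (!all(df$y %in% c(0, 1))) stop("SFI must be binary 0/1")
  sep <- tapply(df$y, df$hc, function(v) all(v == 0) || all(v == 1))
  separation <- names(sep)[sep]
  if (length(separation)) {
    warning("complete separation: herd cluster(s) with constant SFI: ",
            paste(separation, collapse = ", "))
  }
  pql <- pql_logit(form, df, max_iter = max_iter, tol = tol, control = ctrl)
  structure(list(fit = pql$fit, trait = trait, model = "model2",
                 data = df, partition_method = partition$method,
                 pql = pql[c("iterations", "converged")],
                 separation = separation),
            class = "hc_trait_fit")
}

# penalized quasi-likelihood: iterate REML fits of the working variate
# z = eta + (y - mu) / (mu (1 - mu)) with weights w = mu (1 - mu)
pql_logit <- function(form, df, max_iter = 50, tol = 1e-6,
                      control = lme4::lmerControl()) {
  y <- df$y
  mu <- (y + 0.5) / 2
  eta <- stats::qlogis(mu)
  fit <- NULL
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    w <- pmax(mu * (1 - mu), 1e-8)
    df$.z <- eta + (y - mu) / w
    df$.w <- w
    zform <- stats::update(form, .z ~ .)
    fit <- suppressWarnings(
      lme4::lmer(zform, data = df, weights = .w, REML = TRUE,
                 control = control))
    eta_new <- stats::fitted(fit)
    if (max(abs(eta_new - eta)) < tol) {
      eta <- eta_new
      converged <- TRUE
      break
    }
    eta <- eta_new
    mu <- stats::plogis(eta)
  }
  if (!converged) warning("PQL did not converge in ", max_iter, " iterations")
  list(fit = fit, iterations = it, converged = converged)
}

#' @export
print.hc_trait_fit <- function(x, ...) {
  cat("Herd-cluster trait model (", x$model, ") for ", x$trait,
      if (!is.null(x$pql)) " [logit PQL]", "\n", sep = "")
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  cat("Variance components:\n")
  print(vc[, c("grp", "vcov")], row.names = FALSE)
  invisible(x)
}

#' Least-squares means for a fixed factor with letter groups
#'
#' Marginal means over an equal-weight reference grid of all fixed factors
#' with covariates at their means, plus unadjusted pairwise Student tests at
#' `alpha` displayed as letter groups (levels not sharing a letter differ
#' significantly). A Tukey adjustment can be requested via `adjust`.
#'
#' @param fit an `hc_trait_fit` (or a bare `lmerMod`).
#' @param factor name of the fixed factor (default `"hc"`).
#' @param alpha significance level for the letter display.
#' @param adjust p-value adjustment passed to emmeans (default `"none"`,
#'   matching unadjusted pairwise t tests).
#' @return object of class `lsm_table`: data.frame with `level`, `estimate`,
#'   `se`, `df`, `letters`, plus attribute `pairwise` (the pairwise test
#'   table).
#' @export
lsmeans_hc <- function(fit, factor = "hc", alpha = 0.05, adjust = "none") {
  mod <- if (inherits(fit, "hc_trait_fit")) fit$fit else fit
  emm <- emmeans::emmeans(mod, specs = factor, lmer.df = "asymptotic")
  es <- as.data.frame(emm)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = adjust))
  lev <- as.character(es[[1]])
  P <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  cmp <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  for (i in seq_along(cmp)) {
    a <- sub("^hc", "", cmp[[i]][1]); b <- sub("^hc", "", cmp[[i]][2])
    a <- gsub("[()]", "", a); b <- gsub("[()]", "", b)
    ai <- match_level(a, lev); bi <- match_level(b, lev)
    P[ai, bi] <- P[bi, ai] <- prs$p.value[i]
  }
  letters <- letter_groups(stats::setNames(es$emmean, lev), P, alpha)
  out <- data.frame(level = lev, estimate = es$emmean, se = es$SE,
                    df = es$df, letters = letters[lev],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, pairwise = prs, class = c("lsm_table", "data.frame"))
}

match_level <- function(x, lev) {
  i <- match(x, lev)
  if (is.na(i)) i <- match(x, paste0("hc", lev))
  if (is.na(i)) {
    hit <- which(vapply(lev, function(l) endsWith(x, l), TRUE))
    if (length(hit) == 1) i <- hit
  }
  if (is.na(i)) stop("cannot map contrast label '", x, "' to a factor level")
  i
}

# compact letter display: insert-and-absorb over estimate-ordered levels
letter_groups <- function(est, P, alpha = 0.05) {
  lev <- names(sort(est))
  k <- length(lev)
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(P[lev[i:(j + 1)], lev[i:(j + 1)]][
      upper.tri(diag(j - i + 2))] > alpha)) {
      j <- j + 1
    }
    groups[[length(groups) + 1]] <- lev[i:j]
  }
  # absorb nested groups
  keep <- rep(TRUE, length(groups))
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (a != b && keep[a] && keep[b] && all(groups[[a]] %in% groups[[b]])) {
      keep[a] <- FALSE
    }
  }
  groups <- groups[keep]
  lab <- stats::setNames(rep("", k), lev)
  for (g in seq_along(groups)) {
    lab[groups[[g]]] <- paste0(lab[groups[[g]]], letters[g])
  }
  lab
}

#' @export
print.lsm_table <- function(x, ...) {
  cat("Least-squares means (levels sharing a letter do not differ):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
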