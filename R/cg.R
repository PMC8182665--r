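#' Legendre polynomial covariates for days in milk
#'
#' Maps DIM from the configured window to t in \[-1, 1\] and evaluates the
#' first four Legendre polynomials
#' (1, t, (3t^2 - 1)/2, (5t^3 - 3t)/2). DIM outside the window is clamped
#' to the window edge with a warning.
#'
#' @param dim days in milk.
#' @param order polynomial order (fixed design supports up to 3).
#' @param window DIM range mapped to \[-1, 1\] (default c(5, 365)).
#' @return matrix with columns P0..P`order`.
#' @export
legendre_dim <- function(dim, order = 3, window = c(5, 365)) {
  stopifnot(order >= 1, order <= 3, window[2] > window[1])
  if (any(dim < window[1] | dim > window[2], na.rm = TRUE)) {
    warning("DIM outside window [", window[1], ", ", window[2],
            "]; clamped to the edge")
    dim <- pmin(pmax(dim, window[1]), window[2])
  }
  t <- 2 * (dim - window[1]) / (window[2] - window[1]) - 1
  P <- cbind(P0 = rep(1, length(t)), P1 = t,
             P2 = (3 * t^2 - 1) / 2, P3 = (5 * t^3 - 3 * t) / 2)
  P[, seq_len(order + 1), drop = FALSE]
}

#' Contemporary-group assignment
#'
#' Builds contemporary groups (CGs) from herd or herd-cluster crossed with
#' test date or calendar test month:
#' \itemize{
#'   \item HTD: herd x test date
#'   \item HCTD: herd cluster x test date
#'   \item HTM: herd x test month
#'   \item HCTM: herd cluster x test month
#' }
#' Groups below `min_size` records follow the configured policy: `"drop"`
#' discards their records (CG set to `NA`), `"merge"` pools them with the
#' nearest-dated group of the same herd unit, repeatedly, until every
#' surviving group meets `min_size` (a herd unit whose total records are
#' below `min_size` is dropped).
#'
#' @param records data.frame with columns `herd` and `test_date`.
#' @param partition a [herd_partition()]; required for cluster schemes.
#' @param scheme one of `"HTD"`, `"HCTD"`, `"HTM"`, `"HCTM"`.
#' @param min_size minimum records per CG (default 3).
#' @param policy `"drop"` (default) or `"merge"`.
#' @return object of class `cg_assignment`: `cg` (factor per record, NA =
#'   dropped), `scheme`, `occupancy` (records per CG), `n_cg`, `dropped`
#'   (record indices), `log`.
#' @export
build_cg <- function(records, partition = NULL,
                     scheme = c("HTD", "HCTD", "HTM", "HCTM"),
                     min_size = 3, policy = c("drop", "merge")) {
  scheme <- match.arg(scheme)
  policy <- match.arg(policy)
  if (!all(c("herd", "test_date") %in% names(records))) {
    stop("records need columns 'herd' and 'test_date'")
  }
  use_cluster <- scheme %in% c("HCTD", "HCTM")
  if (use_cluster && is.null(partition)) {
    stop("scheme ", scheme, " needs a herd partition")
  }
  unit <- if (use_cluster) {
    lab <- partition$labels[as.character(records$herd)]
    if (anyNA(lab)) stop("some herds carry no cluster label")
    paste0("HC", lab)
  } else paste0("H", as.character(records$herd))
  dt <- as.Date(records$test_date)
  time_key <- if (scheme %in% c("HTM", "HCTM")) format(dt, "%Y-%m")
              else format(dt, "%Y-%m-%d")
  cg <- paste(unit, time_key, sep = ":")
  log <- character(0)
  if (policy == "drop") {
    tab <- table(cg)
    small <- names(tab)[tab < min_size]
    drop <- cg %in% small
    if (any(drop)) {
      log <- sprintf("dropped %d records in %d CGs below %d records",
                     sum(drop), length(small), min_size)
    }
    cg[drop] <- NA
  } else {
    ord <- order(unit, dt)
    for (u in unique(unit)) {
      sel <- which(unit == u)
      repeat {
        tab <- table(cg[sel])
        if (!length(tab) || min(tab) >= min_size || length(tab) == 1) break
        smallest <- names(tab)[which.min(tab)]
        # merge into the group with the nearest median date
        meds <- vapply(names(tab), function(g) {
          as.numeric(stats::median(dt[sel][cg[sel] == g]))
        }, 0)
        others <- setdiff(names(tab), smallest)
        target <- others[which.min(abs(meds[others] - meds[smallest]))]
        cg[sel][cg[sel] == smallest] <- target
        log <- c(log, sprintf("merged CG %s into %s", smallest, target))
      }
      tab <- table(cg[sel])
      if (length(tab) == 1 && tab[1] < min_size) {
        cg[sel] <- NA
        log <- c(log, sprintf("dropped herd unit %s (%d records < %d)",
                              u, tab[1], min_size))
      }
    }
  }
  cgf <- factor(cg)
  occ <- table(cgf)
  structure(list(cg = cgf, scheme = scheme,
                 occupancy = as.integer(occ),
                 cg_ids = names(occ), n_cg = nlevels(cgf),
                 dropped = which(is.na(cg)), min_size = min_size,
                 policy = policy, log = log),
            class = "cg_assignment")
}

#' @export
print.cg_assignment <- function(x, ...) {
  cat("Contemporary groups (", x$scheme, "): ", x$n_cg, " CGs, ",
      length(x$cg) - length(x$dropped), " records (",
      length(x$dropped), " dropped); occupancy median ",
      stats::median(x$occupancy), ", mean ",
      sprintf("%.2f", mean(x$occupancy)), "\n", sep = "")
  invisible(x)
}
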