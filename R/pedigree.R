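#' Pedigree table
#'
#' Validates and topologically sorts a three-column pedigree. Unknown
#' parents may be coded `NA`, `""` or `"0"`. Parents that appear only in the
#' sire/dam columns are added as founders. A cycle (an animal among its own
#' ancestors) is an error.
#'
#' @param animal,sire,dam identifier vectors (or a data.frame as first
#'   argument with columns `animal`, `sire`, `dam`).
#' @return data.frame of class `pedigree` with character columns `animal`,
#'   `sire`, `dam` (NA = unknown), sorted so parents precede offspring.
#' @export
pedigree_table <- function(animal, sire = NULL, dam = NULL) {
  if (is.data.frame(animal)) {
    stopifnot(all(c("animal", "sire", "dam") %in% names(animal)))
    sire <- animal$sire; dam <- animal$dam; animal <- animal$animal
  }
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA")] <- NA
    x
  }
  animal <- clean(animal); sire <- clean(sire); dam <- clean(dam)
  if (!length(animal)) stop("empty pedigree")
  if (anyNA(animal)) stop("animal ids must be known")
  if (anyDuplicated(animal)) stop("duplicated animal ids in pedigree")
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  n <- length(animal)
  idx <- stats::setNames(seq_len(n), animal)
  si <- unname(idx[sire]); di <- unname(idx[dam])
  # Kahn topological sort
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (j in kids[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(ord) != n) stop("pedigree contains a cycle")
  out <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "animals (",
      sum(is.na(x$sire) & is.na(x$dam)), "founders )\n")
  invisible(x)
}

#' Inbreeding coefficients (Meuwissen-Luo recursion)
#'
#' @param ped a [pedigree_table()].
#' @return named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  s <- unname(idx[ped$sire]); d <- unname(idx[ped$dam])
  s[is.na(s)] <- 0L; d[is.na(d)] <- 0L
  f <- numeric(n)                    # F_i
  L <- numeric(n)                    # work vector of path coefficients
  dii <- numeric(n)                  # within-family variances
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0) f[s[i]] else -1
    fd <- if (d[i] > 0) f[d[i]] else -1
    dii[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0 || d[i] == 0) {
      f[i] <- 0
      next
    }
    # accumulate A_ii via ancestor traversal
    L[] <- 0
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * dii[j]
      if (s[j] > 0) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0) L[d[j]] <- L[d[j]] + 0.5 * L[j]
      L[j] <- 0
    }
    f[i] <- aii - 1
  }
  stats::setNames(f, ped$animal)
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense recursive construction of A; quadratic in memory, intended for
#' modest pedigrees and as a cross-check of [a_inverse()].
#'
#' @param ped a [pedigree_table()].
#' @return dense symmetric matrix A with animal ids as dimnames.
#' @export
make_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  s <- unname(idx[ped$sire]); d <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        aij <- 0
        if (!is.na(si)) aij <- aij + 0.5 * A[j, si]
        if (!is.na(di)) aij <- aij + 0.5 * A[j, di]
        A[i, j] <- A[j, i] <- aij
      }
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding from the Meuwissen-Luo recursion: for
#' animal i with Mendelian sampling variance
#' d_i = 0.5 - 0.25 (F_s + F_d) (unknown parents contribute F = -1), add
#' 1/d_i to (i,i), -1/(2 d_i) to animal-parent pairs and 1/(4 d_i) to
#' parent-parent pairs.
#'
#' @param ped a [pedigree_table()].
#' @return sparse symmetric `Matrix::dsCMatrix` A-inverse with attribute
#'   `inbreeding` (per-animal F).
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  s <- unname(idx[ped$sire]); d <- unname(idx[ped$dam])
  f <- inbreeding(ped)
  ii <- integer(9 * n); jj <- integer(9 * n); xx <- numeric(9 * n)
  pos <- 0L
  add <- function(i, j, x) {
    pos <<- pos + 1L
    ii[pos] <<- i; jj[pos] <<- j; xx[pos] <<- x
  }
  for (i in seq_len(n)) {
    fs <- if (!is.na(s[i])) f[s[i]] else -1
    fd <- if (!is.na(d[i])) f[d[i]] else -1
    alpha <- 1 / (0.5 - 0.25 * (fs + fd))
    add(i, i, alpha)
    for (p in c(s[i], d[i])) {
      if (!is.na(p)) {
        add(i, p, -alpha / 2); add(p, i, -alpha / 2)
        add(p, p, alpha / 4)
      }
    }
    if (!is.na(s[i]) && !is.na(d[i])) {
      add(s[i], d[i], alpha / 4); add(d[i], s[i], alpha / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii[seq_len(pos)], j = jj[seq_len(pos)],
                               x = xx[seq_len(pos)], dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  attr(Ainv, "inbreeding") <- f
  Ainv
}
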