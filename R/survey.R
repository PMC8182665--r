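#' Typed herd survey
#'
#' A `typed_survey` couples a herd-by-variable table of mixed-type survey
#' responses with a per-variable type declaration. Variable types drive both
#' the editing rules and the Gower dissimilarity: quantitative columns are
#' compared on a range-normalised absolute difference, nominal and symmetric
#' binary columns on simple mismatch, ordinal columns on rank-normalised
#' scores, and asymmetric binary columns on mismatch with joint absences
#' excluded from the comparison.
#'
#' @param values data.frame with one row per herd and one column per
#'   variable. Entries may be `NA`.
#' @param specs data.frame with columns `name`, `vtype` and optionally
#'   `levels` (a single string with levels separated by `|`, required for
#'   ordinal variables) and `weight` (nonnegative, default 1). `vtype` must
#'   be one of `"quantitative"`, `"nominal"`, `"ordinal"`,
#'   `"binary_symmetric"`, `"binary_asymmetric"`.
#' @param herd_ids character vector of herd identifiers; defaults to the
#'   row names of `values`.
#'
#' @return An object of class `typed_survey`: a list with elements
#'   `herd_ids`, `values` and `specs`.
#' @export
typed_survey <- function(values, specs, herd_ids = rownames(values)) {
  stopifnot(is.data.frame(values), is.data.frame(specs))
  if (is.null(herd_ids)) herd_ids <- paste0("herd", seq_len(nrow(values)))
  herd_ids <- as.character(herd_ids)
  if (anyDuplicated(herd_ids)) stop("herd ids must be unique")
  if (length(herd_ids) != nrow(values)) {
    stop("herd_ids must match the number of survey rows")
  }
  specs <- validate_specs(specs, colnames(values))
  for (j in seq_along(values)) {
    vt <- specs$vtype[match(colnames(values)[j], specs$name)]
    if (vt == "quantitative" && !is.numeric(values[[j]])) {
      stop("quantitative column '", colnames(values)[j], "' is not numeric")
    }
    if (vt == "binary_asymmetric") {
      v <- values[[j]]
      if (!all(v %in% c(0, 1, NA))) {
        stop("asymmetric binary column '", colnames(values)[j],
             "' must be coded 0 (absence) / 1 (presence)")
      }
    }
  }
  structure(list(herd_ids = herd_ids, values = values, specs = specs),
            class = "typed_survey")
}

VTYPES <- c("quantitative", "nominal", "ordinal",
            "binary_symmetric", "binary_asymmetric")

validate_specs <- function(specs, var_names) {
  if (!all(c("name", "vtype") %in% names(specs))) {
    stop("specs need columns 'name' and 'vtype'")
  }
  specs$name <- as.character(specs$name)
  specs$vtype <- as.character(specs$vtype)
  if (anyDuplicated(specs$name)) stop("variable names must be unique")
  bad <- setdiff(specs$vtype, VTYPES)
  if (length(bad)) stop("unknown variable type(s): ", paste(bad, collapse = ", "))
  if (!is.null(var_names)) {
    if (!setequal(specs$name, var_names)) {
      stop("specs must cover exactly the survey columns")
    }
    specs <- specs[match(var_names, specs$name), , drop = FALSE]
  }
  if (is.null(specs$weight)) specs$weight <- 1
  specs$weight[is.na(specs$weight)] <- 1
  if (any(specs$weight < 0)) stop("variable weights must be nonnegative")
  if (is.null(specs$levels)) specs$levels <- NA_character_
  ord <- specs$vtype == "ordinal"
  if (any(ord)) {
    nlev <- vapply(strsplit(specs$levels[ord], "|", fixed = TRUE), length, 1L)
    if (any(is.na(specs$levels[ord])) || any(nlev < 2)) {
      stop("ordinal variables need >= 2 ordered levels declared via 'levels'")
    }
  }
  rownames(specs) <- NULL
  specs
}

#' @export
print.typed_survey <- function(x, ...) {
  tab <- table(factor(x$specs$vtype, levels = VTYPES))
  cat("Typed herd survey:", length(x$herd_ids), "herds x",
      nrow(x$specs), "variables\n")
  cat("  ", paste(names(tab)[tab > 0], tab[tab > 0], sep = ": ",
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.typed_survey <- function(x) dim(x$values)

spec_levels <- function(spec_row) {
  strsplit(spec_row$levels, "|", fixed = TRUE)[[1]]
}

is_qualitative <- function(vtype) vtype != "quantitative"

#' Standardize a quantitative column (z transformation)
#'
#' Centers to mean 0 and scales to sample variance 1 over the non-missing
#' entries; missing entries stay missing.
#'
#' @param x numeric vector with at least 2 non-missing values.
#' @return numeric vector of the same length.
#' @export
z_transform <- function(x) {
  if (!is.numeric(x)) stop("z_transform needs a numeric column")
  obs <- x[!is.na(x)]
  if (length(obs) < 2) stop("z_transform needs >= 2 non-missing values")
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0) {
    stop("degenerate variable: zero variance, cannot z-transform")
  }
  (x - mean(obs)) / s
}

#' Standardize all quantitative survey columns
#'
#' @param survey a [typed_survey()].
#' @return the survey with every quantitative column z-transformed.
#' @export
standardize_survey <- function(survey) {
  stopifnot(inherits(survey, "typed_survey"))
  for (j in which(survey$specs$vtype == "quantitative")) {
    survey$values[[j]] <- z_transform(survey$values[[j]])
  }
  survey
}

#' Edit survey variables before clustering
#'
#' Removes variables with limited variation or strong pairwise association:
#' qualitative variables with fewer than two observed levels or whose most
#' frequent level covers at least `max_dominant_share` of the herds, and
#' quantitative variables that are constant or correlated above
#' `max_abs_cor` in absolute value with an earlier-listed quantitative
#' variable (the later one of each offending pair is removed).
#'
#' @param survey a [typed_survey()].
#' @param max_dominant_share dominant-level share at or above which a
#'   qualitative variable is dropped (default 0.95).
#' @param max_abs_cor absolute Pearson correlation above which one of a
#'   pair of quantitative variables is dropped (default 0.95).
#' @return list with elements `survey` (edited) and `log` (data.frame of
#'   removed variables with a `reason` per removal).
#' @export
edit_variables <- function(survey, max_dominant_share = 0.95,
                           max_abs_cor = 0.95) {
  stopifnot(inherits(survey, "typed_survey"))
  specs <- survey$specs
  vals <- survey$values
  drop <- character(0)
  reason <- character(0)
  for (j in seq_len(nrow(specs))) {
    nm <- specs$name[j]
    v <- vals[[nm]]
    obs <- v[!is.na(v)]
    if (is_qualitative(specs$vtype[j])) {
      tab <- table(obs)
      if (length(tab) < 2) {
        drop <- c(drop, nm); reason <- c(reason, "single observed level")
      } else if (max(tab) / length(obs) >= max_dominant_share) {
        drop <- c(drop, nm)
        reason <- c(reason, sprintf("dominant level share %.2f >= %.2f",
                                    max(tab) / length(obs), max_dominant_share))
      }
    } else {
      if (length(unique(obs)) < 2) {
        drop <- c(drop, nm); reason <- c(reason, "constant quantitative")
      }
    }
  }
  keep_q <- setdiff(specs$name[specs$vtype == "quantitative"], drop)
  if (length(keep_q) > 1) {
    qm <- as.matrix(vals[keep_q])
    cm <- suppressWarnings(stats::cor(qm, use = "pairwise.complete.obs"))
    for (a in seq_along(keep_q)) {
      for (b in seq_along(keep_q)) {
        if (b <= a) next
        if (keep_q[b] %in% drop) next
        r <- cm[a, b]
        if (is.finite(r) && abs(r) > max_abs_cor && !(keep_q[a] %in% drop)) {
          drop <- c(drop, keep_q[b])
          reason <- c(reason, sprintf("|r| = %.3f with %s > %.2f",
                                      abs(r), keep_q[a], max_abs_cor))
        }
      }
    }
  }
  keep <- setdiff(specs$name, drop)
  if (!length(keep)) warning("variable editing removed every variable")
  out <- typed_survey(vals[keep], specs[specs$name %in% keep, , drop = FALSE],
                      survey$herd_ids)
  list(survey = out,
       log = data.frame(variable = drop, reason = reason,
                        stringsAsFactors = FALSE))
}
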