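#' Read a herd survey from CSV with a variable-spec sidecar
#'
#' The survey CSV has herds as rows (first column = herd id, header row of
#' variable names). The spec sidecar is a CSV with columns `name`, `vtype`,
#' optional `levels` (levels separated by `|`) and `weight`.
#'
#' @param survey_file path to the survey CSV.
#' @param specs_file path to the variable-spec CSV.
#' @return a [typed_survey()].
#' @export
read_survey <- function(survey_file, specs_file) {
  raw <- utils::read.csv(survey_file, stringsAsFactors = FALSE,
                         check.names = FALSE)
  herd_ids <- as.character(raw[[1]])
  vals <- raw[-1]
  specs <- utils::read.csv(specs_file, stringsAsFactors = FALSE)
  typed_survey(vals, specs, herd_ids)
}

#' Write a herd survey and its variable specs to CSV
#'
#' @param survey a [typed_survey()].
#' @param survey_file,specs_file output paths.
#' @export
write_survey <- function(survey, survey_file, specs_file) {
  out <- cbind(herd_id = survey$herd_ids, survey$values)
  utils::write.csv(out, survey_file, row.names = FALSE)
  utils::write.csv(survey$specs, specs_file, row.names = FALSE, na = "")
  invisible(NULL)
}

#' Write a dissimilarity matrix as square CSV
#'
#' @param D a `herd_dissim` (or square matrix).
#' @param file output path.
#' @export
write_dissimilarity <- function(D, file) {
  utils::write.csv(as.data.frame(dissim_matrix(D)), file)
  invisible(NULL)
}

#' Write a partition as a two-column CSV (herd_id, cluster)
#'
#' @param partition a [herd_partition()].
#' @param file output path.
#' @export
write_partition <- function(partition, file) {
  utils::write.csv(data.frame(herd_id = partition$herd_ids,
                              cluster = partition$labels),
                   file, row.names = FALSE)
  invisible(NULL)
}

#' Read a pedigree from a 3-column CSV (animal, sire, dam; 0/empty unknown)
#'
#' @param file path to the pedigree CSV.
#' @return a [pedigree_table()].
#' @export
read_pedigree <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df)[1:3] <- c("animal", "sire", "dam")
  pedigree_table(df)
}
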