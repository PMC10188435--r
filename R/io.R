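#' Write / read a feature matrix
#'
#' TSV with one row per sample and the 80 component columns in canonical
#' scheme order; integer counts round-trip bit-exactly.
#'
#' @param features A feature-matrix tibble ([extract_cna_features()]).
#' @param path Output/input path.
#' @param scheme Component scheme used to check and order columns.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the feature-matrix tibble.
#' @export
write_feature_matrix <- function(features, path,
                                 scheme = component_scheme()) {
  if (nrow(features) == 0) {
    stop("refusing to write an empty feature matrix", call. = FALSE)
  }
  missing <- setdiff(scheme$label, names(features))
  if (length(missing) > 0) {
    stop("feature matrix is missing component column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- features[, c("sample_id", scheme$label), drop = FALSE]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, scheme = component_scheme()) {
  fm <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_integer()
  ))
  missing <- setdiff(scheme$label, names(fm))
  if (length(missing) > 0) {
    stop("not a feature matrix for this scheme; missing: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  fm[, c("sample_id", scheme$label), drop = FALSE]
}
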