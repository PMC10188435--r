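#' The 80-component classification scheme
#'
#' The eight fundamental CNA feature distributions (BP10MB, BPArm, CN, CNCP,
#' OsCN, SS, NC50, BoChr) are summarised into 80 components, each a bin of
#' one feature's value support. Bins are left-open/right-closed
#' (`lower < value <= upper`, as the label `SS[>7 & <=8]` dictates); the
#' lowest and highest bin of every feature are open-ended so out-of-range
#' values clamp into them.
#'
#' The scheme ships as a package data file so it can be corrected without
#' code changes; `scheme_path` loads an alternative table.
#'
#' @param scheme_path Optional path to a TSV with columns `feature`, `label`,
#'   `lower`, `upper` overriding the packaged scheme.
#' @return A tibble with one row per component: `feature`, `label`, `lower`,
#'   `upper`, in canonical order.
#' @examples
#' sc <- component_scheme()
#' nrow(sc)              # 80
#' dplyr::count(sc, feature)
#' @export
component_scheme <- function(scheme_path = NULL) {
  path <- scheme_path %||%
    system.file("extdata", "component_scheme.tsv", package = "cnahrd",
                mustWork = TRUE)
  sc <- readr::read_tsv(path, col_types = readr::cols(
    feature = readr::col_character(),
    label = readr::col_character(),
    lower = readr::col_double(),
    upper = readr::col_double()
  ))
  validate_scheme(sc)
  sc
}

validate_scheme <- function(scheme) {
  if (anyDuplicated(scheme$label)) {
    stop("component scheme has duplicated labels", call. = FALSE)
  }
  bad <- scheme |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      ok = is.infinite(.data$lower[1]) && .data$lower[1] < 0 &&
        is.infinite(.data$upper[dplyr::n()]) &&
        all(.data$lower[-1] == .data$upper[-dplyr::n()]),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("component scheme bins for feature(s) ",
         paste(bad$feature, collapse = ", "),
         " are not contiguous open-ended intervals", call. = FALSE)
  }
  invisible(scheme)
}

#' Bin one feature's observations into component counts
#'
#' @param values Numeric observations of a single feature.
#' @param feature Feature name present in the scheme.
#' @param scheme A component scheme tibble.
#' @return Named integer vector of counts, one per component of the feature,
#'   in scheme order; values beyond the extreme bins clamp into them.
#' @keywords internal
bin_feature <- function(values, feature, scheme) {
  bins <- scheme[scheme$feature == feature, , drop = FALSE]
  if (nrow(bins) == 0) {
    stop("feature '", feature, "' is absent from the component scheme",
         call. = FALSE)
  }
  counts <- integer(nrow(bins))
  names(counts) <- bins$label
  if (length(values) > 0) {
    # left-open/right-closed: a value lands in the first bin whose upper
    # bound is >= it; the Inf top bin makes this exhaustive (clamping).
    idx <- findInterval(values, bins$upper, left.open = TRUE) + 1L
    counts[] <- tabulate(idx, nbins = nrow(bins))
  }
  counts
}
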