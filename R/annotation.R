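#' Load a genome annotation
#'
#' Returns the chromosome geometry (length and centromere interval per
#' chromosome) that the feature operators and genomic-scar scores need.
#' The p-arm is `[1, centromere_start]` and the q-arm
#' `[centromere_end, length]` (1-based, closed coordinates).
#'
#' @param build One of `"hg19"`, `"hg38"` (packaged cytoband-derived tables,
#'   chromosomes 1-22 and X) or `"toy"` (a small five-chromosome genome for
#'   tests and simulation; see [toy_genome()]).
#' @return A tibble with columns `chrom`, `length`, `centromere_start`,
#'   `centromere_end`, carrying the build name in attribute `"build"`.
#' @examples
#' load_genome_annotation("hg19")
#' load_genome_annotation("toy")
#' @export
load_genome_annotation <- function(build = c("hg19", "hg38", "toy")) {
  if (length(build) != 1L || !build %in% c("hg19", "hg38", "toy")) {
    stop("unknown genome build: ", paste(build, collapse = ", "),
         " (available: hg19, hg38, toy)", call. = FALSE)
  }
  if (build == "toy") {
    return(toy_genome())
  }
  path <- system.file("extdata", paste0("annotation_", build, ".tsv"),
                      package = "cnahrd", mustWork = TRUE)
  ann <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    length = readr::col_double(),
    centromere_start = readr::col_double(),
    centromere_end = readr::col_double()
  ))
  validate_annotation(ann)
  attr(ann, "build") <- build
  ann
}

#' Build a small toy genome annotation
#'
#' Five chromosomes of 150 to 30 Mb with centromeres at roughly 40% of the
#' chromosome, small enough that feature counts can be checked by hand but
#' with realistic arm-scale geometry (arms of 14-90 Mb).
#'
#' @param lengths Named numeric vector of chromosome lengths in bp; names are
#'   chromosome labels.
#' @param centromere_start,centromere_end Numeric vectors aligned with
#'   `lengths` giving the centromere interval per chromosome.
#' @return A genome annotation tibble as in [load_genome_annotation()].
#' @export
toy_genome <- function(lengths = c(`1` = 150e6, `2` = 120e6, `3` = 90e6,
                                   `4` = 60e6, `5` = 30e6),
                       centromere_start = c(60e6, 48e6, 36e6, 24e6, 14e6),
                       centromere_end = c(65e6, 52e6, 39e6, 26e6, 16e6)) {
  ann <- tibble::tibble(
    chrom = names(lengths),
    length = unname(lengths),
    centromere_start = centromere_start,
    centromere_end = centromere_end
  )
  validate_annotation(ann)
  attr(ann, "build") <- "toy"
  ann
}

validate_annotation <- function(ann) {
  stopifnot(all(c("chrom", "length", "centromere_start", "centromere_end")
                %in% names(ann)))
  bad <- ann$centromere_start <= 0 | ann$centromere_end <= ann$centromere_start |
    ann$length <= ann$centromere_end
  if (any(bad)) {
    stop("invalid annotation: need 0 < centromere_start < centromere_end < length for chrom ",
         paste(ann$chrom[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$chrom)) {
    stop("invalid annotation: duplicated chromosome labels", call. = FALSE)
  }
  invisible(ann)
}

#' Split an annotation into chromosome arms
#'
#' @param annotation A genome annotation tibble.
#' @return A tibble with one row per arm: `chrom`, `arm` (`"p"`/`"q"`),
#'   `arm_start`, `arm_end`.
#' @keywords internal
genome_arms <- function(annotation) {
  dplyr::bind_rows(
    dplyr::transmute(annotation, chrom = .data$chrom, arm = "p",
                     arm_start = 1, arm_end = .data$centromere_start),
    dplyr::transmute(annotation, chrom = .data$chrom, arm = "q",
                     arm_start = .data$centromere_end, arm_end = .data$length)
  ) |>
    dplyr::arrange(match(.data$chrom, annotation$chrom), .data$arm)
}

# Chromosome label -> integer index 1..23 (X = 23) used by the BoChr feature.
chrom_index <- function(chrom) {
  idx <- match(chrom, c(as.character(1:22), "X"))
  idx[is.na(idx)] <- suppressWarnings(as.integer(chrom[is.na(idx)]))
  idx
}
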