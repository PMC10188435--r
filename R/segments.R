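#' Read an allele-specific segment table
#'
#' Reads a TSV/CSV of copy-number segments (one row per segment) into the
#' validated tibble that the feature operators consume. Coordinates are
#' 1-based and fully closed, so segment length is `end - start + 1`.
#'
#' @param path Path to a tab- or comma-separated file.
#' @param dialect `"generic"` expects columns `sample` (or `sample_id`),
#'   `chromosome` (or `chrom`), `start`, `end`, `segVal` (or `total_cn`) and
#'   optionally `minor_cn`. `"ascat"` expects ASCAT output headers
#'   (`sample`, `chr`, `startpos`, `endpos`, `nMajor`, `nMinor`); total copy
#'   number is `nMajor + nMinor`.
#' @param drop_sex_mito Drop chromosome Y and mitochondrial segments with a
#'   warning (default `TRUE`); the component scheme spans chromosomes 1-22
#'   and X only.
#' @return A segment tibble with columns `sample_id`, `chrom`, `start`,
#'   `end`, `total_cn`, `minor_cn` (`NA` when the input has no allele-specific
#'   columns), sorted by sample, chromosome and start.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tchromosome\tstart\tend\tsegVal",
#'              "S1\tchr1\t1\t10000000\t2",
#'              "S1\tchr1\t10000001\t20000000\t3"), tf)
#' read_segment_table(tf)
#' @export
read_segment_table <- function(path, dialect = c("generic", "ascat"),
                               drop_sex_mito = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = readr::col_guess()),
                           progress = FALSE, show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  pick <- function(aliases) {
    hit <- intersect(aliases, names(raw))
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  if (dialect == "ascat") {
    cols <- c(sample_id = pick(c("sample", "sample_id", "sampleid")),
              chrom = pick(c("chr", "chromosome", "chrom")),
              start = pick(c("startpos", "start")),
              end = pick(c("endpos", "end")),
              major = pick("nmajor"), minor = pick("nminor"))
    required <- c("sample_id", "chrom", "start", "end", "major", "minor")
  } else {
    cols <- c(sample_id = pick(c("sample", "sample_id", "sampleid")),
              chrom = pick(c("chromosome", "chrom", "chr")),
              start = pick("start"), end = pick("end"),
              total_cn = pick(c("segval", "total_cn", "totalcn", "cn")),
              minor_cn = pick(c("minor_cn", "minorcn", "nminor")))
    required <- c("sample_id", "chrom", "start", "end", "total_cn")
  }
  missing <- required[is.na(cols[required])]
  if (length(missing) > 0) {
    stop("segment table is missing required column(s) for dialect '", dialect,
         "': ", paste(missing, collapse = ", "), call. = FALSE)
  }
  seg <- tibble::tibble(
    sample_id = as.character(raw[[cols[["sample_id"]]]]),
    chrom = as.character(raw[[cols[["chrom"]]]]),
    start = as.numeric(raw[[cols[["start"]]]]),
    end = as.numeric(raw[[cols[["end"]]]])
  )
  if (dialect == "ascat") {
    major <- round_half_up(as.numeric(raw[[cols[["major"]]]]))
    minor <- round_half_up(as.numeric(raw[[cols[["minor"]]]]))
    seg$total_cn <- major + minor
    seg$minor_cn <- pmin(minor, major)
  } else {
    seg$total_cn <- round_half_up(as.numeric(raw[[cols[["total_cn"]]]]))
    seg$minor_cn <- if (is.na(cols[["minor_cn"]])) {
      NA_real_
    } else {
      round_half_up(as.numeric(raw[[cols[["minor_cn"]]]]))
    }
  }
  validate_segments(seg, drop_sex_mito = drop_sex_mito)
}

# ASCAT-style tables are TSV; tolerate CSV by sniffing the header line.
guess_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

round_half_up <- function(x) floor(x + 0.5)

#' Validate and normalize a segment tibble
#'
#' Normalizes chromosome labels (`"chr1"` to `"1"`, `"23"` to `"X"`), rounds
#' fractional copy numbers half-up, sorts segments, enforces the minor allele
#' to be the smaller one, and checks the profile invariants (non-negative
#' integer copy numbers, `end >= start`, no overlapping segments within a
#' chromosome). Idempotent: validating a validated table is a no-op.
#'
#' @param segments A data frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `total_cn` and optionally `minor_cn`.
#' @inheritParams read_segment_table
#' @return The normalized segment tibble.
#' @export
validate_segments <- function(segments, drop_sex_mito = TRUE) {
  segments <- tibble::as_tibble(segments)
  needed <- c("sample_id", "chrom", "start", "end", "total_cn")
  missing <- setdiff(needed, names(segments))
  if (length(missing) > 0) {
    stop("segment table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"minor_cn" %in% names(segments)) segments$minor_cn <- NA_real_
  seg <- dplyr::mutate(
    segments,
    sample_id = as.character(.data$sample_id),
    chrom = normalize_chrom(.data$chrom),
    start = as.numeric(.data$start),
    end = as.numeric(.data$end),
    total_cn = round_half_up(as.numeric(.data$total_cn)),
    minor_cn = round_half_up(as.numeric(.data$minor_cn))
  )
  if (drop_sex_mito) {
    drop <- seg$chrom %in% c("Y", "M", "MT")
    if (any(drop)) {
      warning(sum(drop), " segment(s) on chromosome Y/MT dropped ",
              "(component scheme spans chromosomes 1-22 and X)", call. = FALSE)
      seg <- seg[!drop, , drop = FALSE]
    }
  }
  known <- c(as.character(1:22), "X", "Y", "M", "MT",
             unique(seg$chrom[grepl("^[0-9]+$", seg$chrom)]))
  unknown <- setdiff(unique(seg$chrom), known)
  if (length(unknown) > 0) {
    stop("unknown chromosome label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(seg$end < seg$start)) stop("segment with end < start", call. = FALSE)
  if (any(seg$total_cn < 0)) stop("negative total copy number", call. = FALSE)
  if (any(!is.na(seg$minor_cn) & seg$minor_cn < 0)) {
    stop("negative minor copy number", call. = FALSE)
  }
  # minor is the smaller allele by definition
  flip <- !is.na(seg$minor_cn) & seg$minor_cn > seg$total_cn - seg$minor_cn
  seg$minor_cn[flip] <- seg$total_cn[flip] - seg$minor_cn[flip]
  seg <- dplyr::arrange(seg, .data$sample_id, chrom_index(.data$chrom),
                        .data$start)
  overlap <- seg |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$start <= dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(overlap) > 0) {
    stop("overlapping segments in sample ", overlap$sample_id[1],
         ", chromosome ", overlap$chrom[1], call. = FALSE)
  }
  seg
}

# "chr1" -> "1", "chrX"/"23" -> "X"; idempotent.
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x %in% c("23", "x")] <- "X"
  x[x %in% c("24", "y")] <- "Y"
  x[x %in% c("m", "mt", "Mt")] <- "MT"
  x
}

seg_length <- function(segments) segments$end - segments$start + 1

#' Write a segment table
#'
#' Writes the generic TSV dialect that [read_segment_table()] reads back
#' losslessly.
#'
#' @param segments A segment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  out <- dplyr::transmute(
    segments,
    sample = .data$sample_id, chromosome = .data$chrom,
    start = .data$start, end = .data$end,
    segVal = .data$total_cn, minor_cn = .data$minor_cn
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
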