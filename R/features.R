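#' @title CNA feature operators
#'
#' @description
#' Each operator scans a segment table and emits the observations of one of
#' the eight fundamental CNA feature distributions, one row per observation
#' unit per sample:
#'
#' * `cna_bp10mb()` — breakpoints per 10-Mb window (one observation per
#'   window of every chromosome the sample covers, zero-count windows
#'   included);
#' * `cna_bparm()` — breakpoints per chromosome arm (p and q of every
#'   covered chromosome; breakpoints inside the centromere interval are
#'   assigned to the q-arm);
#' * `cna_cn()` — total copy number, one observation per segment;
#' * `cna_cncp()` — absolute copy-number change between adjacent segments;
#' * `cna_oscn()` — lengths of oscillating copy-number chains (a
#'   three-segment A,B,A pattern scores 1; chromosomes with no chain
#'   contribute a 0);
#' * `cna_ss()` — log10 segment size;
#' * `cna_nc50()` — the minimal number of chromosomes carrying at least half
#'   of the sample's altered length (one observation per sample);
#' * `cna_bochr()` — the chromosome index (1-22, X = 23) of every altered
#'   segment.
#'
#' A *breakpoint* is the junction between two adjacent observed segments on
#' the same chromosome whose total copy numbers differ; its position is the
#' start of the downstream segment, so junctions across an uncovered gap
#' still count when the copy number changes. "Altered" (NC50, BoChr) means
#' total copy number different from the diploid 2.
#'
#' @param segments A validated segment tibble (see [read_segment_table()]);
#'   may hold many samples.
#' @param annotation A genome annotation tibble ([load_genome_annotation()]).
#' @param window Window size in bp for `cna_bp10mb()` (default 10 Mb).
#' @param baseline_cn Copy number considered unaltered for `cna_nc50()` and
#'   `cna_bochr()` (default 2).
#' @return A tibble with columns `sample_id`, `feature`, `value`, one row
#'   per observation.
#' @seealso [classify_components()], [extract_cna_features()]
#' @name cna_features
NULL

check_profile_chroms <- function(segments, annotation) {
  unknown <- setdiff(unique(segments$chrom), annotation$chrom)
  if (length(unknown) > 0) {
    stop("profile contains chromosome(s) absent from the annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(segments)
}

# junctions between adjacent same-chromosome segments with differing total CN
breakpoints <- function(segments) {
  segments |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$total_cn != dplyr::lag(.data$total_cn)) |>
    dplyr::ungroup() |>
    dplyr::transmute(sample_id = .data$sample_id, chrom = .data$chrom,
                     pos = .data$start)
}

# all (sample, chrom) pairs the profile covers, in canonical order
covered_chroms <- function(segments) {
  dplyr::distinct(segments, .data$sample_id, .data$chrom)
}

#' @rdname cna_features
#' @export
cna_bp10mb <- function(segments, annotation, window = 10e6) {
  check_profile_chroms(segments, annotation)
  windows <- covered_chroms(segments) |>
    dplyr::left_join(annotation[, c("chrom", "length")], by = "chrom") |>
    dplyr::reframe(win = seq_len(ceiling(.data$length / window)),
                   .by = c("sample_id", "chrom"))
  bp <- breakpoints(segments) |>
    dplyr::mutate(win = floor((.data$pos - 1) / window) + 1) |>
    dplyr::count(.data$sample_id, .data$chrom, .data$win, name = "n_bp")
  windows |>
    dplyr::left_join(bp, by = c("sample_id", "chrom", "win")) |>
    dplyr::transmute(sample_id = .data$sample_id, feature = "BP10MB",
                     value = dplyr::coalesce(.data$n_bp, 0L))
}

#' @rdname cna_features
#' @export
cna_bparm <- function(segments, annotation) {
  check_profile_chroms(segments, annotation)
  arms <- covered_chroms(segments) |>
    dplyr::left_join(annotation[, c("chrom", "centromere_start")],
                     by = "chrom") |>
    tidyr::crossing(arm = c("p", "q"))
  bp <- breakpoints(segments) |>
    dplyr::left_join(annotation[, c("chrom", "centromere_start")],
                     by = "chrom") |>
    # the p-arm ends at the centromere start; centromeric junctions go to q
    dplyr::mutate(arm = dplyr::if_else(.data$pos <= .data$centromere_start,
                                       "p", "q")) |>
    dplyr::count(.data$sample_id, .data$chrom, .data$arm, name = "n_bp")
  arms |>
    dplyr::left_join(bp, by = c("sample_id", "chrom", "arm")) |>
    dplyr::transmute(sample_id = .data$sample_id, feature = "BPArm",
                     value = dplyr::coalesce(.data$n_bp, 0L))
}

#' @rdname cna_features
#' @export
cna_cn <- function(segments) {
  dplyr::transmute(segments, sample_id = .data$sample_id, feature = "CN",
                   value = .data$total_cn)
}

#' @rdname cna_features
#' @export
cna_cncp <- function(segments) {
  segments |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::mutate(delta = abs(.data$total_cn - dplyr::lag(.data$total_cn))) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$delta)) |>
    dplyr::transmute(sample_id = .data$sample_id, feature = "CNCP",
                     value = .data$delta)
}

# chain lengths of maximal oscillating runs in one chromosome's CN sequence;
# 0 when the chromosome has no run of >= 3 alternating segments
oscn_chain_lengths <- function(cn) {
  n <- length(cn)
  if (n >= 3) {
    ok <- cn[3:n] == cn[1:(n - 2)] & cn[3:n] != cn[2:(n - 1)]
    if (any(ok)) {
      r <- rle(ok)
      return(r$lengths[r$values])
    }
  }
  0L
}

#' @rdname cna_features
#' @export
cna_oscn <- function(segments) {
  segments |>
    dplyr::summarise(value = list(oscn_chain_lengths(.data$total_cn)),
                     .by = c("sample_id", "chrom")) |>
    tidyr::unnest("value") |>
    dplyr::transmute(sample_id = .data$sample_id, feature = "OsCN",
                     value = .data$value)
}

#' @rdname cna_features
#' @export
cna_ss <- function(segments) {
  dplyr::transmute(segments, sample_id = .data$sample_id, feature = "SS",
                   value = log10(.data$end - .data$start + 1))
}

#' @rdname cna_features
#' @export
cna_nc50 <- function(segments, baseline_cn = 2) {
  nc50_one <- function(seg) {
    alt <- seg[seg$total_cn != baseline_cn, , drop = FALSE]
    if (nrow(alt) == 0) return(0L)
    len <- sort(tapply(seg_length(alt), alt$chrom, sum), decreasing = TRUE)
    as.integer(which(cumsum(len) >= 0.5 * sum(len))[1])
  }
  segments |>
    dplyr::summarise(value = nc50_one(dplyr::pick(dplyr::everything())),
                     .by = "sample_id") |>
    dplyr::mutate(feature = "NC50", .after = "sample_id")
}

#' @rdname cna_features
#' @export
cna_bochr <- function(segments, baseline_cn = 2) {
  segments |>
    dplyr::filter(.data$total_cn != baseline_cn) |>
    dplyr::transmute(sample_id = .data$sample_id, feature = "BoChr",
                     value = chrom_index(.data$chrom))
}

#' Classify feature observations into the 80-component count vector
#'
#' Bins the observations emitted by the feature operators into per-sample
#' component counts. Within each feature the bins are exhaustive, so the
#' counts of a feature always sum to that feature's observation count.
#'
#' @param observations A tibble with columns `sample_id`, `feature`, `value`
#'   (rows from the `cna_*` operators, typically bound together).
#' @param scheme A component scheme tibble ([component_scheme()]).
#' @param sample_ids Optional character vector fixing the output rows (so
#'   samples with no observations still get an all-zero vector).
#' @return A feature-matrix tibble: one row per sample, `sample_id` plus one
#'   integer column per component, in canonical scheme order.
#' @export
classify_components <- function(observations, scheme = component_scheme(),
                                sample_ids = NULL) {
  unknown <- setdiff(unique(observations$feature), unique(scheme$feature))
  if (length(unknown) > 0) {
    stop("observations for feature(s) absent from the scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sample_ids <- sample_ids %||% unique(observations$sample_id)
  mat <- matrix(0L, nrow = length(sample_ids), ncol = nrow(scheme),
                dimnames = list(sample_ids, scheme$label))
  obs_split <- split(observations[c("feature", "value")],
                     factor(observations$sample_id, levels = sample_ids))
  for (sid in sample_ids) {
    obs <- obs_split[[sid]]
    if (is.null(obs) || nrow(obs) == 0) next
    by_feat <- split(obs$value, obs$feature)
    for (feat in names(by_feat)) {
      mat[sid, scheme$feature == feat] <- bin_feature(by_feat[[feat]],
                                                      feat, scheme)
    }
  }
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                   tibble::as_tibble(mat))
}

#' Extract the per-sample 80-component feature matrix
#'
#' Runs all eight feature operators on every sample in the segment table and
#' classifies the observations into component counts. Deterministic and
#' independent of sample order.
#'
#' @inheritParams cna_features
#' @param scheme A component scheme tibble ([component_scheme()]).
#' @param baseline_cn Copy number considered unaltered for NC50/BoChr
#'   (default 2, the diploid baseline).
#' @return A feature-matrix tibble: `sample_id` plus 80 integer columns.
#' @examples
#' fx <- fixture_profiles()
#' ann <- fx$annotation
#' extract_cna_features(fx$segments[fx$segments$sample_id == "T1", ], ann)
#' @export
extract_cna_features <- function(segments, annotation,
                                 scheme = component_scheme(),
                                 baseline_cn = 2) {
  segments <- validate_segments(segments)
  check_profile_chroms(segments, annotation)
  obs <- dplyr::bind_rows(
    cna_bp10mb(segments, annotation),
    cna_bparm(segments, annotation),
    cna_cn(segments),
    cna_cncp(segments),
    cna_oscn(segments),
    cna_ss(segments),
    cna_nc50(segments, baseline_cn),
    cna_bochr(segments, baseline_cn)
  )
  classify_components(obs, scheme, sample_ids = unique(segments$sample_id))
}
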