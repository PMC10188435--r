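#' Genomic instability scar scores: LOH, TAI, LST and the HRD score
#'
#' @description
#' The three classical genomic-scar counts and their sum, computed per
#' sample from an allele-specific segment profile:
#'
#' * **LOH** — number of merged loss-of-heterozygosity regions (minor copy
#'   number 0, total copy number >= 1) longer than `loh_min_size`, excluding
#'   regions spanning a whole chromosome;
#' * **TAI** — number of maximal allelic-imbalance regions (minor allele
#'   different from major allele) that reach a telomere — the first or last
#'   covered base of the chromosome — without crossing the centromere;
#' * **LST** — number of large-scale state transitions: after smoothing away
#'   segments shorter than `lst_smooth`, breakpoints whose flanking regions
#'   are both at least `lst_min_flank` long with an inter-segment gap below
#'   `lst_smooth`, counted per chromosome arm.
#'
#' The HRD score is `loh + tai + lst`; samples with a score of at least
#' `cutoff` (default 42) are called HRD.
#'
#' @param segments A validated allele-specific segment tibble; `minor_cn`
#'   must be present for LOH and TAI.
#' @param annotation A genome annotation tibble.
#' @param loh_min_size Minimum merged LOH region length in bp (default 15 Mb).
#' @param lst_min_flank Minimum flanking-region length for an LST in bp
#'   (default 10 Mb).
#' @param lst_smooth Segments shorter than this are smoothed away and gaps
#'   must be below it for an LST (default 3 Mb).
#' @param cutoff HRD-score call threshold (default 42; call is HRD iff
#'   `hrd_score >= cutoff`).
#' @return `gis_score()` returns a tibble with one row per sample:
#'   `sample_id`, `loh`, `tai`, `lst`, `hrd_score`, `call`. The single-score
#'   functions return `sample_id` plus the named count.
#' @examples
#' fx <- fixture_profiles()
#' gis_score(fx$segments[fx$segments$sample_id == "T2", ], fx$annotation)
#' @export
gis_score <- function(segments, annotation, loh_min_size = 15e6,
                      lst_min_flank = 10e6, lst_smooth = 3e6, cutoff = 42) {
  segments <- validate_segments(segments)
  check_profile_chroms(segments, annotation)
  res <- score_loh(segments, annotation, loh_min_size) |>
    dplyr::left_join(score_tai(segments, annotation), by = "sample_id") |>
    dplyr::left_join(score_lst(segments, annotation, lst_min_flank,
                               lst_smooth), by = "sample_id") |>
    dplyr::mutate(hrd_score = .data$loh + .data$tai + .data$lst,
                  call = ifelse(.data$hrd_score >= cutoff, "HRD", "HRP"))
  res
}

require_minor_cn <- function(segments, what) {
  if (any(is.na(segments$minor_cn))) {
    stop("allele-specific data required: ", what,
         " needs minor_cn for every segment", call. = FALSE)
  }
  invisible(segments)
}

# merge runs of consecutive segments flagged TRUE into regions
merge_flagged <- function(seg, flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(region_start = seg$start[starts[keep]],
                 region_end = seg$end[ends[keep]])
}

#' @rdname gis_score
#' @export
score_loh <- function(segments, annotation, loh_min_size = 15e6) {
  segments <- validate_segments(segments)
  require_minor_cn(segments, "LOH")
  one_chrom <- function(seg, chrom_len) {
    regions <- merge_flagged(seg, seg$minor_cn == 0 & seg$total_cn >= 1)
    len <- regions$region_end - regions$region_start + 1
    sum(len > loh_min_size & len < chrom_len)
  }
  segments |>
    dplyr::left_join(annotation[, c("chrom", "length")], by = "chrom") |>
    dplyr::summarise(
      n = one_chrom(dplyr::pick(dplyr::everything()), .data$length[1]),
      .by = c("sample_id", "chrom")
    ) |>
    dplyr::summarise(loh = as.integer(sum(.data$n)), .by = "sample_id")
}

#' @rdname gis_score
#' @export
score_tai <- function(segments, annotation) {
  segments <- validate_segments(segments)
  require_minor_cn(segments, "TAI")
  one_chrom <- function(seg, cent_start, cent_end) {
    ai <- seg$minor_cn != seg$total_cn - seg$minor_cn
    regions <- merge_flagged(seg, ai)
    if (nrow(regions) == 0) return(0L)
    # telomere = first/last covered base; crossing = overlapping the
    # centromere on both sides
    p_tel <- min(seg$start)
    q_tel <- max(seg$end)
    touches <- regions$region_start == p_tel | regions$region_end == q_tel
    crosses <- regions$region_start < cent_start & regions$region_end > cent_end
    sum(touches & !crosses)
  }
  segments |>
    dplyr::left_join(annotation[, c("chrom", "centromere_start",
                                    "centromere_end")], by = "chrom") |>
    dplyr::summarise(
      n = one_chrom(dplyr::pick(dplyr::everything()),
                    .data$centromere_start[1], .data$centromere_end[1]),
      .by = c("sample_id", "chrom")
    ) |>
    dplyr::summarise(tai = as.integer(sum(.data$n)), .by = "sample_id")
}

# iteratively drop sub-threshold segments, absorbing equal-CN neighbours,
# then merge adjacent equal-CN segments; operates on one arm's segments
smooth_segments <- function(seg, min_len) {
  repeat {
    # merge adjacent equal-CN segments (keeps gap structure implicit:
    # merged region spans from first start to last end)
    if (nrow(seg) > 1) {
      g <- cumsum(c(TRUE, diff(seg$total_cn) != 0))
      grp <- factor(g, levels = unique(g))
      seg <- tibble::tibble(
        start = as.numeric(tapply(seg$start, grp, min)[levels(grp)]),
        end = as.numeric(tapply(seg$end, grp, max)[levels(grp)]),
        total_cn = as.numeric(tapply(seg$total_cn, grp,
                                     function(x) x[1])[levels(grp)])
      )
    }
    len <- seg$end - seg$start + 1
    small <- which(len < min_len)
    if (length(small) == 0 || nrow(seg) == 1) return(seg)
    # drop the shortest sub-threshold segment and re-merge
    seg <- seg[-small[which.min(len[small])], , drop = FALSE]
  }
}

#' @rdname gis_score
#' @export
score_lst <- function(segments, annotation, lst_min_flank = 10e6,
                      lst_smooth = 3e6) {
  segments <- validate_segments(segments)
  arms <- genome_arms(annotation)
  one_arm <- function(seg) {
    seg <- smooth_segments(seg, lst_smooth)
    if (nrow(seg) < 2) return(0L)
    i <- seq_len(nrow(seg) - 1)
    left_len <- seg$end[i] - seg$start[i] + 1
    right_len <- seg$end[i + 1] - seg$start[i + 1] + 1
    gap <- seg$start[i + 1] - seg$end[i] - 1
    sum(seg$total_cn[i] != seg$total_cn[i + 1] &
          left_len >= lst_min_flank & right_len >= lst_min_flank &
          gap < lst_smooth)
  }
  # clip segments to arms so centromere-spanning segments contribute to both
  by_arm <- segments |>
    dplyr::inner_join(arms, by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$end >= .data$arm_start &
                    .data$start <= .data$arm_end) |>
    dplyr::mutate(start = pmax(.data$start, .data$arm_start),
                  end = pmin(.data$end, .data$arm_end))
  counts <- by_arm |>
    dplyr::summarise(n = one_arm(dplyr::pick(dplyr::everything())),
                     .by = c("sample_id", "chrom", "arm")) |>
    dplyr::summarise(lst = as.integer(sum(.data$n)), .by = "sample_id")
  # samples whose segments all fall inside centromeres would drop out
  missing <- setdiff(unique(segments$sample_id), counts$sample_id)
  if (length(missing) > 0) {
    counts <- dplyr::bind_rows(
      counts, tibble::tibble(sample_id = missing, lst = 0L))
  }
  counts
}
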