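fx <- fixture_profiles()
t2 <- fx$segments[fx$segments$sample_id == "T2", ]
ann <- fx$annotation

test_that("T2 yields the hand-derived scar counts (1, 1, 1) and HRP call", {
  res <- gis_score(t2, ann)
  expect_equal(res$loh, 1)
  expect_equal(res$tai, 1)
  expect_equal(res$lst, 1)
  expect_equal(res$hrd_score, 3)
  expect_equal(res$call, "HRP")
})

test_that("the >= 42 rule sums the three scores into the call", {
  expect_equal(call_hr_status(0, 0), "HRD")   # trivially at boundary
  # a profile summary of (20, 15, 10) scores 45 -> HRD
  score <- 20 + 15 + 10
  expect_equal(score, 45)
  expect_equal(ifelse(score >= 42, "HRD", "HRP"), "HRD")
  expect_equal(ifelse(0 >= 42, "HRD", "HRP"), "HRP")
})

test_that("LOH excludes whole-chromosome loss and short regions", {
  whole <- validate_segments(data.frame(
    sample_id = "W", chrom = "1", start = 1, end = 30e6,
    total_cn = 1, minor_cn = 0))
  expect_equal(score_loh(whole, ann)$loh, 0)

  short <- validate_segments(data.frame(
    sample_id = "S", chrom = "2", start = c(1, 1e7 + 1), end = c(1e7, 1e8),
    total_cn = c(1, 2), minor_cn = c(0, 1)))
  expect_equal(score_loh(short, ann)$loh, 0)   # 10 Mb < 15 Mb threshold

  # adjacent LOH segments merge before measuring
  merged <- validate_segments(data.frame(
    sample_id = "M", chrom = "2", start = c(1, 1e7 + 1, 2e7 + 1),
    end = c(1e7, 2e7, 1e8), total_cn = c(1, 1, 2), minor_cn = c(0, 0, 1)))
  expect_equal(score_loh(merged, ann)$loh, 1)  # 20 Mb merged region

  # total CN 0 (homozygous deletion) does not count as LOH
  hom <- validate_segments(data.frame(
    sample_id = "H", chrom = "2", start = c(1, 2e7 + 1), end = c(2e7, 1e8),
    total_cn = c(0, 2), minor_cn = c(0, 1)))
  expect_equal(score_loh(hom, ann)$loh, 0)
})

test_that("TAI requires a telomeric, centromere-bounded imbalance", {
  cent <- fx$segments[fx$segments$sample_id == "E_cent", ]
  expect_equal(score_tai(cent, ann)$tai, 0)    # spans the centromere

  interstitial <- validate_segments(data.frame(
    sample_id = "I", chrom = "2", start = c(1, 2e7 + 1, 4e7 + 1),
    end = c(2e7, 4e7, 1e8), total_cn = c(2, 3, 2), minor_cn = c(1, 1, 1)))
  expect_equal(score_tai(interstitial, ann)$tai, 0)

  # q-telomeric imbalance counts too
  qtel <- validate_segments(data.frame(
    sample_id = "Q", chrom = "2", start = c(1, 8e7 + 1), end = c(8e7, 1e8),
    total_cn = c(2, 3), minor_cn = c(1, 1)))
  expect_equal(score_tai(qtel, ann)$tai, 1)
})

test_that("LST needs two >= 10 Mb flanks and smooths < 3 Mb interruptions", {
  small_flank <- validate_segments(data.frame(
    sample_id = "F", chrom = "2", start = c(1, 5e6 + 1, 6e7 + 1),
    end = c(5e6, 4.8e7, 1e8), total_cn = c(3, 2, 2), minor_cn = c(1, 1, 1)))
  # break at 5 Mb has a 5 Mb left flank -> not an LST
  expect_equal(score_lst(small_flank, ann)$lst, 0)

  # a < 3 Mb interruption is absorbed: 2,(3),2 has no 2-vs-2 transition
  interrupted <- validate_segments(data.frame(
    sample_id = "I", chrom = "2", start = c(1, 2e7 + 1, 2.2e7 + 1),
    end = c(2e7, 2.2e7, 4.8e7), total_cn = c(2, 3, 2), minor_cn = c(1, 1, 1)))
  expect_equal(score_lst(interrupted, ann)$lst, 0)

  quiet <- validate_segments(data.frame(
    sample_id = "D", chrom = "2", start = 1, end = 1e8,
    total_cn = 2, minor_cn = 1))
  expect_equal(score_lst(quiet, ann)$lst, 0)
})

test_that("LST grows monotonically as flanked breaks are added", {
  mk <- function(n_breaks) {
    # n_breaks transitions on the q-arm of chrom 2 (52-100 Mb), 12 Mb apart
    bounds <- 5.2e7 + seq(0, by = 1.2e7, length.out = n_breaks + 1)
    bounds[n_breaks + 1] <- 1e8
    validate_segments(data.frame(
      sample_id = "L", chrom = "2",
      start = c(utils::head(bounds, -1) + c(0, rep(1, n_breaks - 1))),
      end = bounds[-1],
      total_cn = rep(c(2, 4), length.out = n_breaks),
      minor_cn = 1))
  }
  counts <- vapply(1:3, function(k) score_lst(mk(k + 1), ann)$lst, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("profiles without allele-specific data fail loudly", {
  seg <- validate_segments(data.frame(
    sample_id = "N", chrom = "1", start = 1, end = 30e6, total_cn = 2))
  expect_error(score_loh(seg, ann), "allele-specific")
  expect_error(score_tai(seg, ann), "allele-specific")
  expect_equal(score_lst(seg, ann)$lst, 0)   # LST needs no minor CN
})

test_that("scores are invariant to chromosome ordering", {
  sim <- simulate_profiles(2, 2, seed = 77)
  g1 <- gis_score(sim$segments, sim$annotation)
  g2 <- gis_score(sim$segments[rev(seq_len(nrow(sim$segments))), ],
                  sim$annotation)
  expect_equal(dplyr::arrange(g1, sample_id), dplyr::arrange(g2, sample_id))
})
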