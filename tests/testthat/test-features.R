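fx <- fixture_profiles()
t1 <- fx$segments[fx$segments$sample_id == "T1", ]
ann <- fx$annotation
sc <- component_scheme()

test_that("T1 reproduces the hand-enumerated observations of every operator", {
  expect_setequal(cna_bp10mb(t1, ann)$value, c(0, 1, 1))
  expect_setequal(cna_bparm(t1, ann)$value, c(1, 1))
  expect_equal(sort(cna_cn(t1)$value), c(2, 2, 3))
  expect_equal(cna_cncp(t1)$value, c(1, 1))
  expect_equal(cna_oscn(t1)$value, 1)       # 2,3,2 scores one chain of 1
  expect_equal(cna_ss(t1)$value, rep(7, 3)) # three exact 10-Mb segments
  expect_equal(cna_nc50(t1)$value, 1)
  expect_equal(cna_bochr(t1)$value, 1)      # one CN3 segment on chrom 1
})

test_that("T1's feature vector matches the composed per-operator counts", {
  fm <- extract_cna_features(t1, ann, sc)
  expect_equal(fm[["BP10MB[0]"]], 1)
  expect_equal(fm[["BP10MB[1]"]], 2)
  expect_equal(fm[["BPArm[1]"]], 2)
  expect_equal(fm[["CN[2]"]], 2)
  expect_equal(fm[["CN[3]"]], 1)
  expect_equal(fm[["CNCP[1]"]], 2)
  expect_equal(fm[["OsCN[1]"]], 1)
  expect_equal(fm[["SS[>6 & <=7]"]], 3)    # log10(1e7) = 7 falls in (6,7]
  expect_equal(fm[["NC50[<=2]"]], 1)
  expect_equal(fm[["BoChr[1]"]], 1)
  expect_equal(sum(fm[, -1]), 1 + 2 + 2 + 2 + 1 + 2 + 1 + 3 + 1 + 1)
})

test_that("degenerate profiles hit the documented edge cases", {
  # single-segment chromosome: all windows observe 0, no CNCP, OsCN 0
  single <- fx$segments[fx$segments$sample_id == "E_bound", ]
  expect_true(all(cna_bp10mb(single, ann)$value == 0))
  expect_equal(nrow(cna_cncp(single)), 0)
  expect_equal(cna_oscn(single)$value, 0)
  expect_equal(cna_ss(single)$value, 7)    # exactly 10^7 bp

  # adjacent equal-CN segments yield no breakpoint
  flat <- validate_segments(data.frame(
    sample_id = "F", chrom = "1", start = c(1, 1e7 + 1),
    end = c(1e7, 2e7), total_cn = c(2, 2), minor_cn = c(1, 1)))
  expect_true(all(cna_bp10mb(flat, ann)$value == 0))
  expect_equal(cna_cncp(flat)$value, 0)

  # 2,3,2,3,2 oscillating chain scores 3
  osc <- fx$segments[fx$segments$sample_id == "E_osc", ]
  expect_equal(cna_oscn(osc)$value, 3)

  # fully diploid profile: NC50 observes 0 (clamped to NC50[<=2]), no BoChr
  expect_equal(cna_nc50(flat)$value, 0)
  expect_equal(nrow(cna_bochr(flat)), 0)
  fmf <- extract_cna_features(flat, ann, sc)
  expect_equal(fmf[["NC50[<=2]"]], 1)
  expect_equal(sum(fmf[, paste0("BoChr[", 1:23, "]")]), 0)
})

test_that("NC50 needs two of four chromosomes when alteration splits equally", {
  seg <- validate_segments(data.frame(
    sample_id = "Q", chrom = c("1", "2", "3", "4"),
    start = 1, end = 1e7, total_cn = 3, minor_cn = 1))
  expect_equal(cna_nc50(seg)$value, 2)
  # all alteration on a single chromosome needs just that one
  one <- validate_segments(data.frame(
    sample_id = "O", chrom = "1", start = 1, end = 1e7,
    total_cn = 3, minor_cn = 1))
  expect_equal(cna_nc50(one)$value, 1)
})

test_that("X chromosome maps to BoChr index 23", {
  seg <- validate_segments(data.frame(
    sample_id = "S", chrom = "X", start = 1, end = 5e7,
    total_cn = 1, minor_cn = 0))
  expect_equal(cna_bochr(seg)$value, 23)
})

test_that("operators match the brute-force oracle on randomized profiles", {
  toy <- toy_genome()
  set.seed(401)
  for (i in 1:40) {
    seg <- validate_segments(random_profile(sprintf("R%02d", i), toy))
    expect_equal(sort(cna_bp10mb(seg, toy)$value), sort(oracle_bp10mb(seg, toy)))
    expect_equal(sort(cna_bparm(seg, toy)$value), sort(oracle_bparm(seg, toy)))
    expect_equal(sort(cna_cn(seg)$value), sort(oracle_cn(seg)))
    expect_equal(sort(cna_cncp(seg)$value), sort(oracle_cncp(seg)))
    expect_equal(sort(cna_oscn(seg)$value), sort(oracle_oscn(seg)))
    expect_equal(sort(cna_ss(seg)$value), sort(oracle_ss(seg)))
    expect_equal(cna_nc50(seg)$value, oracle_nc50(seg))
    expect_equal(sort(cna_bochr(seg)$value), sort(oracle_bochr(seg)))
  }
})

test_that("conservation invariants hold on simulated profiles", {
  sim <- simulate_profiles(8, 8, seed = 19)
  fm <- extract_cna_features(sim$segments, sim$annotation, sc)
  per_sample <- split(sim$segments, sim$segments$sample_id)
  for (sid in names(per_sample)) {
    seg <- per_sample[[sid]]
    row <- fm[fm$sample_id == sid, ]
    n_seg <- nrow(seg)
    chroms <- unique(seg$chrom)
    n_windows <- sum(ceiling(
      sim$annotation$length[match(chroms, sim$annotation$chrom)] / 1e7))
    sum_feature <- function(f) sum(row[, sc$label[sc$feature == f]])
    expect_equal(sum_feature("CN"), n_seg)
    expect_equal(sum_feature("SS"), n_seg)
    expect_equal(sum_feature("BP10MB"), n_windows)
    expect_equal(sum_feature("BPArm"), 2 * length(chroms))
    expect_equal(sum_feature("CNCP"),
                 sum(pmax(0, table(seg$chrom) - 1)))
    expect_equal(sum_feature("BoChr"), sum(seg$total_cn != 2))
    expect_equal(sum_feature("NC50"), 1)
  }
})

test_that("extraction is order-invariant and deterministic", {
  sim <- simulate_profiles(3, 3, seed = 5)
  fm1 <- extract_cna_features(sim$segments, sim$annotation, sc)
  shuffled <- sim$segments[rev(seq_len(nrow(sim$segments))), ]
  fm2 <- extract_cna_features(shuffled, sim$annotation, sc)
  expect_equal(dplyr::arrange(fm1, sample_id), dplyr::arrange(fm2, sample_id))
})

test_that("whole-window translation leaves non-positional features unchanged", {
  big <- toy_genome(lengths = c(`1` = 200e6), centromere_start = 90e6,
                    centromere_end = 95e6)
  base <- validate_segments(data.frame(
    sample_id = "S", chrom = "1", start = c(1e6, 2.2e7, 3.7e7),
    end = c(2e7, 3e7, 5e7), total_cn = c(2, 4, 1), minor_cn = c(1, 1, 0)))
  shifted <- dplyr::mutate(base, start = start + 3e7, end = end + 3e7)
  for (op in list(cna_cn, cna_cncp, cna_oscn, cna_ss, cna_nc50, cna_bochr)) {
    expect_equal(sort(op(base)$value), sort(op(shifted)$value))
  }
})
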