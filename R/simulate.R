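#' Parameters of the synthetic segment-profile simulator
#'
#' The two classes differ in the ways the classifier exploits in real
#' cohorts: HRD genomes carry a high density of isolated breakpoints
#' (enriching 10-Mb windows with exactly one break and 10-100 Mb segments,
#' i.e. log10 size in (7, 8]), oscillating copy-number chains and frequent
#' LOH; HRP genomes are mostly diploid with few large events.
#'
#' @param bp_per_arm Named vector: mean breakpoints per chromosome arm for
#'   each class (negative-binomial mean; defaults HRD 4.0, HRP 0.7).
#' @param bp_dispersion Negative-binomial size parameter (common to both
#'   classes).
#' @param size_shape Gamma shape for the segment-length weights within an
#'   arm; larger values give more even splits. The HRD default (8) makes
#'   breakpoint-dense arms fall apart into similar 10-100 Mb pieces.
#' @param min_spacing Per-class soft minimum segment size in bp: an arm
#'   never receives more breakpoints than `arm_length / min_spacing`. The
#'   HRD default (12 Mb) is the size-bias mechanism placing HRD segment
#'   mass in the 10-100 Mb (log10 in (7, 8]) range.
#' @param rate_sdlog Per-class standard deviation (log scale) of the
#'   per-sample multiplicative factor on the breakpoint rate. Tumors of a
#'   class differ in overall CNA burden; without this heterogeneity a
#'   single window-count component would separate the classes almost
#'   perfectly, which real cohorts do not show.
#' @param osc_prob Probability that a copy-number transition returns to the
#'   previous state (oscillation) per class.
#' @param loh_prob Probability that an altered segment loses one allele
#'   entirely (minor copy number 0) per class (defaults HRD 0.4, HRP 0.1).
#' @param cnloh_prob Probability of copy-neutral LOH on an unaltered
#'   (total 2) segment per class.
#' @param max_cn Largest total copy number the transition chain can reach.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(bp_per_arm = c(HRD = 4.0, HRP = 0.7),
                       bp_dispersion = 5,
                       size_shape = c(HRD = 8, HRP = 1.5),
                       min_spacing = c(HRD = 12e6, HRP = 3e6),
                       rate_sdlog = c(HRD = 0.5, HRP = 0.5),
                       osc_prob = c(HRD = 0.6, HRP = 0.15),
                       loh_prob = c(HRD = 0.4, HRP = 0.1),
                       cnloh_prob = c(HRD = 0.1, HRP = 0.02),
                       max_cn = 8) {
  p <- list(bp_per_arm = bp_per_arm, bp_dispersion = bp_dispersion,
            size_shape = size_shape, min_spacing = min_spacing,
            rate_sdlog = rate_sdlog, osc_prob = osc_prob,
            loh_prob = loh_prob, cnloh_prob = cnloh_prob,
            max_cn = as.integer(max_cn))
  for (f in c("bp_per_arm", "size_shape", "min_spacing", "rate_sdlog",
              "osc_prob", "loh_prob", "cnloh_prob")) {
    stopifnot(all(c("HRD", "HRP") %in% names(p[[f]])), all(p[[f]] >= 0))
  }
  stopifnot(all(p$osc_prob <= 1), all(p$loh_prob <= 1),
            all(p$cnloh_prob <= 1), p$bp_dispersion > 0, p$max_cn >= 2)
  structure(p, class = "sim_params")
}

# next total CN given current and previous state: oscillate back with the
# class's probability, otherwise a near-diploid-biased draw != current
next_cn <- function(current, previous, osc_p, max_cn) {
  if (!is.na(previous) && previous != current && stats::runif(1) < osc_p) {
    return(previous)
  }
  states <- setdiff(0:max_cn, current)
  w <- exp(-abs(states - 2) / 1.5)
  sample(states, 1, prob = w)
}

simulate_arm <- function(arm_start, arm_end, start_cn, cls, params,
                         rate_factor = 1) {
  arm_len <- arm_end - arm_start + 1
  k <- stats::rnbinom(1, size = params$bp_dispersion,
                      mu = rate_factor * params$bp_per_arm[[cls]])
  # size bias: cap breakpoints so pieces average >= the class's spacing
  k <- min(k, floor(arm_len / params$min_spacing[[cls]]))
  w <- stats::rgamma(k + 1, shape = params$size_shape[[cls]], rate = 1)
  bounds <- arm_start - 1 + round(arm_len * cumsum(w) / sum(w))
  bounds[k + 1] <- arm_end
  starts <- c(arm_start, utils::head(bounds, -1) + 1)
  keep <- bounds >= starts            # drop zero-length rounding artefacts
  starts <- starts[keep]; ends <- bounds[keep]
  cn <- numeric(length(starts))
  prev <- NA_real_
  cur <- start_cn
  for (i in seq_along(cn)) {
    if (i > 1) {
      nxt <- next_cn(cur, prev, params$osc_prob[[cls]], params$max_cn)
      prev <- cur; cur <- nxt
    }
    cn[i] <- cur
  }
  tibble::tibble(start = starts, end = ends, total_cn = cn)
}

#' Simulate labeled HRD/HRP segment profiles
#'
#' For every sample and chromosome arm the simulator draws a
#' negative-binomial breakpoint count, splits the arm at
#' gamma-weighted positions, walks a Markov chain over total copy numbers
#' 0..`max_cn` starting from the diploid 2 at each chromosome (adjacent
#' segments always differ within an arm, so every junction is a true
#' breakpoint), and assigns minor copy numbers with class-specific LOH
#' inflation. Fully deterministic per seed.
#'
#' @param n_hrd,n_hrp Number of profiles per class.
#' @param params A [sim_params()] list.
#' @param annotation Genome to tile (default the toy genome).
#' @param seed Integer seed.
#' @return A list: `segments` (one validated tibble for all samples),
#'   `labels` (`sample_id`, `label`), `annotation`.
#' @examples
#' sim <- simulate_profiles(n_hrd = 3, n_hrp = 3, seed = 1)
#' dplyr::count(sim$segments, sample_id)
#' @export
simulate_profiles <- function(n_hrd, n_hrp, params = sim_params(),
                              annotation = load_genome_annotation("toy"),
                              seed = 1L) {
  stopifnot(inherits(params, "sim_params"), n_hrd >= 0, n_hrp >= 0)
  if (nrow(annotation) == 0 || any(annotation$length <= 0)) {
    stop("zero-length genome", call. = FALSE)
  }
  ids <- c(sprintf("HRD_%03d", seq_len(n_hrd)),
           sprintf("HRP_%03d", seq_len(n_hrp)))
  cls <- rep(c("HRD", "HRP"), c(n_hrd, n_hrp))
  arms <- genome_arms(annotation)
  segments <- with_seed(seed, {
    purrr::map2(ids, cls, function(sid, cl) {
      sdl <- params$rate_sdlog[[cl]]
      rf <- stats::rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
      per_chrom <- purrr::map(split(arms, factor(arms$chrom,
                                                 unique(arms$chrom))),
                              function(a) {
        # chain starts at 2 at the chromosome start and runs across the
        # centromere so junction counts equal the drawn breakpoint counts
        p <- simulate_arm(a$arm_start[a$arm == "p"],
                          a$arm_end[a$arm == "p"], 2, cl, params, rf)
        q <- simulate_arm(a$arm_start[a$arm == "q"], a$arm_end[a$arm == "q"],
                          p$total_cn[nrow(p)], cl, params, rf)
        dplyr::bind_rows(p, q) |>
          dplyr::mutate(chrom = a$chrom[1])
      })
      seg <- dplyr::bind_rows(per_chrom)
      altered <- seg$total_cn != 2
      minor <- integer(nrow(seg))
      u <- stats::runif(nrow(seg))
      minor[!altered] <- ifelse(u[!altered] < params$cnloh_prob[[cl]], 0L, 1L)
      if (any(altered)) {
        lo <- u[altered] < params$loh_prob[[cl]]
        half <- floor(seg$total_cn[altered] / 2)
        minor[altered] <- ifelse(
          lo, 0L,
          floor(stats::runif(sum(altered)) * (half + 1)))
      }
      seg$minor_cn <- pmin(minor, seg$total_cn)
      seg$sample_id <- sid
      seg
    }) |> dplyr::bind_rows()
  })
  list(
    segments = validate_segments(segments),
    labels = tibble::tibble(sample_id = ids, label = cls),
    annotation = annotation
  )
}

#' Hand-countable fixture profiles
#'
#' Small named profiles whose feature values can be enumerated by hand,
#' used throughout the documentation and tests:
#'
#' * `T1` — chromosome 1 (30 Mb, centromere 14-16 Mb): three 10-Mb
#'   segments with copy numbers 2, 3, 2;
#' * `T2` — chromosome 2 (100 Mb, centromere 48-52 Mb): a 20-Mb LOH
#'   segment (total 1, minor 0) followed by balanced 2+1 segments; yields
#'   genomic-scar counts (LOH, TAI, LST) = (1, 1, 1);
#' * `E_osc` — a five-segment 2,3,2,3,2 oscillating chain;
#' * `E_bound` — a single segment of exactly 10^7 bp (log10 size 7.0,
#'   exercising the closed upper bound of `SS[>6 & <=7]`);
#' * `E_cent` — an allelic-imbalance segment spanning the centromere.
#'
#' @return A list: `segments` (all fixtures in one tibble), `annotation`
#'   (chromosome 1: 30 Mb, centromere 14-16 Mb; chromosome 2: 100 Mb,
#'   centromere 48-52 Mb).
#' @export
fixture_profiles <- function() {
  ann <- toy_genome(lengths = c(`1` = 30e6, `2` = 100e6),
                    centromere_start = c(14e6, 48e6),
                    centromere_end = c(16e6, 52e6))
  seg <- function(sample_id, chrom, start, end, total_cn, minor_cn) {
    tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                   end = end, total_cn = total_cn, minor_cn = minor_cn)
  }
  segments <- dplyr::bind_rows(
    seg("T1", "1", c(1, 1e7 + 1, 2e7 + 1), c(1e7, 2e7, 3e7),
        c(2, 3, 2), c(1, 1, 1)),
    seg("T2", "2", c(1, 2e7 + 1, 5.2e7), c(2e7, 4.8e7, 1e8),
        c(1, 2, 2), c(0, 1, 1)),
    seg("E_osc", "1", c(1, 2e6 + 1, 4e6 + 1, 6e6 + 1, 8e6 + 1),
        c(2e6, 4e6, 6e6, 8e6, 1e7), c(2, 3, 2, 3, 2), c(1, 1, 1, 1, 1)),
    seg("E_bound", "1", 1, 1e7, 3, 1),
    seg("E_cent", "2", c(1, 4e7 + 1, 6e7 + 1), c(4e7, 6e7, 1e8),
        c(2, 3, 2), c(1, 0, 1))
  )
  list(segments = validate_segments(segments), annotation = ann)
}
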