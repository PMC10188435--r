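# Brute-force reference implementations of the eight feature operators,
# written as plain per-profile loops, deliberately independent of the
# package's vectorized code paths. Each takes one sample's segments
# (a data frame sorted by chrom/start) and returns the multiset of
# observations as an unsorted numeric vector.

oracle_breakpoints <- function(seg) {
  out <- data.frame(chrom = character(0), pos = numeric(0))
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) < 2) next
    for (i in 2:nrow(s)) {
      if (s$total_cn[i] != s$total_cn[i - 1]) {
        out <- rbind(out, data.frame(chrom = ch, pos = s$start[i]))
      }
    }
  }
  out
}

oracle_bp10mb <- function(seg, ann, window = 1e7) {
  bp <- oracle_breakpoints(seg)
  obs <- numeric(0)
  for (ch in unique(seg$chrom)) {
    len <- ann$length[ann$chrom == ch]
    n_win <- ceiling(len / window)
    for (w in seq_len(n_win)) {
      lo <- (w - 1) * window + 1
      hi <- w * window
      obs <- c(obs, sum(bp$chrom == ch & bp$pos >= lo & bp$pos <= hi))
    }
  }
  obs
}

oracle_bparm <- function(seg, ann) {
  bp <- oracle_breakpoints(seg)
  obs <- numeric(0)
  for (ch in unique(seg$chrom)) {
    cs <- ann$centromere_start[ann$chrom == ch]
    here <- bp[bp$chrom == ch, ]
    obs <- c(obs, sum(here$pos <= cs), sum(here$pos > cs))
  }
  obs
}

oracle_cn <- function(seg) seg$total_cn

oracle_cncp <- function(seg) {
  obs <- numeric(0)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) < 2) next
    for (i in 2:nrow(s)) obs <- c(obs, abs(s$total_cn[i] - s$total_cn[i - 1]))
  }
  obs
}

oracle_oscn <- function(seg) {
  obs <- numeric(0)
  for (ch in unique(seg$chrom)) {
    cn <- seg$total_cn[seg$chrom == ch]
    # walk the sequence; count consecutive "returns to the state two back"
    chains <- numeric(0)
    run_len <- 0
    k <- 3
    while (k <= length(cn)) {
      if (cn[k] == cn[k - 2] && cn[k] != cn[k - 1]) {
        run_len <- run_len + 1
      } else if (run_len > 0) {
        chains <- c(chains, run_len)
        run_len <- 0
      }
      k <- k + 1
    }
    if (run_len > 0) chains <- c(chains, run_len)
    obs <- c(obs, if (length(chains) == 0) 0 else chains)
  }
  obs
}

oracle_ss <- function(seg) log10(seg$end - seg$start + 1)

oracle_nc50 <- function(seg) {
  alt <- seg[seg$total_cn != 2, ]
  if (nrow(alt) == 0) return(0)
  totals <- c()
  for (ch in unique(alt$chrom)) {
    totals[ch] <- sum(alt$end[alt$chrom == ch] - alt$start[alt$chrom == ch] + 1)
  }
  totals <- sort(totals, decreasing = TRUE)
  acc <- 0
  for (i in seq_along(totals)) {
    acc <- acc + totals[i]
    if (acc >= 0.5 * sum(totals)) return(i)
  }
}

oracle_bochr <- function(seg) {
  alt <- seg[seg$total_cn != 2, ]
  if (nrow(alt) == 0) return(numeric(0))
  idx <- match(alt$chrom, c(as.character(1:22), "X"))
  idx[is.na(idx)] <- as.integer(alt$chrom[is.na(idx)])
  idx
}

# random toy profiles for oracle-equivalence tests: <= 5 chromosomes,
# <= 12 segments each, gaps allowed, adjacent segments may share a CN
random_profile <- function(sample_id, ann) {
  seg <- NULL
  for (ch in ann$chrom) {
    n <- sample(0:12, 1)
    if (n == 0) next
    len <- ann$length[ann$chrom == ch]
    cuts <- sort(sample(seq(1e5, len - 1e5, by = 1e5), n))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, len)
    keep <- sort(sample(seq_len(n + 1), n))
    cn <- sample(0:10, n, replace = TRUE)
    minor <- pmin(sample(0:3, n, replace = TRUE), floor(cn / 2))
    seg <- rbind(seg, data.frame(
      sample_id = sample_id, chrom = ch,
      start = starts[keep], end = ends[keep],
      total_cn = cn, minor_cn = minor
    ))
  }
  if (is.null(seg)) {
    seg <- data.frame(sample_id = sample_id, chrom = ann$chrom[1],
                      start = 1, end = ann$length[1],
                      total_cn = 2, minor_cn = 1)
  }
  seg
}

with_seed_shuffle <- function(seed, x) {
  set.seed(seed)
  sample(x)
}

# feature-matrix row counts expected from the oracle observations
oracle_feature_counts <- function(seg, ann, scheme) {
  obs <- list(
    BP10MB = oracle_bp10mb(seg, ann), BPArm = oracle_bparm(seg, ann),
    CN = oracle_cn(seg), CNCP = oracle_cncp(seg), OsCN = oracle_oscn(seg),
    SS = oracle_ss(seg), NC50 = oracle_nc50(seg), BoChr = oracle_bochr(seg)
  )
  counts <- integer(nrow(scheme))
  names(counts) <- scheme$label
  for (f in names(obs)) {
    bins <- scheme[scheme$feature == f, ]
    for (v in obs[[f]]) {
      hit <- which(v <= bins$upper)[1]
      counts[bins$label[hit]] <- counts[bins$label[hit]] + 1L
    }
  }
  counts
}
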