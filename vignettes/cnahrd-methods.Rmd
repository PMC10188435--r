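---
title: "Methods: copy-number features and boosted HRD classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number features and boosted HRD classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnahrd)
```

## The problem

Homologous recombination deficiency (HRD) leaves a characteristic imprint
on a tumor genome: unable to repair double-strand breaks faithfully, the
genome accumulates many scattered copy-number changes. Because
allele-specific copy-number profiles can be derived from cheap assays
(shallow WGS, SNP arrays, gene panels), a classifier reading HRD status
off segment profiles is clinically attractive: HRD tumors respond to PARP
inhibition and platinum chemotherapy.

`cnahrd` implements that reading in three layers:

1. **Feature quantification** — eight fundamental distributions summarise
   a segment profile, binned into an 80-component integer count vector.
2. **Classification** — a gradient-boosted stump ensemble maps the count
   vector to a probability of HRD, dichotomised at 0.2.
3. **Comparators** — the classical genomic-scar scores (LOH, TAI, LST and
   their sum, thresholded at 42) for benchmarking.

A synthetic profile simulator generates labeled cohorts with the same
class structure, so the entire pipeline is testable without any external
data.

## Segment profiles and genome geometry

A profile is a table of segments: `sample_id`, `chrom` (1–22, X),
1-based closed coordinates `start`/`end`, integer `total_cn`, and
optionally `minor_cn` (the smaller allele). On ingest, fractional copy
numbers are rounded half-up, `chr` prefixes are stripped, the minor
allele is forced to be the smaller one, and overlapping segments are
rejected. Chromosome Y and mitochondrial segments are dropped with a
warning — the component scheme spans chromosomes 1–22 and X only.
X-chromosome segments are kept as reported; no ploidy adjustment for male
samples is attempted. Gaps between consecutive segments are permitted and
never imputed: all operators act on observed segments only.

Arm and telomere geometry derive from the genome annotation: the p-arm is
`[1, centromere_start]`, the q-arm `[centromere_end, length]`. Packaged
tables cover hg19 and hg38; `toy_genome()` provides a five-chromosome
30–150 Mb genome whose feature counts can be checked by hand.

## The eight feature distributions

A *breakpoint* is the junction between two adjacent observed segments on
the same chromosome with differing total copy number, positioned at the
start of the downstream segment. Junctions across an uncovered gap count
when the copy number changes; equal-CN junctions never count.

| Feature | Observation unit | Value |
|---------|-----------------|-------|
| BP10MB | each 10-Mb window | breakpoints in the window |
| BPArm  | each chromosome arm | breakpoints on the arm |
| CN     | each segment | total copy number |
| CNCP   | each adjacent pair | absolute copy-number change |
| OsCN   | each oscillating chain (or chromosome without one) | chain length |
| SS     | each segment | log10 segment size |
| NC50   | the sample | minimal chromosomes carrying half the altered length |
| BoChr  | each altered segment | chromosome index (X = 23) |

Conventions worth stating because they are not forced by the definitions:

* Windows tile the whole annotated chromosome from position 1; the last,
  shorter window still contributes an observation, and zero-count windows
  are observed, so the number of BP10MB observations is fixed by the
  annotation. Only chromosomes covered by the profile contribute.
* Breakpoints inside the centromere interval are assigned to the q-arm.
  Both arms of every covered chromosome contribute observations.
* An oscillating chain is a maximal run with `cn[i] == cn[i-2]` and
  `cn[i] != cn[i-1]`; its length is the run's segment count minus 2, so
  the minimal A,B,A pattern scores 1. Chromosomes without a chain
  contribute a 0 — this is what makes the `OsCN[0]` component attainable.
* "Altered" for NC50 and BoChr means `total_cn != 2`, an absolute diploid
  baseline rather than a sample-ploidy-relative one (configurable via
  `baseline_cn`).

## The 80-component scheme

Each feature's value support is cut into bins: BP10MB 7, BPArm 12, CN 10,
CNCP 9, OsCN 6, NC50 7, SS 6, BoChr 23 — 80 components in all. Bins are
left-open/right-closed, as the label `SS[>7 & <=8]` dictates: a segment
of exactly 10^7 bp (log10 = 7) falls in `SS[>6 & <=7]`, and 10–100 Mb
segments fall in `SS[>7 & <=8]`. The extreme bins of every feature are
open-ended, so out-of-range values clamp into them and every observation
maps to exactly one component. The scheme ships as a TSV data file
(`inst/extdata/component_scheme.tsv`) so it can be corrected without code
changes; within each feature the counts always sum to the feature's
observation count, an invariant the tests enforce on every simulated
profile.

## Genomic-scar comparators

The three scar scores are defined operationally on the merged segment
profile:

* **LOH**: merged regions with `minor_cn = 0` and `total_cn >= 1` longer
  than 15 Mb, excluding regions spanning the whole chromosome.
* **TAI**: maximal allelic-imbalance regions (`minor != total - minor`)
  whose boundary reaches the first or last covered base of the chromosome
  without crossing the centromere. Segment tables rarely reach the
  physical chromosome ends, so "telomere" means the first/last covered
  base.
* **LST**: after iteratively smoothing away segments shorter than 3 Mb
  (absorbing equal-CN neighbours), copy-number transitions flanked on
  both sides by regions of at least 10 Mb with a gap under 3 Mb, counted
  per arm. Probe-level filters from SNP-array implementations are out of
  scope — segment tables carry no probe counts.

The HRD score is the plain sum; `>= 42` calls HRD. All thresholds are
arguments. These scores are comparators for the boosted classifier, not
the headline method, and the package makes no claim of exact concordance
with any particular SNP-array implementation of them.

## The four-step training procedure

The classifier is a Bernoulli-loss gradient-boosted ensemble of stumps
(`interaction_depth = 1`; depth is configurable but stumps are the
default of the boosting tradition this follows). Defaults: learning rate
0.01, tree budget 6000, bagging fraction 0.8.

1. *(Optional)* restrict to components that differ between classes
   (two-sided Wilcoxon rank-sum, BH-adjusted q < 0.05). Off by default:
   which components pass is a property of a cohort, not of the method.
2. Pick the tree count minimizing 10-fold cross-validated Bernoulli
   deviance, `-2 mean(y log p + (1-y) log(1-p))`, over 1..6000 trees.
   Folds are stratified and the fold count is capped at the
   minority-class size.
3. Estimate each component's relative influence — per-split loss
   improvement averaged over the trees using it, normalized to sum
   to 100 — as the mean over 500 Monte-Carlo refits on stratified 80%
   subsamples. Keep the top 10; ties break by canonical scheme order for
   determinism.
4. Re-tune the tree count on the 10 retained components and fit the
   final ensemble.

Scores are probabilities in [0, 1]; the HRD call is `score >= 0.2`, with
an inclusive boundary — conventional for a risk flag, and stated here
because the choice is otherwise arbitrary. The fitted ensemble is backed
by xgboost; every stochastic step (folds, bagging, subsampling) is seeded
from the single `seed` hyperparameter, and a fitted model serializes to a
single JSON bundle that restores with bit-identical scores.

Numerical notes: the CV deviance curve averages per-fold out-of-fold
logloss per tree count (the standard CV curve); single-class label sets,
non-finite features and scoring data lacking a model column are hard
errors rather than silent repairs.

## Evaluation

AUC uses the Mann–Whitney formulation with half credit for ties, making
it exactly the concordance probability and invariant under monotone
transforms; PR-AUC integrates the right-continuous step precision–recall
curve. The Youden cutoff maximizes sensitivity + specificity − 1 over
midpoints between adjacent distinct scores, returning the lowest maximizer
on ties. Single components (counts, e.g. `BP10MB[1]`) can be evaluated as
standalone biomarkers by using the raw count as the score.

## The simulator: what it emulates, and what it does not

`simulate_profiles()` generates the class structure the classifier
exploits:

* **HRD** profiles: ~4 breakpoints per arm (negative binomial, size 5),
  splitting arms into similar pieces (gamma-weighted boundaries, shape 8,
  with at most one breakpoint per 12 Mb) — hence many 10-Mb windows with
  exactly one break and many 10–100 Mb segments; oscillating
  copy-number chains (60% return transitions); LOH on 40% of altered
  segments.
* **HRP** profiles: ~0.7 breakpoints per arm, uneven splits (shape 1.5),
  rare oscillation (15%), LOH on 10% of altered segments — mostly diploid
  genomes with few large events.

Copy numbers follow a Markov chain over 0..8 starting at 2 at each
chromosome start and running across the centromere, so every junction is
a true copy-number change and per-arm junction counts equal the drawn
breakpoint counts. Each sample carries a lognormal factor (sdlog 0.5) on
its breakpoint rate: tumors within a class differ in overall CNA burden,
and without this heterogeneity a single window-count component separates
the classes almost perfectly — a degenerate geometry real cohorts do not
show, under which greedy stumps concentrate all influence on one
component. Minor alleles are uniform on `[0, floor(total/2)]` outside the
LOH events; diploid segments are heterozygous except for rare
copy-neutral LOH (10% HRD, 2% HRP).

The simulator runs on the toy genome by default (five chromosomes,
30–150 Mb, hand-checkable) and on hg19/hg38 geometry if asked. It does
**not** attempt realistic mutational processes: no clonal mixtures, no
replication-timing or GC covariates, no platform noise, no focal
amplicon structure. Passing the recovery experiment therefore shows that
the training procedure finds planted class differences of realistic
shape and magnitude — it does not certify performance on real cohorts,
which depends on label quality and assay noise the simulator does not
model.

## Problem sizes and reproducibility

The package's own validation experiments use cohorts of 150 + 150
training and 50 + 50 held-out profiles on the toy genome, the full
four-step procedure with the default 6000-tree budget, and a
Monte-Carlo budget of 50 repeats — large enough for stable influence
ranking at these effect sizes while keeping a full run in minutes on one
CPU. Under these conditions the held-out AUC is ≈ 0.97–0.98, the
selected top-10 contains `BP10MB[1]` and `SS[>7 & <=8]` (they rank first
and second), and a label-shuffled null control (mean over three
shuffles, reducing Monte-Carlo noise in a single-shuffle AUC) sits near
0.5. `scripts/acceptance.R` re-runs exactly this experiment from scratch.

## Known limitations

* The component bin edges follow the canonical published scheme; a
  different upstream segmentation (e.g. very fragmented shallow-WGS
  profiles) may warrant a recalibrated scheme, which can be supplied as
  a TSV without code changes.
* The scar-score implementations are segment-level; implementations that
  use probe counts or ploidy-relative baselines will differ on real
  arrays.
* Training labels are an input. Deriving HRD/HRP truth from variant
  calls (biallelic BRCA1/2 inactivation and friends) is out of scope.
* The Wilcoxon pre-filter (step 1) is available but off by default; on
  small cohorts it can drop weakly informative components that the
  influence ranking would have kept.
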