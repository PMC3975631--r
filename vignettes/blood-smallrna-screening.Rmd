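---
title: "Screening blood small RNAs for seminoma metastasis status: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening blood small RNAs for seminoma metastasis status: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seminomiR)
```

## The problem

Seminoma is the most common histological subtype of testicular cancer, and
most patients present without visible metastasis at primary staging. A
substantial fraction of clinical stage I patients nevertheless carry occult
metastases that only become apparent as relapse during follow-up, while CT
staging detects the lymphogen (lymph-node) metastasized cases. A blood-borne
molecular marker that separates metastasized (lymphogen or occult) from
truly non-metastasized patients at the time of primary diagnosis would spare
patients either overtreatment or intensive surveillance.

seminomiR implements a complete, testable small RNA sequencing analysis for
a three-group design — non-metastasized (reference), lymphogen metastasized
and occult metastasized, five patients per group — profiled in peripheral
whole blood:

1. **Read processing**: 3' adapter trimming, collapsing of trimmed inserts
   into unique *tags*, annotation against a mature miRNA / ncRNA reference,
   and per-library accounting (total reads, reads after trimming, annotated
   reads, tags, annotated tags).
2. **Screening**: a candidate filter (read depth and fold change against the
   non-metastasized reference), a univariate Firth-penalized logistic
   regression per small RNA for each of three comparisons (lymphogen,
   occult, combined), and overlap statistics of the three candidate lists.
3. **Pair separation**: an exhaustive evaluation of all candidate pairs for
   *complete separation* — a line in the two features' expression plane that
   classifies every sample correctly.
4. **Cohort reporting** and a synthetic-data generator that emulates the
   study design so every stage is testable without any external download.

## Read processing

A read is kept iff a prefix of the 3' adapter (at least `min_overlap = 7`
bases, at most `max_mismatch = 1` mismatches) matches at some position
through the read's 3' end, or the full adapter occurs internally; the insert
is everything before the leftmost such match. Reads without an adapter hit
are discarded (`no_adapter`), as are inserts shorter than 15 nt
(`too_short`; an insert of exactly 15 nt is kept). The three outcomes
partition every read set — `kept + no_adapter + too_short = total` is an
invariant the tests assert unconditionally. The overlap/mismatch defaults
are conventional small-RNA trimming settings; no published parameter set
exists for this design, so read-level concordance with any particular
commercial trimmer is not claimed.

Kept inserts are collapsed into unique tags. A tag is assigned to a
reference entry if it equals the entry's sequence or differs from it only by
up to `end_tolerance = 2` missing or additional 3' bases — the usual
allowance for 3'-end length heterogeneity of mature small RNAs (a deliberate
minimal isomiR model; 5' variation and internal edits are out of scope).
When entries of both classes match, miRNA entries outrank ncRNA entries,
reflecting that mature miRNAs are the primary annotation universe.
Ambiguous tags (more than one entry of the winning class) are excluded from
the count matrix but tallied in the library statistics: fractional
assignment schemes are not deterministic across implementations, and
exclusion keeps the quantification reproducible. Feature identity is the
reference entry id, so distinct precursors of the same mature sequence
remain distinct rows.

## Normalization and candidate filter

Library sizes in blood small-RNA data vary several-fold, so all expression
comparisons are made on counts per million (CPM) over annotated small-RNA
reads — the minimal normalization consistent with read-count thresholds.
The candidate filter for a comparison retains a small RNA iff

* its mean raw count is at least `min_reads = 50` in at least one of the
  two compared groups (the least restrictive reading of a "50 reads"
  threshold that still uses the comparison structure), and
* the ratio of CPM group means (target over reference, each mean with a
  pseudocount of 0.5) is at least 2 or at most 1/2.

The filter is applied per comparison against the non-metastasized
reference. Raising either threshold can only shrink the filtered set; the
tests assert this monotonicity.

## Firth-penalized logistic screening

Each filtered feature is tested in a one-predictor logistic regression of
group membership (reference = 0, target = 1) on `log2(CPM + 1)`. With five
samples per class, complete separation of a predictor is common, and plain
maximum likelihood then diverges to infinite odds ratios. The package
therefore maximizes the Jeffreys-penalized likelihood (Firth's bias
reduction),

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det I(\beta),$$

which has a finite maximizer for every configuration. The p-value is a
penalized likelihood-ratio test of zero slope (the null profile keeps the
penalty of the full design), and the confidence interval is a profile
penalized-likelihood interval — both standard choices for Firth fits. The
fit uses a Newton iteration on the Firth-modified score with step halving
and a quasi-Newton fallback; the profile bounds are found by bracketed root
search on the profile deviance. An independent three-stage dense grid
search over the penalized likelihood, written separately in the test suite,
reproduces the slope to 10^-3 on a completely separated 5-vs-5 instance.

Significance is declared at p ≤ 0.05 without multiple-testing adjustment,
matching the explorative character of a screening design with n = 15; a
Benjamini-Hochberg toggle is available for users who want it. The screen
reports both the expression fold change (CPM-mean ratio) and the logistic
odds ratio per log2 unit with its profile interval; they are different
quantities and are labeled unambiguously rather than conflated.

## Complete separation of feature pairs

The pair search evaluates every unordered pair of candidates once, in the
plane spanned by the two features' `log2(CPM + 1)` values. "Complete
separation" is interpreted strictly: some line must classify every training
sample correctly with no sample on the line. This is a geometric fact about
the two point sets, so the primary decision procedure is exact geometry
rather than an iterative classifier: the classes are strictly separable iff
their convex hulls are disjoint, decided via monotone-chain hulls, the
hull-to-hull distance and containment checks. The reported `margin` is the
hull-to-hull distance — the widest empty band between the classes. A linear
soft-margin SVM with cost 10^6 on standardized coordinates is run alongside
as a cross-check (training accuracy 100% iff separable; because emulating a
hard margin needs a penalty of order inverse squared margin, the cost is
escalated once before a near-degenerate instance is declared
non-separable); the two routes
agreed on every instance ever tested, and disagreements would be recorded
in the pair table's attributes. A brute-force third oracle (enumeration of
candidate lines through point pairs, perturbed both ways) backs both in the
test suite.

Two structural properties follow from the geometry and are asserted on
synthetic runs: every pair separating the combined comparison (10 vs 5)
also separates each subtype comparison (whose point sets are subsets with
labels preserved), and a feature that separates alone in 1-D makes all its
pairs separable in 2-D. By default pairs are drawn from the comparison's
significant-candidate list (`pool = "significant"`); `pool = "filtered"`
widens the pool to all filter-passing features.

## The synthetic-data generator

The generator emulates the study conditions — 3 groups × 5 samples of blood
small RNA — at desk scale, with known ground truth:

* **Reference**: random miRNA-like entries (18-25 nt) and ENST-style
  ncRNA entries (30-120 nt). Two rejection rules make the library a clean
  quantification target: no sequence (nor any 3'-truncation by up to 2 nt,
  once the adapter is appended) produces a spurious adapter hit at the
  default trimming stringency, and no two sequences share their first 13
  bases, so every tag within the 3' tolerance resolves uniquely.
* **Counts**: negative binomial per feature and sample, with a log-normal
  baseline across features (`baseline_log_sd = 1.5`), renormalized per
  sample so the expected column sum equals the library size. Defaults:
  `library_size_mean = 1e5` annotated reads (the study's absolute 10^7
  depth is not emulated; all statistics of interest are scale-free),
  `library_size_cv = 0.3`, and `dispersion = 0.4` (biological CV ≈ 0.63),
  reflecting the large between-subject variability of circulating small
  RNAs in human cohorts. Truth features have their baseline multiplied by
  `fold_change` in the affected groups; an optional `baseline_mean` pins an
  implanted biomarker's expected raw count, mirroring that real candidates
  are by construction quantifiable (all pass the 50-read filter).
* **Reads**: per feature and sample, `count` reads consisting of the mature
  sequence with up to ±2 nt of 3'-end jitter followed by the adapter, plus
  three noise classes: junk reads without adapter (default 25% of the
  total), short-insert reads (2%), and clean inserts not drawn from the
  reference (13%). These defaults place the trimming survival at 73% and
  the annotated fraction of trimmed reads near 82%, inside the ranges
  reported for this kind of blood small-RNA library. Every emitted read is
  verified against the default trimmer (random components are redrawn on
  the rare spurious adapter hit), so the read classes are exact and
  quantifying noise-free reads reproduces the simulated count matrix
  *exactly* — an end-to-end identity the acceptance tests assert.
  Qualities are constant placeholders; no stage consumes them. Base-space
  sequences only; colorspace chemistry, sequencing error and genome
  alignment are out of scope.

What the generator deliberately does not model: correlated features,
compositional effects beyond renormalization, batch structure, GC or length
bias, and 5' heterogeneity. Green tests on synthetic data therefore
demonstrate the correctness and calibration of the *procedures*, not the
biological validity of any particular candidate list from real data.

## Numerical and design choices

* **Rounding** of displayed summaries is half away from zero (one decimal
  for cohort tables, nearest integer for overlap percentages); full
  precision is carried internally and display rounding never feeds back
  into computation.
* **Type-I calibration** of the screen is checked under a global-null
  simulation (no truth features, 5 vs 5, 2000 features) among
  *depth-filtered* features (mean ≥ 50 reads): the fraction with p ≤ 0.05
  must lie in [0.01, 0.12]; measured values sit near the nominal 0.04-0.05.
  Conditioning additionally on an observed two-fold change and then testing
  the same contrast is a selection effect that no test calibration can
  absorb — the fold filter is part of candidate *discovery*, and its
  false-positive cost at this sample size is the reason the screen's
  candidates require independent validation.
* **Power**: an implanted fold-6 pair at `baseline_mean = 200` and
  dispersion 0.05 is recovered as significant and separating in ≥ 90% of
  200 replicates (measured: ~100%).
* **Degenerate inputs**: constant predictors return odds ratio 1 with p = 1;
  all-identical points with mixed labels are never separable; empty read
  sets produce empty tag tables with zeroed accounting.
* **Problem sizes** used by the automated checks (200 features × 200
  replicates for recovery, 2000 features for calibration, 500 random
  instances for the separability cross-oracle) were chosen to give stable
  estimates at interactive run times.
* **Determinism**: every stochastic component consumes an explicit seed;
  fixed seeds give bitwise-identical count matrices, FASTA output and
  report bundles (FASTQ determinism is content-level; gzip containers are
  not byte-compared).

## Known limitations

* The trimming/annotation parameters of the original instrument software
  are unpublished; this package's defaults are field conventions, and exact
  read-level concordance with the original processing is neither claimed
  nor checkable.
* The published per-comparison candidate counts, p-values and
  separating-pair counts (891/668/87) are functions of the unpublished
  sequencing data and cannot be recomputed; the package reproduces the
  quantities derivable from printed inputs (cohort summaries, candidate-list
  overlaps) exactly, and substitutes property-based checks (cross-oracle
  agreement, restriction, recovery, calibration, determinism) for the rest.
* With five samples per group, complete separation in two dimensions is a
  weak criterion — many pairs separate any such dataset. The package
  reports training-set separation only, as designed; it deliberately
  implements no cross-validation or generalization claim.

## A worked example

```{r example, eval = FALSE}
library(seminomiR)

truth <- data.frame(feature_id = c("mir-sim-1", "mir-sim-2"),
                    groups = "lymphogen,occult", fold_change = 6,
                    baseline_mean = 200)
cfg <- simulation_config(n_features = 40, library_size_mean = 2e4,
                         dispersion = 0.05, truth_set = truth, seed = 42)
ref <- generate_reference(32, 8, seed = 42)
sim <- simulate_counts(cfg, ref)

res <- run_pipeline(list(counts = sim$counts, metadata = sim$metadata,
                         out_dir = "report"))
attr(res$screens$combined, "candidates")
subset(res$pairs$combined, separable)
```

The same objects are produced from FASTQ files via `simulate_study()` and
the `fastq_dir`/`reference` config entries, and from the shell via the
script in `inst/scripts/seminomir-cli.R`.
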