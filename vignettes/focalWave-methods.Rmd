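---
title: "Detecting recurrent focal copy-number alterations from WGS read depth"
author: "focalWave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent focal copy-number alterations from WGS read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Somatic copy-number alterations come in two flavors: broad, often
arm-level events involving hundreds of genes, and focal events of
roughly 0.1–3 Mb that are far more informative about driver genes.
Given tumor/normal WGS pairs from many patients, focalWave asks: which
focal regions are altered recurrently, more often than independent
per-patient alteration would explain?

The observed per-bin signal is modeled as `y_i = f(x_i) + e_i`, where
`f` is the true copy-number change at genomic location `x_i` and `e_i`
is noise. `y_i` is the chromosome-normalized log2 depth ratio
`log2((Tumor_i/Tumor_chr)/(Normal_i/Normal_chr))` over 100 bp bins.
Normalizing by per-chromosome totals makes the ratio invariant to
library size; its side effect — a slight downward baseline shift of
chromosomes carrying large gains, mirrored as negative flanking signal
— is real signal under this definition, visible in the worked examples,
and should be kept in mind when interpreting loss calls that flank
strong gains.

Rather than denoising and segmenting each sample, the method isolates
the *high-frequency* component of `y`. The stationary (undecimated,
circular) Haar transform computes, at each level `t` with dilation
`h = 2^(t-1)`,

```
s_t[i] = (s_{t-1}[i] + s_{t-1}[i+h]) / 2      (scaling: neighbor means)
w_t[i] = (s_{t-1}[i] - s_{t-1}[i+h]) / 2      (detail: half-differences)
```

Details are hard-thresholded per level at the universal threshold
`lambda_j = C * sigma_j * sqrt(2 log n_j)`, with the robust noise scale
`sigma_j = median(|w_j|)/0.6745` and `n_j` the number of coefficients in
the level (constant across levels for the stationary transform;
coefficients with `|w| <= lambda_j`, non-strict, are zeroed).
Reconstructing from the thresholded details alone — coarsest scaling set
to zero, branch-averaged (shift-corrected) inverse — yields `y_HIGH`,
which measures each bin's difference from its neighborhood up to
`2^(J-M)` bins. Under pure noise no coefficient survives the threshold
at C = 2 and `y_HIGH` is identically zero; a broad event survives only
near its edges; a focal event survives in full.

`y_HIGH` places artifact regions of opposite sign next to every true
change. Each maximal same-sign region of `y_HIGH` is therefore compared
with the log2 ratio over that region (the sign of its sum) and zeroed
whole when they disagree, giving the per-patient signal `ŷ_HIGH`. The
filter operates on regions, not bins: bin-wise filtering would shatter
`ŷ_HIGH` into thousands of single-bin fragments wherever the noisy
ratio flips sign, which contradicts both the intended "remove the
artifact lobe" semantics and the method's characteristically low
segment counts.

Patients are integrated by summation, `ŷ_sum[i] = Σ_p ŷ_HIGH^(p)[i]`:
co-located alterations reinforce; isolated ones stay small. Maximal
same-sign nonzero runs of `ŷ_sum` (never crossing a chromosome) are
grouped when their gaps are at most `d`, subgrouped at gaps at most
`r`, and each group reports its maximum-|score| subgroup as a cluster
(score = sum of `ŷ_sum`; ties go to the leftmost subgroup for
determinism; gaps are measured end-to-start, exclusive, in
concatenated-bin units times the bin size).

## Significance: the permutation null

Under the null hypothesis that patients' alterations are independent,
each patient's maximal nonzero runs are reallocated uniformly at random
within their chromosome's unmasked territory (values kept intact and in
order; a patient's runs may not overlap each other — longest placed
first by rejection sampling, with a sequential random packing fallback
after 1,000 rejections; different patients may overlap). Summing,
run-extraction and clustering are repeated with the observed `d` and
`r` for `B` permutations (default 1,000).

Five p-value schemes compare an observed cluster — always against random
clusters of the same sign, on absolute score:

* **FDC1** — fraction of permutations whose maximum random |score|
  reaches the observed |score|;
* **FDC2** — as FDC1 with each permutation's maximum restricted to
  random clusters no longer than the observed cluster;
* **FDC3** — as FDC2, also requiring no more patients than observed;
* **FDC4** — |score| regressed on length across all pooled same-sign
  random clusters; p = fraction of random clusters whose residual
  reaches the observed residual;
* **FDC5** — as FDC4 with patient count as a second covariate.

FDC1–3 are nested by construction (`p3 <= p2 <= p1`); permutations with
no qualifying random cluster count as non-exceedances, and FDC4/5 are
undefined (NA, with a warning) below three pooled random clusters.
Restricting to per-permutation maxima (rather than pooling) in FDC2/3
keeps them consistent with FDC1; cluster "length" on both sides of the
comparison is the concatenated-bin span times the bin size, so masked
gaps inside a cluster do not inflate it.

## Masking

Two genomic pathologies would otherwise create spurious CNAs. Reference
N gaps (centromeres, heterochromatin) are excised before the transform
by concatenating non-gap bins; every concatenation joint is recorded,
and clusters spanning a joint carry a `spansJunction` flag since wavelet
support can leak across joints (including chromosome boundaries — the
baseline-step lobe at a junction is a known, flagged artifact).

Sparse-mapping stretches are detected from each patient's *normal*
track: the same high-frequency procedure is run on the normal counts,
maximal nonzero runs of the (unfiltered) thresholded signal delimit
candidate segments, and each segment's mean normal reads per bp is
clustered with 1-D 2-means (initialized at the feature minimum and
maximum for determinism; with exactly two segments the nearest-center
assignment is used directly, which is the exact solution; ties go to
the lower class). Segments in the low class at least 3 kb long are
masked, the mask is unioned across patients, and the wavelet pass is
re-run on the cleaned signal. Masking is monotone — bins are never
unmasked. Note the detected segment is the wavelet-support region
around an artifact and is wider than the artifact itself; the 3 kb
floor therefore applies to that support region.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| bin size | 100 | bp | read-count bin width |
| J | 25 (derived for small genomes) | — | `2^J` covers the concatenated genome |
| M | 10 | — | coarsest retained level; `J - M` = 15 levels ≈ 3 MB neighbor scale |
| C | 2.0 | — | threshold multiplier; smaller C keeps more (noisier) structure |
| d | 3e5 | bp | run-grouping gap |
| r | 3e5 | bp | subgrouping gap |
| B | 1000 | — | permutations |
| alpha | 0.1 | — | significance level on the chosen FDC |
| outlier window / quantile | 200 / 0.95 | bp / — | per-base winsorization |
| mask floor | 3000 | bp | minimum low-mapping segment removed |

For genomes smaller than `2^J` bins only the decomposition depth
matters, so `waveletParams(nLevels = 15)` preserves the ~3 MB neighbor
scale regardless of genome size. Segment counts per sample decrease
monotonically as C grows (in practice roughly an order of magnitude
from C = 1 to C = 2 on fractured fixtures), which is the handle for
controlling WGS read-depth artifacts.

## The synthetic cohort generator

`simulationSpec()`/`simulateCohort()` emulate multi-patient binned WGS
read depth: negative-binomial counts (gamma–Poisson, dispersion
`size = 20` by default — WGS depth is overdispersed, and a Poisson model
would make the noise thresholds trivial) around 49.6 (tumor) and 43.7
(normal) reads per 100 bp bin, typical of TCGA-era tumor/normal WGS;
planted focal (≤ 3 Mb) and broad (> 25% of the chromosome) events with
arbitrary carrier sets, multiplying tumor depth by `2^dLog2`; reference
N gaps zeroed in both tracks; optional germline events multiplying both
tracks; optional "fracturing" (piecewise-constant log-normal tumor
depth jitter resampled every 50 kb, sd(log) = 0.25) emulating the
excessive read-depth changes seen in a subset of real tumor WGS; and
sparse-mapping stretches.

Sparse stretches are modeled as strong depth suppression with *unequal*
retention between tumor and normal libraries (defaults 0.04 and 0.15 of
nominal). Fully zeroed bins would be invalid in both tracks and produce
no signal at all; unequal sparse retention is what makes such regions
masquerade as deletions, which is the artifact the masking pass exists
to remove. This is the generator's model of the phenomenon, not a
measured property of any particular dataset.

What the generator does **not** emulate: GC and mappability bias,
replication-timing waves, subclonality and purity dilution, paired-end
artifacts, or real breakpoint microstructure. Passing tests on this
generator therefore demonstrate the machinery's correctness and
statistical behavior under its stated model, not performance on real
tumors.

## Numerical choices

* The average/half-difference Haar normalization follows the method's
  definition rather than the orthonormal convention; the acceptance
  surface is perfect reconstruction of the unthresholded transform
  (≤ 1e-10 on random inputs), which the branch-averaged inverse
  delivers at machine precision.
* The compiled fast path reconstructs `y_HIGH` sparsely: a surviving
  detail `w_t[i]` contributes exactly `+w·2^-t` over the circular block
  `[i, i+h-1]` and `-w·2^-t` over `[i+h, i+2h-1]`, accumulated in a
  difference array and materialized with one cumulative sum. Residue
  below `1e-9 × max|y_HIGH|` is snapped to exact zero in both engines
  (true contributions are orders of magnitude larger), so "nonzero run"
  is well defined; the R reference implementation and the compiled path
  agree to 1e-10 and both are exercised by the tests.
* Signal extension is mirror-reflection to the next power of two;
  the transform is circular on the extended signal and cropped back.
* Winsorization caps values above the type-1 (order-statistic) window
  quantile and iterates to a fixed point (2–3 passes in practice):
  a single pass is not idempotent because capping a spike shifts
  neighboring windows' quantiles.
* Zero tumor or normal counts make a bin invalid (no pseudocounts —
  they would fabricate deletions); invalid bins enter the transform as
  zeros and can never pass the sign filter.
* Hard thresholding is non-strict (`|w| <= lambda` is zeroed), and
  FDC exceedances are non-strict (`>=`), making `p = 0` attainable
  only when no permutation reaches the observed score.

## Problem sizes used in the test suite

Cohort-level checks run on a 3 × 30 Mb genome with 20 patients
(6 carrying a 1 Mb focal gain, Δlog2 = 1, nested in a 20 Mb broad gain,
Δlog2 = 0.3), 50 replicates at B = 200; scheme-nesting runs 20 seeded
5 Mb two-chromosome cohorts; masking regression runs 20 seeded 10 Mb
cohorts of 6 patients; the type-I sanity check runs 20 pure-noise
cohorts of 10 patients on 10 Mb at B = 200. These sizes were chosen to
make the suite's statistical assertions sharp at interactive runtimes;
the per-replicate detection behavior is scale-free in the neighbor
scale, which is held at its genome-scale value (15 levels) throughout.

## Known limitations

* Per-chromosome normalization folds large gains into a genome-wide
  baseline shift on that chromosome; flanking "losses" next to strong
  gains must be interpreted accordingly.
* Wavelet support spreads ±`2^(J-M)` bins around true edges, so cluster
  boundaries overshoot event boundaries by up to the neighbor scale,
  and clusters near concatenation joints can leak across them (flagged
  via `spansJunction`).
* The permutation null preserves per-patient run content but not
  long-range covariance of artifacts shared across patients; shared
  systematic artifacts (e.g. unmasked mappability structure) can
  therefore look recurrent.
* FDC4/5 assume an approximately linear |score|–length relation among
  random clusters; with very few random clusters they are undefined.
* BAF/allele-frequency signals, purity/ploidy, GC correction, and
  arm-level event calling are out of scope.
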