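---
title: "Evaluating decision-support robustness across laboratories and scanners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating decision-support robustness across laboratories and scanners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscrdss)
```

## The system under evaluation

Hirschsprung's disease (HSCR) is a congenital absence of ganglion cells in
the enteric plexuses; its histological diagnosis requires surveying dozens
of slides for ganglion cells and calling the disease only in their
absence. An algorithm-assisted workflow replaces the manual survey: a
detector scores ganglion-cell candidates on whole-slide images with a
confidence $s \in [0,1]$ and presents the top candidates to a pathologist
in up to 12 image sets per case, each of which the pathologist scores on a
1–5 ordinal scale (1 = certainly no ganglion cells, 5 = certainly ganglion
cells).

This package does **not** implement the detector. It implements everything
needed to evaluate such a system's robustness across laboratories and
scanner models: the case-classification rule, the image-set-level error
analysis, colour-distribution comparison, and synthetic generators that
stand in for the (undeposited) clinical data.

## The decision rule

For a case with pathologist scores $p_1,\dots,p_k$ and DSA scores
$s_1,\dots,s_k$ ($1 \le k \le 12$), let $n_5 = \#\{i : p_i = 5\}$ and
$\bar{s}$ the unweighted mean of all $s_i$:

* **positive** (ganglion cells present, non-HSCR) iff $n_5 \ge 2$;
* **negative** (HSCR) iff $n_5 < 2$ and $\bar{s} < 0.6$;
* **in doubt** iff $n_5 < 2$ and $\bar{s} \ge 0.6$ — the case is referred
  to an expert whose call on the presented sets becomes the final label.

Conventions we fixed where the rule's prose leaves room:

* the boundary is inclusive on the in-doubt side ($\bar{s} = 0.6$ refers);
  a pathologist score of 4 never counts toward the positive criterion;
* each image set carries **one** DSA score. Where an upstream system
  scores the individual images inside a set, we take the set's score to be
  its best candidate's score, matching the ranking semantics by which
  sets are presented;
* the mean is over *all* presented sets of the case, unweighted;
* `positive` always means *ganglion cells present*, i.e. non-HSCR; the
  enum names `ganglion_present` / `ganglion_absent` are used everywhere to
  keep the sign convention impossible to invert silently;
* records with missing pathologist scores are rejected, never imputed.

Performance is summarised per stratum by `summarize_cohort()`: case
counts, disease mix, correct/incorrect final calls, referral counts, and
sensitivity among ganglion-present cases both pre-referral (an in-doubt
case counts as not yet correct) and post-referral.

## Image-set discordance and its causes

Complete pathologist/algorithm disagreement is flagged per image set:

* **false negative** — pathologist 5 with DSA score $< 0.3$ (the
  algorithm under-scored a true ganglion cell);
* **false positive** — pathologist 1 with DSA score $> 0.7$.

The cutoffs are strict as printed: scores of exactly 0.3 or 0.7 are
concordant. Rates are percentages of all sets in a stratum, so the
false-positive and false-negative rates add exactly to the total error
rate. Discordant sets may carry causative-factor annotations from the
four-way taxonomy *technical* / *missing sensitivity-specificity* /
*new-abnormal findings* / *unknown*; a set may carry several. Cause
percentages are reported relative to the error-type total (all
false-negative causes of a stratum sum to ~100%), matching how such
tables are conventionally printed. Display rounding uses two decimals for
rates below 1% and one decimal otherwise; stored values keep full
precision.

Error profiles between strata are compared with a Pearson chi-square test
of independence (`chi_square_independence()`): expected counts
$E_{ij} = R_i C_j / N$, statistic $\sum (O-E)^2/E$,
$\mathrm{df} = (r-1)(c-1)$, p-value from the upper tail of the
$\chi^2$ distribution, with an optional Yates correction for $2\times2$
tables. Pairwise comparisons are uncorrected by default (an optional
Bonferroni flag exists) since multiple pairwise p-values are
conventionally reported raw in this literature.

## Colour-distribution analysis

Laboratories differ in staining; scanners differ in colour rendering.
Both are quantified on per-channel 256-bin histograms of 8-bit RGB tiles,
each channel normalized to sum to 1. Distances use the squared Euclidean
($L^2$) metric summed over all 768 bins. Choices we fixed:

* normalization is per channel and the distance sums over channels
  without averaging; with per-channel normalization the absolute distance
  scale depends on that convention, so cross-study comparisons should use
  *relative* quantities (e.g. `percent_increase()` between two distances)
  rather than absolute values;
* case-level histograms average the per-image histograms unweighted (an
  image contributes equally regardless of pixel count);
* no background masking by default; a luminance mask can be supplied to
  `compute_histogram()` to exclude white background.

`spread_summary()` quantifies the qualitative "greater distribution of
colour pixel values with lower peaks" pattern as the per-channel peak
height, occupied-bin count and pixel-value standard deviation.
`recover_scanner()` is a nearest-reference harness: a tile's histogram is
assigned to the closest labelled reference histogram, with deterministic
first-label tie-breaking.

## What the synthetic generators emulate

The study's slides and per-set scores are not deposited, so the package
ships generators whose *defaults are the study conditions* and which are
deterministic given a seed (Mersenne-Twister; the root seed fans out to
per-case and per-tile sub-seeds so prefixes are reproducible).

**Score cohorts** (`generate_cohort()`): 186 cases, HSCR prevalence
62/186, 12 image sets per case. Ganglion-absent cases contain no
true-ganglion sets; ganglion-present cases contain at least one (each set
is ganglion-bearing with probability 0.6). DSA scores are Beta(8, 2) for
true-ganglion content and Beta(1.5, 6) otherwise — the Beta family was
chosen for bounded support and a single, easily controlled separation;
the true distributional shape of real detector scores is unknown, so
these are stated assumptions, not estimates. The pathologist is a 5×2
categorical confusion (90% certainty mass on the correct extreme). Two
mechanisms create the observed error regimes:

* **technical artifacts** (probability 0.08 by default): a true-ganglion
  set loses 0.45 of its DSA score (clipped), while the pathologist score
  is untouched — encoding the observation that staining/scanning
  irregularities degrade the algorithm but not the human reader. High
  artifact probability produces the false-negative-dominant profile of
  external laboratories.
* **mimics** (probability 0.04): a non-ganglion set draws its DSA score
  from the true-content distribution, producing the
  false-positive-dominant profile of the home laboratory whose cutoffs
  favour sensitivity.

The generator's bookkeeping columns (`true_content`, `artifact`, `mimic`)
are the oracle the tests compare reports against. Synthetic experts are
always right, so referred synthetic cases resolve correctly; real expert
fallibility is out of the model.

**Tiles** (`generate_tile()`): a procedural renderer — textured
eosinophilic stroma, scattered hematoxylin nuclei, and content-specific
structures (pale-cytoplasm ganglion cells with dark rims and nucleoli;
wavy plexus bands) — followed by a laboratory affine colour transform
(per-channel gain/offset) and a scanner pipeline of Gaussian blur
(`EBImage::gblur`), gamma, and additive Gaussian colour noise, clipped
and rounded to 8 bits. This is deliberately not photorealistic histology:
only histogram-level behaviour is consumed downstream, and properties
such as "wider colour spread lowers peaks and widens support" hold by
construction of the noise model, not by resemblance to tissue. Passing
tests on these tiles therefore demonstrates the *machinery* (histograms,
distances, recovery) and the qualitative regime behaviour — they cannot
validate performance on real H&E variability, which also includes
stain-batch drift, tissue-fold artifacts, compression and
scanner-specific sharpening that the renderer does not model.

`example_scanner_profiles()` fixes three rendering profiles: two sharp,
low-noise, near-neutral profiles and one soft, noisy, low-contrast
profile, mirroring the published pattern in which two scanner brands
cluster together and the third diverges.

## Numerical choices and degenerate inputs

* Histogram normalization is checked to $10^{-9}$ per channel; distances
  on unnormalized input raise an error rather than silently rescaling.
* Chi-square on a table with a zero marginal errors out (expected counts
  undefined); non-integer or negative cells are validation errors.
* Classification of a case with zero image sets is an error, as is an
  in-doubt case without an expert call, a duplicated `set_index` within a
  case, or a score table referencing an unknown case id — the offending
  ids are named in the error.
* Empty strata are dropped from discordance tables with a warning.
* Tie-breaks in `recover_scanner()` go to the first reference label.

## Problem sizes used in the checks

The test suite exercises the decision rule exhaustively over all
pathologist-score/DSA-score combinations on a 0.1 grid for cases of up to
3 sets (~170k cases), histogram invariants over 100 random tiles, the two
error regimes on seeded cohorts of 500 cases (6000 image sets each,
compared by chi-square), and scanner-profile recovery over 300 tiles of
96×96 pixels against references averaged from 15 tiles per profile —
sizes at which the Monte-Carlo properties are stable across seeds while
the whole suite stays quick to run.

## Known limitations

* Absolute histogram distances depend on the normalization convention and
  on image content; only relative comparisons are meaningful across
  setups.
* The score generator models one pathologist and one detector; no
  inter-observer variability, no per-center stain-conditional score
  distributions beyond the artifact/mimic mechanisms.
* The published per-comparison chi-square p-values of the original
  evaluation depend on grouping choices (pairwise vs pooled, case- vs
  set-level) that the printed marginals do not determine, so they are not
  targets of the reproduction; the machinery to compute any of the
  candidate groupings is exported instead.
* Case counts in published summary tables and the accompanying text can
  disagree by one case (125 vs 124 ganglion-positive); reporting uses
  whatever the input tables contain and does not attempt to adjudicate.
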