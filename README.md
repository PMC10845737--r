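# hscrdss

Robustness-evaluation toolkit for an algorithm-assisted decision support
system (DSS) used in the histopathological diagnosis of Hirschsprung's
disease (HSCR).

## The problem

HSCR is diagnosed by the *absence* of ganglion cells across many rectal
biopsy slides. A decision support algorithm (DSA) surveys whole-slide
images, proposes ganglion-cell candidates with confidence scores
*s* ∈ [0, 1], and presents the best candidates to a pathologist in up to 12
image sets per case; the pathologist scores each set on a 1–5 ordinal scale
(1 = certainly no ganglion cells, 5 = certainly ganglion cells). Because
laboratories differ in staining and slide preparation, and scanner models
differ in colour rendering, any such system must be validated across sites
and devices. This package implements the evaluation machinery for that kind
of multi-center, multi-scanner robustness study, for researchers validating
image-analysis decision support against pre-analytic variability:

* **Decision engine** — the DSS case-classification rule with referral
  logic. With *n₅* the number of sets scored 5 by the pathologist and
  *s̄* the mean DSA score over the case's sets:
  * *positive* (non-HSCR) ⇔ *n₅* ≥ 2;
  * *negative* (HSCR) ⇔ *n₅* < 2 and *s̄* < 0.6;
  * *in doubt* (expert referral) ⇔ *n₅* < 2 and *s̄* ≥ 0.6;

  plus referral resolution and per-cohort performance summaries
  (sensitivity among ganglion-present cases, pre- and post-referral).
* **Discordance statistics** — image-set-level error labels
  (*false negative*: pathologist 5 with DSA < 0.3; *false positive*:
  pathologist 1 with DSA > 0.7), per-stratum rate tables with a
  causative-factor taxonomy (technical / missing sensitivity-specificity /
  new-abnormal findings / unknown), and Pearson chi-square tests of
  independence comparing error profiles between strata.
* **Colour analysis** — per-channel 256-bin RGB histograms normalized to
  sum to 1, squared-Euclidean distance
  d(h₁, h₂) = Σ₍c,v₎ (h₁[c,v] − h₂[c,v])², case-level histogram averaging,
  and spread summaries (peak height, occupied bins, pixel-value SD)
  quantifying the "wider distribution, lower peaks" pattern of divergent
  scanners.
* **Synthetic generators** — seeded score cohorts (Beta-distributed DSA
  scores conditional on true content, categorical pathologist confusion,
  technical-artifact and mimic mechanisms) and procedural H&E-like RGB
  tiles under parameterized laboratory stain and scanner rendering
  profiles, so the whole pipeline is testable without clinical slides.

## Worked example

```r
library(hscrdss)

# a seeded synthetic cohort: 20 cases, 12 image sets each
coh <- generate_cohort(score_gen_params(n_cases = 20), seed = 3)
res <- run_classification(coh$sets, coh$cases, stratify_by = "cohort")
writeLines(format_cohort_table(res$summary))
#> Stratum          Cases  HSCR non-HSCR  Correct  Incorrect  Referrals  Sens.pre Sens.post
#> ----------------------------------------------------------------------------------------
#> synthetic           20    11        9       20          0          0    100.0%    100.0%
#> Total               20    11        9       20          0          0    100.0%    100.0%

# image-set-level discordance
print(tabulate_discordance(coh$sets, by = "cohort"))
#> synthetic: 240 image sets, 13 total errors (5.4%)
#>   false positive: 10 (4.2%) | technical 0 (0.0%), missing_sens_spec 10 (100.0%), ...
#>   false negative: 3 (1.2%) | technical 1 (33.3%), missing_sens_spec 0 (0.0%), ...
```

All 20 cases classify correctly: the default generator is a near-expert,
well-separated regime, so errors concentrate at the image-set level (here
13 of 240 sets discordant) rather than the case level. The `Sens.pre` /
`Sens.post` columns are the sensitivity among ganglion-present cases
before and after expert referrals are resolved.

Colour side:

```r
tile <- generate_tile(96, 96, "ganglion",
                      scanner = example_scanner_profiles()$histech_like,
                      seed = 7)
spread_summary(compute_histogram(tile))  # peak height, occupied bins, SD per channel
```

A thin command-line wrapper with subcommands `classify`, `discordance`,
`color-report`, `simulate-scores` and `simulate-images` is installed at
`inst/cli/hscrdss.R`.

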