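---
title: "Fragility auditing of trial corpora: model, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragility auditing of trial corpora: model, conventions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragilityaudit)
```

## The statistic

The Fragility Index (FI) asks a blunt question of a statistically
significant two-arm trial with a binary outcome: how many patients would
have had to end up with a different outcome for the significance to vanish?
Writing the trial as the 2×2 table with `a`/`b` events/non-events in arm A
and `c`/`d` in arm B, the engine:

1. computes the two-sided Fisher exact p-value — conditional on the margins
   the events-in-arm-A cell is hypergeometric, and the two-sided p sums the
   point probabilities of all same-margin tables whose probability does not
   exceed the observed table's;
2. if p ≥ α, stops with FI = 0;
3. otherwise converts one non-event to an event in the arm holding the
   fewer events (arm A on a tie), recomputes p, and repeats; the FI is the
   number of conversions at which p first reaches α.

Significance is *lost* at p ≥ α, matching the convention that significance
means p < α. The default α is 0.05 and is always supplied explicitly —
never inferred from a trial's reported p-value, because reported p-values
come from heterogeneous tests and the audit deliberately re-tests every
table with the same exact test.

### Assumptions and scope

The FI as implemented applies to parallel two-arm trials with a dichotomous
outcome and a superiority question. Time-to-event outcomes enter only
through dichotomization (event by a landmark time), which is how guideline
audits typically extract them. Non-inferiority designs, multi-arm trials,
and continuous outcomes are out of scope, as are mid-p or chi-square FI
variants, the fragility quotient, and the reverse FI for non-significant
trials.

### Conventions where the literature is loose

* **Which arm is modified.** The original procedure adds events to the arm
  with the fewer events; popular online calculators do the same, and so
  does `fragility_index()` (arm A on ties). The choice matters:
  `fragility_index_bruteforce()` searches both arms exhaustively, and
  `fi_exhaustive_check()` compares the two over every small table rather
  than asserting they always agree.
* **FI = 0.** Trials are admitted to an audit because their *publication*
  claimed significance. Re-testing the extracted counts with the exact test
  can disagree, and such trials receive FI = 0 rather than an error; this
  is exactly how FI = 0 entries arise in published audits.
* **Saturation.** On extreme tables the fewer-events arm can run out of
  non-events while the table is still significant — for example
  `(2,0,2,13)`, where the tied-events rule picks arm A, which has no
  non-events at all. `fragility_index()` signals a typed condition
  (`fragility_saturation_error`) carrying the partial trajectory;
  `fi_exhaustive_check()` records such tables with `fi = NA` in its
  divergence catalogue. Over all tables with arm totals ≤ 25 these
  saturating tables are the *only* divergences: wherever the sequential
  search completes, it equals the exhaustive two-arm minimum (the
  `analysis/03_engine_validation.R` run and the acceptance suite compute
  this).
* **Floating-point ties.** A same-margin table counts toward the two-sided
  p when its point probability is ≤ observed × (1 + 1e−7). The buffer
  absorbs floating-point representations of exact ties (symmetric tables
  produce genuinely tied probabilities); exact rational arithmetic would be
  an acceptable alternative at a complexity cost. Arm-exchange symmetry
  consequently holds to summation rounding (≈1e−15), which is why the test
  suite asserts it at 1e−12 rather than bitwise.

## The LTFU robustness criterion

For each trial the audit records the number of randomized patients whose
outcome was never ascertained (lost to follow-up, LTFU). A result should be
viewed with skepticism when LTFU > FI — strictly greater — because the
unknown outcomes alone could then overturn it. The flag is computed per
study (`score_corpus()`) and per category on medians
(`summarize_corpus()`: flagged when median LTFU > median FI). "Lost to
follow-up" is operationally ambiguous across publications
(randomized-but-unanalyzed versus explicit withdrawal); the corpus field
carries whichever convention the extractor used, and the generator uses
randomized-but-unanalyzed.

## Summaries

Corpus summaries report median and interquartile range, the natural scale
for counts as skewed as FIs. Quartiles use linear interpolation between
order statistics (quantile type 7, the default of mainstream statistical
software); published audits report fractional quartiles consistent with an
interpolating rule but rarely name it, so the rule here is documented and
verified against an independently hand-rolled interpolation in the tests.
Categories with zero studies are omitted rather than emitted as NaN rows.
Small categories (the default corpus has one with two studies) still get an
IQR; with n = 2 it simply spans the two values.

## What the synthetic generator emulates

No public dataset carries per-trial 2×2 extraction data for a guideline
citation corpus, so the package ships a seeded generator whose default
configuration (`nccn_like_config()`, stored as
`inst/extdata/nccn_like.yaml`) emulates the *shape* of such a corpus:

* 67 trials in 9 treatment categories, split 10/5/6/3/9/19/5/2/8 across
  neoadjuvant chemotherapy, radiotherapy, chemoradiation and immunotherapy,
  surgery, metastatic liver disease treatment, adjuvant chemotherapy and
  immunotherapy, and follow-up/chemoprevention;
* per-arm sizes drawn log-uniformly (right-skewed trial sizes), calibrated
  so the corpus-wide median total is near 161 patients with an IQR of
  roughly 72–255;
* a control event rate and an intervention odds ratio per trial, binomial
  event counts per arm;
* near-1:1 allocation: one size draw per trial split by blocked
  randomization (imbalance ≤ 2). Drawing the two arm sizes independently is
  not just unrealistic — it creates tables whose fewer-events arm has the
  *higher* event rate, which saturates the FI search;
* a significance screen: trials are redrawn until the exact p < α,
  emulating the inclusion filter of audits that only admit significant
  results. Rejection sampling biases realized effect sizes upward, so the
  redraw count is kept on each record (`n_redraws`) to make the bias
  observable;
* loss to follow-up as an outcome-independent fraction of the randomized
  total (non-informative dropout) — the simplest defensible model, and a
  known limitation: informative censoring would tighten the link between
  LTFU and fragility that the flag is meant to probe;
* category-level power built in deliberately: neoadjuvant immunotherapy is
  small with weak effects (barely significant, fragile, high dropout),
  surgery is large with strong effects (robust). The recovery experiment
  checks the pipeline recovers that ordering.

Each trial runs on its own RNG substream derived from the root seed, the
category name (rolling polynomial hash), and the trial counter, so editing
one category never perturbs another's draws, and identical configurations
produce byte-identical corpora.

What the generator does **not** emulate: real outcome definitions and their
correlation structure, informative dropout, multi-center heterogeneity,
publication-year trends, or the actual per-category FI medians of any
published audit — those depend on unpublished extraction data, and matching
them is explicitly not attempted. Passing tests on synthetic corpora
therefore validate the *pipeline* (extraction-form handling, eligibility
screening, exact-test FI, aggregation, flags), not any substantive claim
about real rectal-cancer evidence.

## Numerical and design choices

* Exact p-values come from `stats::dhyper` point probabilities enumerated
  over the hypergeometric support; degenerate margins (an all-zero outcome
  column or arm) have a single attainable table and return p = 1.
* The brute-force oracle tries each arm independently and every conversion
  count up to a bound, returning `NA` ("not found within bound") when
  exhausted — including the coherent edge case that a table already at
  p ≥ α has minimum 0.
* Eligibility screening errors on *structurally impossible* records
  (events exceeding arm size, unknown category, LTFU above the randomized
  total) instead of returning an ineligibility verdict: those are
  extraction bugs, not screening outcomes. The category vocabulary is
  closed so typos cannot silently form new groups.
* Deduplication keeps the most recent publication among records sharing a
  non-`"NR"` short name; `"NR"` is a sentinel that never matches itself.
* Floating-point values in written CSVs are rounded to 6 significant
  digits for cross-platform diffability; in-memory values keep full
  precision.

## Problem sizes used by the checks

The exhaustive engine audits run over all tables with arm totals ≤ 25
(122,500 tables; 52,296 significant) for FI-vs-oracle equivalence and
threshold coherence, and over all 245,025 tables with margins ≤ 30 for
agreement of the exact test with an independent binomial-coefficient
enumeration at 1e−12. The FI = 0 ⇔ p ≥ α equivalence is additionally
verified exhaustively over arm totals ≤ 12. The recovery experiment uses
200 replicate corpora of the two extreme categories (five trials each);
the null-calibration check uses 10,000 unscreened draws. These sizes keep
each property exhaustive or well-powered at desk scale while the whole
suite stays fast.

## Known limitations

* The FI inherits the exact test's conservatism; a chi-square-based FI can
  differ by a step or two near the threshold.
* The fewer-events-arm convention is one of several in circulation;
  divergence from the two-arm minimum is confined to saturating extreme
  tables at the audited sizes, but users comparing against other tools
  should check which convention those implement.
* Category-level flags compare medians of skewed small samples; with two
  or three trials per category they are descriptive, not inferential.
* The generator's non-informative dropout understates the evidential
  damage of real, possibly informative, loss to follow-up.
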