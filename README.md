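# fragilityaudit

Audit the robustness of randomized controlled trial (RCT) evidence with the
Fragility Index (FI), at the scale of a whole guideline's citation corpus.

Clinical practice guidelines — such as those covering rectal cancer — rest
on a body of RCTs whose primary outcomes were reported as statistically
significant. Statistical significance alone says little about robustness: in
many trials, a handful of patients with different outcomes would have erased
the result. The FI makes that concrete. For a parallel two-arm trial with a
binary outcome summarized as the 2×2 table

|        | events | non-events |
|--------|--------|------------|
| arm A  | a      | b          |
| arm B  | c      | d          |

the FI is the minimum number of patients whose status must change from
non-event to event for the two-sided Fisher exact p-value to reach
p ≥ α (α = 0.05). Starting from a significant table, one non-event is
converted to an event in the arm with the fewer events, the exact test is
recomputed, and the count of conversions at which p first reaches α is the
FI. A trial whose counts are already non-significant under the exact test
has FI = 0 — a real phenomenon among trials admitted on *reported*
significance. A companion robustness criterion compares the FI to the number
of patients lost to follow-up (LTFU): when LTFU > FI, the unknown outcomes
of the lost patients alone could overturn the result.

The package provides:

- `fisher_exact_two_sided()` / `fragility_index()` — the exact-test engine
  and the deterministic FI search, with a full per-step audit trail;
- `fragility_index_bruteforce()` / `fi_exhaustive_check()` — an exhaustive
  verification oracle and a small-table sweep that catalogues every table
  where the fewer-events-arm convention cannot complete;
- a trial-corpus data model (`trial_record()`, `read_corpus()`,
  `validate_trial()`, `deduplicate()`) mirroring a standard extraction form;
- corpus summaries (`score_corpus()`, `summarize_corpus()`) — median/IQR of
  FI and LTFU per treatment category, with LTFU > FI flags;
- a seeded synthetic-corpus generator (`simulate_corpus()`,
  `nccn_like_config()`) emulating a 67-trial, 9-category guideline corpus,
  plus a parameter-recovery harness (`recovery_experiment()`).

## Worked example

A single trial: 1/10 events under intervention versus 9/10 under control.

```r
library(fragilityaudit)
fragility_index(contingency_table(1, 9, 9, 1))
#> Fragility Index: 3
#>   initial p = 0.00109333 (alpha = 0.05)
#>   final p   = 0.0572755 after 3 non-event -> event conversion(s) in arm A
#>   step 1: (2,8,9,1)  p = 0.00547749
#>   step 2: (3,7,9,1)  p = 0.0197666
#>   step 3: (4,6,9,1)  p = 0.0572755
```

Three flipped outcomes erase this "p = 0.001" result. The full corpus
analysis is the numbered scripts under `analysis/`:

```sh
Rscript analysis/01_simulate_corpus.R     # 67-trial synthetic corpus
Rscript analysis/02_fragility_audit.R     # per-study FI + category summaries
Rscript analysis/03_engine_validation.R   # exhaustive small-table audit
Rscript analysis/04_recovery_experiment.R # fragility-ordering recovery
```

On the default configuration and seed, step 2 prints:

```
Corpus fragility summary: 67 studies in 9 categories
  overall median FI 8 (IQR 3-14), median LTFU 2 (IQR 0-7.5)
  flagged (median LTFU > median FI): neoadjuvant immunotherapy; follow-up and chemoprevention
```

Reading: across the corpus a median of 8 outcome flips would be needed to
lose significance, but the flagged categories combine fragile results
(median FI 2 and 7.5) with more patients lost to follow-up than that —
their evidence could be overturned by the dropouts alone. Tables land in
`results/audit/`, figures as `fi_by_category.pdf` and `fi_vs_ltfu.pdf`.

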