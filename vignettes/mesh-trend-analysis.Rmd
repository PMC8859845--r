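---
title: "Comparative MeSH-term frequency and trend analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative MeSH-term frequency and trend analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Every MEDLINE article is manually indexed with roughly 10–15 Medical
Subject Headings (MeSH) descriptors drawn from a curated hierarchical
vocabulary. Because the indexing is consistent across journals and time,
the yearly frequency with which a descriptor is attached to articles is a
usable proxy for how much of a field's attention a topic receives. Two
questions follow naturally for anyone surveying a research area:

1. **Which topics distinguish a field from the background literature?**
   Compare a *target* sample of articles (matching a field query) with a
   *control* sample (a broad background query) and find terms whose usage
   frequency differs.
2. **Which topics are rising or declining?** Within each sample, find terms
   whose yearly frequency moves monotonically over a decade-scale window.

`meshtrends` implements this comparison pipeline end to end, plus a
synthetic corpus generator with known ground truth so every stage can be
validated offline.

## The procedure

Articles from both samples are binned by year (calendar years by default;
PubMed-style `[PDat]` windows such as Oct 22–Oct 21 via
`pdat_intervals()`). Three preparation rules are applied:

* **Disjoint samples.** Any PMID occurring in both samples is excluded from
  both, so each article is uniquely target or control.
* **Category restriction.** Analysis is limited by default to descriptors
  in categories C ("Diseases"), D ("Chemicals and Drugs") and E
  ("Analytical, Diagnostic and Therapeutic Techniques, and Equipment"),
  subcategories included — these are the categories in which topical
  signal, rather than publication mechanics, lives. Membership is decided
  by the first letter of a descriptor's tree numbers.
* **Support filter.** Terms associated with five or fewer articles are
  removed. The rule is applied per sample (a term must have at least six
  articles in the target *and* six in the control over the whole window):
  the motivation is the chi-square rule of thumb that expected cell counts
  below five make the test unreliable, and a cell can be starved on either
  side.

For term $i$ and year $y$, let $PM_{iy}$ and $GM_{iy}$ be the number of
target and control articles carrying the term and $N_{t,y}$, $N_{c,y}$ the
sample sizes. The pipeline computes:

* **Per-year proportion tests.** $H_0: PM_{iy}/N_{t,y} = GM_{iy}/N_{c,y}$
  via the 2×2 Pearson chi-square with 1 df, Yates-corrected by default
  (matching the behaviour of `prop.test` on a 2×2 table). Power grows with
  sample size: 9/10 vs 7/10 is not significant at $\alpha = 0.05$
  ($\chi^2 = 0.3125$, $p = 0.58$), while 90/100 vs 70/100 is
  ($\chi^2 = 11.28$).
* **FDR control.** Benjamini–Hochberg adjustment of the per-year p-values.
  The family is *all terms within one year*: each year's sweep over the
  vocabulary is one multiple-testing event.
* **Fisher aggregation.** A term's raw per-year p-values are combined as
  $\chi^2 = -2\sum_y \ln p_{iy}$ on $2k$ df. Raw (not FDR-adjusted)
  p-values are aggregated, as Fisher's method is defined for them; the
  adjusted per-year values are reported alongside. A BH adjustment of the
  aggregated p-values across terms (`fisher_q`) is also emitted and is the
  default significance gate — the underlying method leaves this cut
  unspecified, so the 0.05 default here is this package's choice, exposed
  as a parameter.
* **Effect size.** $\mathrm{logratio}_i = \log_2(PM_i / GM_i)$ on pooled
  whole-window relative frequencies (and per year). Positive means
  target-enriched; $|{\mathrm{logratio}}| = 2$ means a four-fold
  difference. When the control count is zero the ratio is undefined and
  the sentinel value 10 is reported — larger than any plausible real
  log-ratio, so such terms sort to the extreme of the target-enriched
  tail. A zero *target* count with a positive control count is reported as
  `-Inf` in per-year tables (the pooled value cannot hit this case for
  supported terms).
* **Trend detection.** Within each sample separately, the Mann–Kendall
  test on each term's yearly relative-frequency series:
  $S = \sum_{i<j}\mathrm{sign}(x_j - x_i)$, tie-corrected variance
  $\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_p t_p(t_p-1)(2t_p+5)]/18$, and a
  continuity-corrected normal score. A trend is classified up or down only
  when the two-sided p-value is at most 0.01; no multiple-testing
  correction is applied across terms, a deliberate concession to the low
  power of the test on series of at most ~13 (typically 9) points. Series
  are eligible only when the term was observed (non-zero count) in at
  least 6 distinct years in that sample; years in which the sample itself
  is empty are removed from a series, not imputed as zeros. Both the
  endpoint change in percentage points and Sen's slope (median pairwise
  slope) are reported — printed summaries of frequency change in the
  literature are ambiguous between the two, so both are emitted and
  neither is privileged.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `categories` | `C, D, E` | category whitelist; `NULL` disables |
| `support_threshold` | 5 | max articles per sample at which a term is still removed |
| `min_years` | 6 | observed years required for trend eligibility |
| `trend_threshold` | 0.01 | Mann–Kendall two-sided p cut for up/down |
| `continuity` | `TRUE` | Yates correction (proportion test) and MK continuity correction |
| `diff_alpha` | 0.05 | gate on `fisher_q` for "specific" terms (wordclouds) |
| `sentinel` | 10 | log-ratio stand-in when the control count is 0 |

The defaults reproduce the method's stated operating point; every one is a
`run_config()` argument.

## The synthetic corpus generator

`simulation_spec()` / `generate_corpus()` emulate the two-sample design:
articles in both samples draw 10–15 descriptors from a category-structured
vocabulary (default 500 terms, 40% C / 30% D / 20% E / 10% B) whose
baseline frequencies decay as a power law ($\propto i^{-0.5}$, scaled so a
term's weight is approximately its per-article inclusion probability).
The default study conditions — 9 yearly bins, 2000 articles per sample per
year — are a scaled-down but proportionate analogue of a decade-long
literature comparison with thousands of articles per year and a
~1000-term analyzable vocabulary. Injected signal:

* **Differential terms** scale the target-sample weight by
  $2^{\mathrm{enrichment}}$, so the pipeline's pooled log-ratio should
  recover the enrichment.
* **Trend terms** interpolate an absolute frequency linearly from a start
  to an end value across the bins in one designated sample.
* **Shared PMIDs** (`overlap_fraction`) are emitted into both samples to
  exercise the exclusion logic.

Term draws per article use Gumbel top-$k$ weighted sampling without
replacement: per-article term counts are exact, and inclusion
probabilities are approximately proportional to weights. The
approximation is excellent for terms holding a small share of the total
weight but *saturates for heavy terms*: a term pushed toward inclusion
probability ~0.5 by a strong positive enrichment will come out with a
somewhat smaller realized enrichment than injected (the draw cannot
include a term twice). Validation of exact effect-size recovery therefore
uses enrichments that keep both sides' frequencies modest; strong
enrichments are validated for detection and sign.

What the generator deliberately does **not** emulate: MeSH indexing lag,
year-to-year vocabulary growth, term co-occurrence structure beyond the
weighted draw, journal/author metadata, and real descriptor names (the
vocabulary is synthetic, with synthetic `X`-prefixed UIs). Passing tests
on these corpora therefore demonstrate the statistical machinery's
correctness and calibration — not robustness to annotation-practice
drift in real PubMed data.

## Numerical and degenerate-input choices

* A 2×2 table with pooled proportion 0 or 1 returns $p = 1$ with a
  degenerate flag rather than NaN.
* Zero p-values entering Fisher aggregation are clamped to the smallest
  positive double (with a warning); $\ln 0$ is undefined.
* An all-tied Mann–Kendall series has $\mathrm{Var}(S) = 0$ and returns
  $S = 0$, $p = 1$, flagged degenerate.
* The continuity correction shifts $S$ by 1 toward zero; $z = 0$ exactly
  when $S = 0$.
* Fisher's method is *not* monotone in the number of combined tests for
  weak evidence: combining two copies of $p = 0.3$ gives 0.307, slightly
  worse than one. This is a property of the method, not a bug; evidence
  accumulates only when the component p-values are individually small.
* Relative frequencies are computed from integer counts at use time and
  never pre-rounded.

## Calibration, and the continuity-correction caveat

The test suite validates calibration on an all-null corpus at the default
study conditions (500 terms × 9 years × 2000 articles/sample/year, fixed
seed): the trend false-positive rate at threshold 0.01 stays within three
binomial standard errors of 0.01, and the per-year proportion-test
p-values are uniform within each year's family (Kolmogorov–Smirnov, not
rejected at 0.01). The uniformity check runs the *uncorrected* chi-square:
the Yates correction makes null p-values deliberately conservative
(stochastically larger than uniform), so the corrected variant fails any
exact uniformity test by construction while remaining the right default
for small-count inference. Parameter-recovery runs on the same conditions
show recall ≥ 0.9 for injected differential terms
($|\mathrm{enrichment}| \ge 1$ at comfortable support) and for injected
linear trends (0.01 → 0.10 over 9 bins). These problem sizes keep the
whole suite in the tens of seconds on one core while leaving per-cell
counts in the regime the chi-square approximation needs.

## Known limitations

* The normal approximation for Mann–Kendall is crude at $n \le 10$; the
  exact permutation test (`mann_kendall_exact`, $n \le 8$) shows decisions
  at the 0.01 threshold agree outside a narrow boundary band, but
  borderline p-values on short series should not be over-read.
* Fisher aggregation assumes the per-year tests are independent, which
  holds across disjoint yearly article sets but ignores secular
  correlation in topic usage.
* Per-year p-values from discrete counts carry an atom at $p = 1$ (equal
  counts in equal-sized samples); pooled-across-years uniformity tests
  will detect this discreteness at large scale even for a perfectly
  calibrated implementation.
* Query construction, live PubMed retrieval and indexing-lag correction
  are out of scope; the package consumes already-retrieved article
  records.
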