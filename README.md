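# meshtrends

Differential frequency and trend analysis of MeSH annotations.

## What it does, and for whom

MEDLINE articles are indexed with 10–15 Medical Subject Headings (MeSH)
descriptors from a curated vocabulary. For anyone mapping a research field
— scientometricians, funders, group leaders choosing directions —
the yearly frequency of a descriptor is a clean, journal-independent
signal of topical attention. `meshtrends` compares a *target* article
sample (a field of interest) against a *control* sample (the background
literature) and answers two questions:

* which MeSH terms are significantly over- or under-represented in the
  target field, and by how much;
* which terms show a credible monotone rise or decline over the years,
  in either sample.

## The statistics at the core

With $PM_{iy}, GM_{iy}$ the target/control article counts carrying term
$i$ in year $y$ and $N_{t,y}, N_{c,y}$ the sample sizes:

* per-year two-proportion chi-square tests (Yates-corrected, 1 df) of
  $PM_{iy}/N_{t,y}$ vs $GM_{iy}/N_{c,y}$, Benjamini–Hochberg-adjusted
  across terms within each year;
* Fisher aggregation of each term's raw per-year p-values,
  $\chi^2 = -2\sum_y \ln p_{iy}$ on $2k$ df;
* the effect size $\mathrm{logratio}_i = \log_2(PM_i/GM_i)$ (pooled and
  per year), with the sentinel value **10** when the control count is
  zero;
* Mann–Kendall trend tests (tie-corrected variance, continuity-corrected
  normal score) on each term's yearly frequency series, classified
  up/down at $p \le 0.01$ with no multiple-testing correction, for series
  observed in at least 6 years.

Supporting rules: shared PMIDs are excluded from both samples; analysis
is restricted to MeSH categories C/D/E; terms with five or fewer articles
in either sample are removed. All thresholds are configurable
(`run_config()`); the vignette in `vignettes/mesh-trend-analysis.Rmd`
documents every choice.

## Worked example

The package ships a synthetic-corpus generator with known ground truth,
so a full run needs no data files. Here we inject one four-fold
target-enriched term (`term0008`), one four-fold control-enriched term
(`term0009`) and one rising trend (`term0250`, frequency 0.01 → 0.10):

```r
library(meshtrends)

spec <- simulation_spec(
  seed = 42, years = 2009:2017, n_target = 1000, n_control = 1000,
  vocabulary_size = 300,
  differential = data.frame(term = c(8L, 9L), log2_enrichment = c(2, -2)),
  trend = data.frame(term = 250L, sample = "target",
                     start_freq = 0.01, end_freq = 0.10))
corp <- generate_corpus(spec)

run <- run_pipeline(run_config(
  corp$target, corp$control, vocabulary = corp$vocabulary,
  intervals = year_intervals(2009:2017)))
run
#> <meshtrends_run>
#>   terms analyzed: 270 (of 300 observed)
#>   trends (p <= 0.01):
#>          direction
#> sample     up down none
#>   control   0    0  270
#>   target    2    2  266

cmp <- run$comparisons
head(cmp[order(cmp$fisher_q),
         c("term", "fisher_q", "target_freq", "control_freq", "logratio")], 3)
#>      term  fisher_q target_freq control_freq logratio
#>  term0008  0.00e+00      0.4179       0.1321    1.661
#>  term0009 3.20e-102      0.0304       0.1193   -1.971
#>  term0250  2.08e-31      0.0534       0.0208    1.363
```

The three injected terms head the ranking: `term0009` recovers its
injected log2 ratio of −2 (four-fold control enrichment); `term0008`
shows the expected sign with magnitude damped by draw saturation at high
frequency (see the vignette); `term0250` is differential because its
frequency grew only in the target sample. The trend table pins it down:

```r
tr <- run$trends
tr[tr$term == "term0250" & tr$sample == "target",
   c("n_years", "S", "p", "direction", "delta_pp", "sen_slope")]
#>  n_years  S       p direction delta_pp sen_slope
#>        9 32 0.00123        up      7.1    0.0110
```

a credible upward trend gaining 7.1 percentage points of the sample over
the window (the two false-positive up/down calls among 270 null terms
per sample are consistent with the 1% threshold). Manifest bookkeeping
(`run$manifest`) records every article and term removed at each filter
stage; `wordcloud_table()`, `heatmap_matrix()` and `corpus_summary()`
export the presentation-layer tables, and `inst/cli/meshtrends.R` wraps
simulate/run/score for shell use.

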