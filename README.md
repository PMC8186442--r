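# rsvstab

Reliability auditing for repeated pulls of Google-Trends-style relative
search volumes (RSVs).

## The problem

Google Trends reports the popularity of a query as a *relative search
volume*: each geographic unit's search share is scaled so the top unit in
the requested geography and time window scores 100. Infoveillance and
infodemiology studies routinely download such RSVs once, correlate them
with an external quantity — COVID-19 case counts, for instance — and draw
epidemiological conclusions.

The trouble is that downloading the *same* query, period and geography on
different calendar days does not return the same numbers. Cities appear in
one day's pull and vanish from the next; coefficients of correlation with
case counts drift from one collection day to the following one; whole
rankings reshuffle. `rsvstab` implements a methodology for quantifying
this instability and deciding whether a dataset of repeated pulls can
support statistical inference at all, plus a collection protocol that
produces defensible summary values when it can.

## The model and statistics

The central container is the **pull matrix**: rows are geographic series
*i* (cities, regions or countries), columns are collection days *j*, and
cell *x*<sub>ij</sub> is the RSV that series *i* showed in the pull made
on day *j* (missing when the series did not appear in that pull).

- **Anomaly audit** — a series is *anomalous* if it is missing from at
  least one pull. If anomalous series exceed 20% of the sample, the whole
  dataset is excluded from statistical analysis; otherwise the anomalous
  series are dropped.
- **Stability summaries** — each retained series' daily variation is
  modelled as a Gaussian *X*(σ<sub>i</sub>, x̄<sub>i</sub>); the package
  reports x̄<sub>i</sub>, the sample SD σ<sub>i</sub>, SEM<sub>i</sub> =
  σ<sub>i</sub>/√n, a 95% CI, and a Shapiro–Wilk normality screen at
  α = .05.
- **Confidence screen** — every pair of series is compared with the Welch
  statistic *t* = |x̄<sub>l</sub> − x̄<sub>m</sub>|/σ̃, with σ̃ =
  √(SEM<sub>l</sub>² + SEM<sub>m</sub>²). A pair with *t* < 1.5 is
  *confident*: statistically indistinguishable, so their relative ranking
  in any single pull is noise. A dataset is *unreliable* when any series
  is confident with more than 20% of its partners.
- **Correlation stability** — Pearson/Spearman correlations between each
  day's RSVs and a per-unit external series (e.g. cumulative cases) are
  computed day by day; drift is quantified with the percentage increase
  Δ = (u_f − u_0)/u_0 · 100 across the observed range, with a
  median ± 3·MAD rule flagging outlier collection days.
- **Collection protocol** — an incremental engine implementing the
  recommended practice: monitor daily pulls until 7 consecutive days show
  no anomalies and no dramatic RSV jumps, keep extending until the series
  become statistically incompatible (and at least 30 pulls when any series
  screens non-normal), then publish per-series mean RSVs with 95% CIs
  instead of single-day values.

A seeded synthetic-data generator reproduces the whole data-generating
mechanism — Gaussian daily variation, per-pull max-normalization to 100,
missingness injection, integer quantization — so every result type is
testable without touching the network.

## Worked example

Four repeated-pull grids collected daily in December 2020 for the query
*coronavirus + covid* ship with the package. Auditing the Italian-cities
grid for investigation period 1 Feb–4 Dec 2020:

```r
library(rsvstab)

pm <- load_fixture("italian_cities_p1")   # 24 cities x 13 daily pulls
glance(detect_anomalies(pm))
#> # A tibble: 1 × 5
#>   n_series n_anomalous anomaly_rate threshold dataset_excluded
#>      <int>       <int>        <dbl>     <dbl> <lgl>
#> 1       24           8        0.333       0.2 TRUE
```

A third of the cities flicker in and out of existence across the 13 pulls
(Perugia is absent 7 times, Prato 10), which is beyond the 20% exclusion
threshold: no correlation computed from a single day's download of this
dataset can be trusted. Even the complete series fail the confidence
screen:

```r
pm |> drop_anomalous() |> confidence_report()
#> # confidence report: |t| < 1.50 on 120 pairs; max confident fraction 27% (Milano);
#> #   threshold 20% -> DATASET UNRELIABLE
#> # A tibble: 16 × 2
#>    unit     confident_fraction
#>  1 Bari                 0.0667
#>  8 Milano               0.267
#> ...
```

Milano's mean RSV is statistically indistinguishable from those of 27% of
the other cities, so its day-to-day position in the ranking is largely
chance. Each report type has `tidy()`/`glance()` tibble views and an
`autoplot()` method; `exec/rsvstab` exposes the same pipeline as a shell
tool (`rsvstab audit matrix.csv`, exit code 2 on exclusion).

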