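---
title: "Auditing the day-of-collection stability of relative search volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the day-of-collection stability of relative search volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvstab)
```

## The phenomenon under study

A relative search volume (RSV) is not a measurement of search activity;
it is a *normalization* of one. Each geographic unit's query share is
rescaled so that the top unit of the requested geography and window
scores 100. Because the provider recomputes this normalization (and
apparently resamples the underlying queries) on every download, pulling
the identical query/period/geography dataset on successive calendar days
yields different numbers, and sometimes different *sets of units*
altogether. `rsvstab` treats the repeated daily pull as the unit of
observation and asks: how much of what a single download shows is signal,
and how much is the day it happened to be downloaded?

## Data model

The pull matrix holds series $i$ (unit) by collection day $j$ with cells
$x_{ij} \in [0, 100]$ or missing. Missing cells are never imputed: a
unit's absence from a pull is precisely the instability being measured,
so imputation would erase the evidence. Cells are stored as decimals even
though served RSVs are integers, because the synthetic generator produces
continuous values before quantization and ingestion must not round.

On disk the matrix is a UTF-8 wide CSV — first column `unit`, remaining
headers ISO-8601 dates, empty string for missing — chosen so the
missingness pattern round-trips unambiguously. Unit names are joined
case-insensitively after whitespace trimming wherever two tables meet
(external series, protocol columns), since such tables are typically
hand-entered.

## Anomaly audit

A series is **anomalous** iff it has at least one missing cell. The
dataset-level rule excludes the whole sample when anomalous series
*exceed* 20% of it; the package reads "exceed" strictly, so a rate of
exactly 0.20 is tolerated. A series with *no* present cell is additionally
flagged unusable, as no statistic can be computed from it. Exclusion does
not physically prevent further analysis — the bundled city grids are all
beyond the threshold yet still worth tabulating — so downstream functions
run on request (the CLI requires `--force`), with the verdict carried in
the reports.

## Stability summaries and the confidence screen

Within a series, day-to-day variation is modelled as Gaussian
$X_i = X(\sigma_i, \bar{x}_i)$ over the present cells: mean, sample SD
($n-1$ denominator), $\mathrm{SEM}_i = \sigma_i / \sqrt{n}$, and a 95% CI
$\bar{x}_i \mp 1.96\,\mathrm{SEM}_i$ clipped to $[0, 100]$. Fewer than
two present cells leave the dispersion fields undefined rather than
zero — absence of evidence, not evidence of stability.

Normality is screened with Shapiro–Wilk. The level $\alpha = .05$ is
indicative, not inferential: the boolean verdict uses a strict
$p < \alpha$, and p-values in $[.04, .06]$ are flagged borderline so a
reader can see how much hangs on the cut. The test is undefined for
$n < 3$ or zero variance; those series report `NA` and are treated as
"no evidence of non-normality" downstream.

Two series are compared with the Welch statistic

$$t = \frac{|\bar{x}_l - \bar{x}_m|}{\tilde{\sigma}}, \qquad
  \tilde{\sigma} = \sqrt{\mathrm{SEM}_l^2 + \mathrm{SEM}_m^2},$$

with no equal-variance assumption — appropriate because observed
per-series SDs range from exactly 0 (a unit pinned at the normalization
ceiling) to several RSV units. $t$ is reported as a magnitude: confidence
is symmetric in the pair, so a one-sided reading would be incoherent.
Degenerate variances get a deterministic convention: $\tilde\sigma = 0$
with equal means is perfect confidence ($t = 0$); with distinct means,
perfect distinguishability ($t = \infty$).

A pair with $t < 1.5$ is **confident** — indistinguishable under the
screen. The 1.5 cut has no distributional derivation; it is a heuristic
screening constant and is exposed as a configurable parameter. For the
dataset verdict, each series' *confident fraction* is the share of its
$N - 1$ partners it is confident with, and the dataset is **unreliable**
when any fraction strictly exceeds 20%. The per-series (rather than
per-pair) denominator is the design choice that makes per-unit figures
reportable ("this city is interchangeable with 27% of the others"); no
multiple-testing correction is applied across the $N(N-1)/2$ pairs
because the screen is a reliability heuristic, not hypothesis-wise
inference.

## Correlation stability

For each collection day the units present in that pull (and matched in
the external series) are correlated — Pearson or Spearman with average
ranks, the standard tie convention for integer RSVs — against one fixed
external value per unit. The external value is a single per-unit total
over the investigation period; no per-day case alignment is attempted.
Days joining fewer than 3 units, or where either vector is constant,
are skipped and listed with reasons rather than contributing an
undefined coefficient.

Drift is summarized with the percentage increase
$\Delta = (u_f - u_0)/u_0 \cdot 100$. Applied to an unordered range
$[a, b]$, the baseline $u_0$ is the endpoint of *smaller magnitude* — the
only convention under which a range like $[0.04, 0.29]$ yields the large
drift (+625%) such a range actually represents. A zero baseline leaves
$\Delta$ undefined (reported as `NA` with the range still shown), and
`percent_increase()` refuses $u_0 = 0$ outright.

Outlier collection days are flagged when a coefficient lies more than
$k \cdot \mathrm{MAD}$ (scaled by 1.4826; default $k = 3$) from the
median. This rule is a package extension — declared as such in the
printed reports — because a trimmed "more representative" range needs
*some* explicit rule, and median ± 3 MAD is the robust-statistics
default. It needs at least 5 retained days; below that the flagging is
skipped with a notice, since a MAD on four points flags nothing
meaningful.

## The collection protocol

The protocol engine turns the recommendations into a state machine fed
one pull a day:

1. **Monitoring.** The streak of stable days grows by one for each
   complete column whose values do not jump "dramatically", and resets to
   zero otherwise. *Dramatic* is operationalized as a change of more than
   10 RSV units against the series' running mean — stable grids in
   practice fluctuate within roughly ±5, so 10 separates routine noise
   from regime change; the threshold is configurable. The jump is
   compared strictly (a jump of exactly 10 is tolerated), and the first
   observation of a series is never dramatic. The 7 stable days must be
   *consecutive* — streak semantics — since a stability claim interrupted
   by an anomaly is no stability claim.
2. **Extending.** After `min_stable_days = 7`, collection continues.
3. **Concluding.** The dataset concludes *reliable* when the confidence
   screen on everything collected is reliable **and** either every series
   screens normal or at least `min_extractions_nonnormal = 30` pulls have
   been made (the central-limit argument for trusting means and CIs
   regardless of shape). The report publishes per-series means with 95%
   CIs — by construction identical to `summarize_series()` on the
   accumulated matrix — and embeds a day-by-day correlation trace when an
   external series is supplied. Phases only move forward; a concluded
   state refuses further ingestion.

## The synthetic generator

`synthetic_truth()` encodes the package's idealization of the provider's
mechanism: per-unit latent interest $\mu_i > 0$ with daily Gaussian
noise $\sigma_i$, floored at 0; **per-day max-normalization** of each
column to exactly 100; per-cell deletion with probability `anomaly_prob`;
optional integer quantization. Per-day (not global) normalization is the
essential modelling choice: it is what couples every unit's observed
value to whichever unit happened to draw the day's maximum, and therefore
what makes single-day snapshots unstable — the phenomenon the audit
exists to detect. The pseudo-random stream is consumed in a documented
order (per day: unit draws, then deletion draws), so a seed pins a matrix
bit-for-bit within this implementation; cross-implementation equality is
not promised.

Two consequences are worth knowing. First, the unit that usually attains
the daily maximum is pinned at 100, compressing its observed SD toward
zero regardless of its true $\sigma$ — so $\sigma$-recovery checks hold
for *most* units by design, never necessarily for the dominant one.
Second, integer quantization interacts with small $\sigma$: rounding
$N(\mu, 1)$ to integers concentrates mass on two or three values and the
Shapiro–Wilk screen rightly balks. Scenario SDs are therefore kept
comfortably above the quantization step (the designed-reliable
`separated` scenario uses $\sigma = 2.5$).

Named scenarios freeze the study conditions: `regions_p1` (20 units,
15 days, $\sigma_i$ spread over $[6.6, 7.6]$, latent means spread
82–100, no missingness) emulates a high-variance, anomaly-free regional
panel; `regions_p2` the same panel at much lower variance (SDs 1.3–2.1,
19 days); `cities_p1` (24 units × 13 days, per-cell missingness 0.25)
the heavily anomalous city grids; `world_p1` (62 units, one dominant
reference unit pinned at 100 with zero observed SD, per-cell missingness
0.0078 so that $1-(1-p)^{13} \approx 0.097$ of series are anomalous) a
world-countries panel. `two_cluster`, `coincident` and `separated` are
designed verdict cases: identical-mean clusters are confident within and
hence unreliable; fully separated means (gaps of ~20 RSV units against
Welch standard errors well under 1) are reliable. Latent-mean layouts
where no published figure constrains them were fixed once on analytic
grounds (spacing relative to $\tilde\sigma$, dominance margins for the
pinned unit) and are not tuning knobs.

What the generator does **not** emulate: media-event shocks, query-mix
drift, provider-side algorithm changes, or any spatial correlation
between units' interests. Tests passing on synthetic data therefore
demonstrate the statistical machinery, not that real pull streams are
Gaussian — the bundled December-2020 grids exist precisely because the
real mechanism is unobservable.

## Numerical choices and test scale

Thresholds compare strictly (`>` for exclusion and unreliability, `<` for
confidence); boundary cases are pinned by unit tests. The day-column
maximum is set to 100 exactly after scaling, avoiding a
floating-point-ulp violation of the normalization invariant. JSON reports
serialize doubles at 17 significant digits so a written report re-reads
bit-identically.

The test suite's stochastic checks use deliberately modest sizes — the
pairwise-confidence oracle on 200 random matrices up to 8×8,
$\sigma$-recovery over 100 seeded 20-unit replicates of 30 pulls,
missingness calibration on 1000–2000 units — sizes at which the binomial
bounds asserted are already sharp. The bundled grids (the audit's
real-world anchors) are tiny and deterministic.

One caveat on the bundled world-city grids: their straightforward
anomalous-series rates (8/22 and 9/21) differ from the rates quoted
alongside the original tabulations (30.4%, 38.1%), whose denominator is
not reconstructible from the printed rows. The package reports what the
definition yields on the data it ships.

## Limitations

The audit is a screen, not a test: the 1.5 Welch cut and 20% thresholds
are conventions, and no p-values accompany the day-by-day correlations —
deliberately, since anomalies invalidate their sampling assumptions. The
external series is a single total per unit; lagged or per-day case
alignment is out of scope. The protocol assumes pulls arrive in calendar
order and treats the 7-day stability window as consecutive; gaps in
collection restart the clock.
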