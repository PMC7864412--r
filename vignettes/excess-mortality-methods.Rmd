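---
title: "Reference-level methods for weekly excess mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-level methods for weekly excess mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmfexcess)
```

## The problem

Epidemics, heat waves and other short-term shocks raise all-cause mortality in
ways that cause-of-death statistics capture late and inconsistently across
countries. Excess mortality — the difference between observed weekly deaths
(or weekly death rates) in a *target year* and a *reference level* of expected
mortality — is the standard objective measure. The hard part is the reference
level: what would mortality have been in week $i$ under usual conditions?

`stmfexcess` works on weekly mortality tables in the STMF (Short-term
Mortality Fluctuations) CSV dialect: one row per (country, ISO year, ISO week,
sex), with death counts and weekly death rates (deaths per person-week) for
age groups 0–14, 15–64, 65–74, 75–84, 85+ and the total. Let $x_{ij}$ denote
the selected measure in week $i$ of year $j$, $T$ the target year, $P$ the
user-chosen reference period (a set of years, which may include $T$), $W$ the
set of weeks available in the target year.

## The six reference levels

Three baselines vary by week and compare the target year with the experience
of previous years:

* **Week-specific average** (`wsa`): $\bar x_i = \sum_{j \in P} x_{ij} / |P|$,
  the per-week mean over the reference years. This is the baseline used by
  most national statistical offices and data journalism teams.
* **Week-specific trend** (`wst`): $\hat x_i = \hat a_i + \hat b_i T$, where
  $(\hat a_i, \hat b_i)$ come from an independent ordinary-least-squares
  regression of $x_{ij}$ on calendar year $j$, one regression per week. This
  absorbs sustained mortality trends (e.g. the steep declines seen in parts
  of Eastern Europe) that bias the plain average.
* **Week-specific lower quartile** (`wsq`):
  $x_i^{Q1} = \text{mean}\{x_{ij} : j \in L_i\}$ with
  $L_i = \{j \in P : x_{ij} \le Q_1(\{x_{ij}\}_{j \in P})\}$ — the mean of the
  low-mortality years for that week. Membership uses $\le$, so values tied
  with the quartile are included.

Three baselines are week-constant within-year "seasonality" references:

* **Yearly average-week** (`yaw`): $\bar x = \sum_{i \in W} \bar x_i / |W|$,
  the flat line a year would have if every week had the average level.
* **Summer average-week** (`saw`): the same mean restricted to non-winter
  weeks $W^*$. Winter is weeks 1–12 and 48–52 in the Northern Hemisphere and
  weeks 22–38 in the Southern; since winter mortality is usually elevated,
  $\bar x^* \le \bar x$ in typical data.
* **Yearly lower-quartile-week** (`ylq`): one lower quartile over *all* values
  $x_{ij}$, $j \in P$, pooled across weeks; the constant level is the mean of
  the pooled values at or below it — a data-driven "low-mortality season"
  reference.

All quartiles use the type-7 linear-interpolation estimator
(`quantile_linear()`): with order statistics $x_{(1..n)}$ and
$h = 1 + (n-1)p$, the quantile is
$x_{(\lfloor h \rfloor)} + (h - \lfloor h \rfloor)(x_{(\lceil h \rceil)} -
x_{(\lfloor h \rfloor)})$, the default of mainstream statistical software.

No confidence intervals are produced for any of these quantities; the six
baselines are deliberately simple, transparent definitions, and the spread
across them is itself the intended sensitivity display.

## Excess, polygons and summaries

`excess_mortality()` differences the target year's observed values against the
chosen level, week by week, exactly. Maximal runs of consecutive available
weeks with a uniformly positive (excess) or negative (deficit) difference form
*polygons*, reported with start week, end week and length. Three conventions
are worth making explicit:

* a week with a difference of exactly zero belongs to no polygon and splits
  runs (zero differences are measure-theoretically negligible in real data,
  but a convention has to be fixed);
* polygon boundaries are whole weeks — no sub-week interpolation of the
  crossing point;
* a gap in the available weeks also terminates a run.

`summarize_selection()` totals a user-chosen week window: **sums** for death
counts, **unweighted means** for death rates (exposures are not part of the
data model, so person-week weighting is not attempted). Weeks of the window
that are unavailable in the result are excluded and reported.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `reference_years` | up to 7 years preceding `target_year` | common practice is a 4–7-year reference period before the target year; the cap keeps the default off very old regimes |
| `hemisphere` | lookup by country code, default `"north"` | determines the winter/summer split for `saw`; a small bundled list marks known southern STMF codes (AUS, CHL, NZL\_\*, ZAF), overridable |
| `p` in the quartile | 0.25 | lower quartile by definition of the two quartile baselines |

## Numerical choices and degenerate inputs

* **Week 53.** Most ISO years have 52 weeks. When the target year has week 53
  but too few reference years contain it (fewer than one observation for the
  average/quartile baselines, fewer than two for the trend), the week-52
  reference observations are carried forward and the week is flagged in
  `diagnostics$week53_fallback`. Dropping the week would silently truncate
  the final week of 53-week target years such as 2020.
* **Ragged reference data.** Real series start mid-history; per-week
  denominators use the number of years actually observed, not $|P|$, and a
  message reports the shortfall.
* **OLS parameterization.** The per-week regressions are fitted with a
  centered year covariate for numerical stability and reported in the
  calendar-year parameterization ($\hat a_i$, $\hat b_i$). A week whose
  reference values are exactly constant short-circuits to a slope of exactly
  zero, so a constant series yields identically zero differences (and hence
  no spurious polygons) under every method.
* **Quartile ties.** All values equal to the quartile are included in the
  lower set, per the $\le$ in the definition.
* **Nearest-point lookup** normalizes each axis by its data range before
  taking Euclidean distance; exact ties resolve to the earlier year, then the
  earlier week.

## The synthetic generator

`generate_stmf()` emits STMF-format tables from a known truth:

$$\mu_{ij} = (\alpha + \beta\,(j - j_0))\,
  \bigl(1 + \gamma \cos(2\pi (i - \phi)/52)\bigr),$$

a linear annual trend times cosine seasonality peaking at week $\phi$
(default 2, so northern winters are elevated and the `saw`-vs-`yaw` ordering
is exercised). An optional shock adds a known total $K$ of deaths over a week
window, allocated flat or triangularly; `ground_truth_excess()` returns the
exact mass in any window. Noise is either none (counts equal $\mu_{ij}$) or
Poisson. Age groups split the total in fixed proportions
(0.005, 0.105, 0.15, 0.27, 0.47 — a plausible elderly-heavy split, chosen
once and documented as arbitrary); rates divide by a constant person-week
population. Years with 53 ISO weeks get week 53 with the week-52 seasonal
factor, which exercises the fallback path above.

What the generator emulates: the trend, seasonality and epidemic-shock
structure the baselines assume, in the exact file schema. What it does not
emulate: reporting delays and revisions, demographic drift in the age
composition, exposure changes within a year, or country-specific data-quality
artifacts. Passing tests on synthetic data therefore validate the estimators'
algebra and the pipeline's bookkeeping, not the epidemiological adequacy of
any particular baseline for a given country.

The default validation sizes — 200 random ragged instances of up to 10 years
by 52–53 weeks for estimator cross-checks, 200 Poisson replicates for
stochastic recovery, 500 random difference vectors for polygon algebra — are
large enough for the checks to be meaningful yet complete in seconds.

## Design choices where the design was open

* **Quantile estimator**: type-7, matching the default of the statistical
  environment this class of tools is built in.
* **Lenient reading drops, never imputes**: every estimator defines its own
  behavior for missing weeks, so imputation at the I/O layer would blur
  responsibilities.
* **Rates summarized by unweighted means**, consistent with "mean of the
  rates" semantics and the absence of exposures in the schema.
* **Week-53 seasonal factor = week-52 factor** in the generator: the simplest
  choice that keeps $\mu$ well-defined for long years.
* **CLI as a thin wrapper**: `exec/stmf-excess` parses flags and calls the
  same exported functions the tests exercise, which is what makes
  CLI-vs-library bit-identity testable.

## Known limitations

* No confidence limits, by design; the baselines are descriptive.
* No additional baseline families (Serfling-type regression, Poisson GLMs,
  splines); the `reference_level` dispatcher is the extension point.
* Hemisphere assignment is a lookup with a northern default; users of
  southern-hemisphere regions not in the list must pass
  `hemisphere = "south"` explicitly.
* ISO week labels are taken as given; no date arithmetic or week re-alignment
  across countries is performed.
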