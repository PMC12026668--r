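---
title: "Quantifying vaccination-status discrimination from composite policy indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vaccination-status discrimination from composite policy indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

During 2021 and 2022 many governments applied different pandemic-response
rules to vaccinated and non-vaccinated residents: venue access, gathering
limits, transport, curfews. Policy-surveillance panels such as the Oxford
COVID-19 Government Response Tracker (OxCGRT) recorded the extent of each
policy as a daily ordinal code per country, and from some point in 2021
onward recorded separate codes for the two status groups wherever a
jurisdiction differentiated. This package turns that differentiation into a
single daily country-level quantity — a discrimination index — and carries
out the downstream analysis: per-country summaries, rankings, a
zero-discrimination partition, regional grouping, equal-interval
classification for choropleth maps, and timeline tables.

## From ordinal codes to composite indices

Each indicator $j$ has an ordinal code $v_j \in \{0, \dots, N_j\}$ and, for
most indicators, a binary scope flag $f_j$ (1 = nationwide, 0 = targeted to
a specific region). The sub-index score is

$$
s_j = \begin{cases}
  0 & v_j = 0 \\
  100\,\big(v_j - 0.5\,(1 - f_j)\big) / N_j & \text{flagged indicators} \\
  100\, v_j / N_j & \text{unflagged indicators.}
\end{cases}
$$

The half-step deduction compensates for codes being assigned from the
strictest subnational policy: a regionally targeted measure counts half a
step less than a nationwide one, so for fixed positive code the targeted
score is lower by exactly $50 / N_j$ points. A composite index is the
unweighted mean of its members' sub-indices: 14 members (C1–C8, H1, H2, H3,
H6, H7, H8) for the Containment and Health Index (CHI), 9 members (C1–C8,
H1) for the Stringency Index. Ten indicators — C1–C8, H6 and H8 — carry
separate vaccinated / non-vaccinated codes during differentiation periods.
Both composite indices are therefore computed per status group: a
differentiated indicator contributes its group-specific code where one is
recorded for that day and the shared code otherwise, and non-differentiated
indicators contribute identically to both groups.

The daily discrimination index for a country is

$$
D(t) = \mathrm{Index}_{\mathrm{non\text{-}vaccinated}}(t) -
       \mathrm{Index}_{\mathrm{vaccinated}}(t),
$$

computed on the CHI basis by default (it contains all ten differentiated
indicators); the Stringency basis yields the same zero/non-zero pattern at
overall higher magnitudes whenever differentiation is confined to the C
indicators, because the same numerator is divided by 9 instead of 14.

## Parameters that matter

* **Index basis** (`"CHI"` default, `"STRINGENCY"`): which composite the
  difference is taken on. Values are points on the 0–100 index scale.
* **Study window**: the closed interval 2021-01-01 to 2022-12-31
  (730 days; neither year has a leap day). The two annual files are
  stacked onto one continuous axis, and `stack_years()` treats any overlap
  or gap at the year seam as a hard error.
* **Summary denominators**: per-country mean, median and maximum of
  $D(t)$ are taken over *all* 730 days, including the pre-differentiation
  zeros. The mean therefore blends duration with magnitude — it is the
  headline ranking statistic — while medians are frequently zero.
* **`mean_chi_basis`**: the "underlying CHI" attached to each country
  summary is the non-vaccinated-basis series averaged over the window by
  default. The alternative (`"average"` of the two groups) is available;
  for zero-discrimination countries the two choices coincide, so the
  partition contrast is unaffected.
* **Classification domains**: five equal-interval classes over
  $[0, 20]$ for two-year averages and $[0, 40]$ for maxima, matching
  common choropleth legend conventions for this metric. Intervals are
  left-open/right-closed with the first class closed at the lower bound
  (a value exactly on a boundary belongs to the class below). Values
  outside the domain are an error, never silently clipped — a legend that
  cannot hold the data should be widened explicitly.
* **H7 flag toggle** (`default_codebook(h7_flag = )`): H7's companion
  variable records cost rather than geographic scope; it participates in
  the flag arithmetic by default and can be excluded.

## Numerical and design choices

* Internal arithmetic is kept at full double precision; rounding to two
  decimals happens only at export boundaries (`write_tidy()`,
  `write_panel_csv()`) and when comparing against published index columns
  (tolerance 0.01, the precision those columns are distributed at).
* Missing cells in wide panels are carried as *absent* observations, not
  imputed to zero; a day on which a composite's member is absent is a
  hard error in strict mode, and `partial = TRUE` averages over present
  members with a warning naming the affected country-days. Strictness is
  the default because a complete panel is an input contract worth
  noticing violations of. A flag missing on a positive code is treated as
  nationwide (no deduction) by the series builder.
* Negative $D(t)$ — the vaccinated group more restricted — is possible in
  principle; it is preserved and surfaced with a warning, never clamped.
* Ranking ties are broken by country code so rankings are a deterministic
  permutation; duplicate observations that agree are de-duplicated while
  contradictory duplicates are fatal.
* OLS associations between per-country statistics use the standard linear
  model slope test; a zero-variance predictor is an error (the fit is
  undefined), and a constant response reports $R^2 = 0$.
* The wide-file column dialect (variant suffixes `NV`/`V`/`M` on
  indicator columns, `_Flag` companions, `ContainmentHealthIndex_*` /
  `StringencyIndex_*` index columns) is isolated in one mapping object so
  other archive dialects can be accommodated without touching the
  parser.

## The synthetic study

The generator exists so the entire pipeline is testable without any
download, with *known* injected effects. A country profile fixes constant
baseline codes and flags plus discrimination episodes; during an episode
the non-vaccinated group's codes for chosen differentiated indicators are
raised by fixed deltas (clamped at each indicator's maximum) while the
vaccinated group stays at baseline. A closed-form oracle
(`expected_index()`) evaluates the composite indices directly from a
profile — without passing through the panel representation — so the
pipeline's output can be checked for exact equality, day by day, and
injected mean/max discrimination can be recovered to machine precision
(`recovery_report()`).

The default study ships thirteen countries across six continents with
onsets from late January 2021 to mid-March 2022, magnitudes from
"always below 5" to a sustained peak of about 36 index points held to
year-end, and two zero-discrimination countries — one with tight but
undifferentiated policies, one with lax policies throughout — so that
partition, ranking, grouping and timeline behaviour are all exercised.
Episode onsets can be jittered uniformly by up to a chosen number of days
under an explicit seed; everything else is deterministic, and the default
is fully deterministic.

What the generator deliberately does **not** emulate: epidemiological
covariates (cases, vaccination coverage), gradual code ramps within an
episode, subnational variation, or recording noise. Passing the recovery
tests therefore demonstrates that the arithmetic pipeline is exact and
self-consistent, not that real archive data are accurate; on real panels
the published index columns serve as the external cross-check
(agreement within 0.01 on the synthetic round-trip, where the embedded
columns are produced by the oracle).

Problem sizes used throughout the shipped analyses and tests: 13
countries × 730 days for the full study (about 150,000 observations),
ten-day windows for unit tests, and 1,000 random profiles for the
boundedness/antisymmetry fuzz.

## Known limitations

* The discrimination index weights all member indicators equally; a
  severity weighting would require normative judgements this package
  deliberately avoids.
* Group-specific index values only exist where the source panel records
  differentiation; policies enforced without being recorded are invisible
  to the metric, and the definition of "vaccinated" follows each
  country's own stipulations.
* The equal-interval class bounds are a display convention, not a
  statistical classification; alternative breaks (quantiles, natural
  breaks) are out of scope.
* Display smoothing used by some published index variants is not
  implemented; the analysis operates on plain daily values.
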