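# discrimindex

Quantifies, per country and day, how much tighter pandemic-response
policies were for non-vaccinated than for vaccinated residents during
2021–2022, using OxCGRT-style daily policy panels. The package is aimed at
public-health and policy researchers who want the metric, its per-country
summaries and rankings, the map-ready classifications and the timeline
tables as one tested, reproducible pipeline — plus a synthetic-panel
generator with a closed-form oracle so every step can be verified without
downloading any archive.

## The metric

Each policy indicator *j* (school closing, gathering limits, …) is a daily
ordinal code *v<sub>j</sub>* ∈ {0, …, *N<sub>j</sub>*}, usually with a
binary scope flag *f<sub>j</sub>* (1 = nationwide, 0 = regionally
targeted). Its sub-index is

```
s_j = 0                                 if v_j = 0
s_j = 100 (v_j − 0.5 (1 − f_j)) / N_j   if flagged
s_j = 100 v_j / N_j                     if unflagged
```

The Containment and Health Index (CHI) is the unweighted mean of 14
sub-indices (C1–C8, H1, H2, H3, H6, H7, H8); the Stringency Index averages
9 (C1–C8, H1). Ten indicators (C1–C8, H6, H8) carry separate codes for
vaccinated and non-vaccinated people while a jurisdiction differentiates,
so both composites exist per status group, and the daily discrimination
index is

```
D(t) = CHI_NonVaccinated(t) − CHI_Vaccinated(t)
```

(on the Stringency basis analogously). Per-country mean / median / maximum
of D over the full 730-day window, rankings, the zero-discrimination
partition, OLS associations, five-class equal-interval map tables and
regional timelines follow from there.

## Worked example

One country with baseline policies (C2 = 1, H1 = 2, nationwide) that
raises C2 by two steps and C4 by three steps for the non-vaccinated group
from 2021-10-01 to 2022-11-30:

```r
library(discrimindex)
cb <- default_codebook()

subindex(3, 1, max_code = 3, has_flag = TRUE)   # 100
subindex(3, 0, max_code = 3, has_flag = TRUE)   # 83.33333 (regional penalty)

prof <- country_profile("AZE", "Asia", "Western Asia", "Azerbaijan",
  baseline = c(C2 = 1L, H1 = 2L),
  episodes = list(episode("2021-10-01", "2022-11-30", c(C2 = 2L, C4 = 3L))))
obs <- generate_panel(list(prof), codebook = cb)
idx <- build_index_series(obs, cb, "CHI")
d   <- discrimination_from_indices(idx)
s   <- summarize_countries(d, idx)
s
#> # A tibble: 1 × 9
#>   country_code country_name continent sub_region mean_d median_d max_d mean_chi
#>   <chr>        <chr>        <chr>     <chr>       <dbl>    <dbl> <dbl>    <dbl>
#> 1 AZE          Azerbaijan   <NA>      <NA>         5.91     10.1  10.1     15.4

equal_interval_classes(setNames(s$mean_d, s$country_code), 5, 0, 20)
#> # A tibble: 1 × 5
#>   country_code value class_index lower upper
#>   <chr>        <dbl>       <int> <dbl> <dbl>
#> 1 AZE           5.91           2     4     8
```

Reading: during the episode the extra C2 steps score 100·(3−0)/3 −
100·(1−0)/3 = 66.7 points and the C4 steps 100·(3−0)/4 = 75 points, so
D = (66.7 + 75)/14 ≈ 10.12 daily; averaged over all 730 days (426 episode
days) the mean is 5.91, which lands in the second of five equal classes on
the [0, 20] map domain. The median equals the peak here because the
episode covers more than half the window.

## The analysis workflow

`analysis/01_simulate.R` … `05_maps_timelines.R` run the full study on the
shipped deterministic synthetic panel: simulate and serialise the wide
annual files, re-parse and rebuild the indices (cross-checked against the
files' embedded index columns to 0.01), stack the years and form D,
summarise/rank/partition/associate with an exact parameter-recovery check,
and classify and group for maps and timelines. Compact tables land in
`results/`, bulky daily series in `scratch/`.

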