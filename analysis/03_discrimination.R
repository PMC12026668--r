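#!/usr/bin/env Rscript
# Step 3 — the discrimination index.
#
# Builds each annual file's per-group CHI series separately, stacks the
# two years onto one continuous 730-day axis, and subtracts the
# vaccinated from the non-vaccinated series to obtain the daily
# discrimination index per country. Daily values go to scratch (they are
# bulky); results/ keeps a monthly-mean table compact enough to read.

library(discrimindex)

cb <- default_codebook()
files <- file.path("scratch/data",
                   sprintf("synthetic_national_%d_v1.csv", 2021:2022))
annual <- lapply(files, function(f) {
  build_index_series(read_policy_panel(f, cb)$observations, cb, "CHI")
})
idx <- stack_years(annual[[1]], annual[[2]])
stopifnot(length(unique(idx$date)) == 730)

d <- discrimination_from_indices(idx)
message("stacked ", length(unique(d$country_code)), " countries x ",
        length(unique(d$date)), " days")

write_tidy(d, "scratch/discrimination_daily.csv")

monthly <- d |>
  dplyr::mutate(month = format(date, "%Y-%m")) |>
  dplyr::group_by(country_code, country_name, month) |>
  dplyr::summarise(mean_d = mean(d), max_d = max(d), .groups = "drop")
write_tidy(monthly, "results/discrimination_monthly.csv")

peak <- d |>
  dplyr::group_by(country_code) |>
  dplyr::summarise(peak = max(d), first_nonzero = dplyr::first(date[d > 0]),
                   .groups = "drop")
message("first differentiation dates and peaks:")
print(peak[order(peak$first_nonzero), ], n = Inf)
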