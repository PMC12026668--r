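#!/usr/bin/env Rscript
# Step 1 — build the synthetic study.
#
# Thirteen countries across six continents with known, injected
# vaccination-status differentiation episodes (varied onsets January 2021
# through March 2022, two countries with none at all). The panel is
# serialised as two annual wide CSVs in the archive dialect — including
# pre-computed index columns derived from the closed-form oracle — plus a
# countries-by-continent lookup, so the downstream steps exercise the
# same file-based path a real archive analysis would.

library(discrimindex)

data_dir <- "scratch/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

cb <- default_codebook()
profs <- default_profiles()
win <- study_window()

message("generating panel for ", length(profs), " countries, ",
        win[1], " .. ", win[2])
obs <- generate_panel(profs, win, cb)

# oracle-derived pre-computed index columns (both bases, both groups)
dates <- seq(win[1], win[2], by = "day")
pub <- dplyr::bind_rows(lapply(profs, function(p) {
  dplyr::bind_rows(lapply(c("CHI", "STRINGENCY"), function(basis) {
    dplyr::bind_rows(lapply(c("non_vaccinated", "vaccinated"), function(g) {
      tibble::tibble(
        country_code = p$country_code, date = dates,
        index_name = basis, status_group = g,
        value = vapply(dates, function(day)
          expected_index(p, day, basis, g, cb), numeric(1)))
    }))
  }))
}))

for (yr in c(2021, 2022)) {
  in_year <- format(obs$date, "%Y") == yr
  path <- file.path(data_dir, sprintf("synthetic_national_%d_v1.csv", yr))
  write_panel_csv(obs[in_year, ], path, cb,
                  indices = pub[format(pub$date, "%Y") == yr, ])
  message("wrote ", path, " (", sum(in_year), " observations)")
}

regions <- synthetic_regions()
readr::write_csv(regions, file.path(data_dir, "countries_by_continent.csv"))

# compact study overview: injected design plus oracle summaries
overview <- dplyr::bind_rows(lapply(profs, function(p) {
  ed <- expected_discrimination(p, win, "CHI", cb)
  onset <- if (length(p$episodes)) min(as.Date(vapply(
    p$episodes, function(e) format(e$start), ""))) else as.Date(NA)
  tibble::tibble(
    country_code = p$country_code, country_name = p$country_name,
    continent = p$continent, sub_region = p$sub_region,
    n_episodes = length(p$episodes), onset = onset,
    oracle_mean_d = mean(ed$d), oracle_max_d = max(ed$d))
}))
write_tidy(overview, "results/study_overview.csv")
message("study overview (oracle values):")
print(overview[order(-overview$oracle_mean_d), ], n = Inf)
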