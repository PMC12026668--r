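# Small in-code fixtures shared across test files.

# ten-day window keeps unit tests fast; the full 730-day window is only
# exercised where the property under test needs it
mini_window <- function() as.Date(c("2021-01-01", "2021-01-10"))

# one country, one episode raising C4 to 4 (flag 1) on days 4..7
mini_profile <- function() {
  country_profile(
    "AAA", "Testland", "Test Region", "Alphaland",
    baseline = c(H1 = 2L),
    episodes = list(episode("2021-01-04", "2021-01-07", c(C4 = 4L), flag = 1))
  )
}

# a quiet second country with no episodes
quiet_profile <- function() {
  country_profile("BBB", "Testland", "Other Region", "Betaland",
                  baseline = c(C1 = 1L, H2 = 1L))
}

mini_regions <- function() {
  tibble::tribble(
    ~country_name, ~iso3, ~sub_region, ~continent,
    "Alphaland", "AAA", "Test Region", "Testland",
    "Betaland", "BBB", "Other Region", "Testland"
  )
}

# index series for hand-built daily values
make_series <- function(code, values, dates, group = "non_vaccinated",
                        index_name = "CHI") {
  tibble::tibble(country_code = code, country_name = code,
                 index_name = index_name, status_group = group,
                 date = dates, value = values)
}
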