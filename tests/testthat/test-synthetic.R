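test_that("closed-form oracle evaluates worked single-indicator examples", {
  cb <- default_codebook()
  # all-zero baseline scores 0 for both groups on both bases
  empty <- country_profile("AAA", "X", "Y")
  expect_equal(expected_index(empty, "2021-06-01", "CHI", "non_vaccinated"), 0)
  expect_equal(expected_index(empty, "2021-06-01", "STRINGENCY", "vaccinated"), 0)

  # NV C1 = 3 vs V C1 = 1 (flag 1): D = (100 - 100/3)/14 on the CHI basis,
  # (100 - 100/3)/9 on the Stringency basis
  p <- country_profile("AAA", "X", "Y", baseline = c(C1 = 1L),
                       episodes = list(episode("2021-06-01", "2021-06-30",
                                               c(C1 = 2L), flag = 1)))
  day <- as.Date("2021-06-15")
  d_chi <- expected_index(p, day, "CHI", "non_vaccinated") -
    expected_index(p, day, "CHI", "vaccinated")
  expect_equal(d_chi, (100 - 100 / 3) / 14)          # 4.76
  d_si <- expected_index(p, day, "STRINGENCY", "non_vaccinated") -
    expected_index(p, day, "STRINGENCY", "vaccinated")
  expect_equal(d_si, (100 - 100 / 3) / 9)            # 7.41

  # episode raising C4 to 4 (flag 1) for 73 of 730 days: mean D = 0.714
  p73 <- country_profile("AAA", "X", "Y",
    episodes = list(episode("2021-01-01", "2021-03-14", c(C4 = 4L), flag = 1)))
  ed <- expected_discrimination(p73, study_window(), "CHI", cb)
  expect_equal(nrow(ed), 730)
  expect_equal(mean(ed$d), (100 / 14) * (73 / 730))
  expect_equal(max(ed$d), 100 / 14)
})

test_that("generated panels satisfy the observation contract", {
  cb <- default_codebook()
  win <- mini_window()
  obs <- generate_panel(list(mini_profile(), quiet_profile()), win, cb)

  # codes within range, flags present exactly for flagged positive codes
  mx <- setNames(cb$max_code, cb$id)
  hf <- setNames(cb$has_flag, cb$id)
  expect_true(all(obs$code >= 0 & obs$code <= mx[obs$indicator]))
  expect_identical(!is.na(obs$flag), unname(hf[obs$indicator]) & obs$code > 0L)

  # no-episode profile has no differentiated rows
  expect_setequal(obs$status_group[obs$country_code == "BBB"], "shared")
  # episode rows exist for both explicit groups on episode days only
  nv <- obs[obs$status_group == "non_vaccinated", ]
  expect_setequal(as.character(nv$date),
                  as.character(seq(as.Date("2021-01-04"),
                                   as.Date("2021-01-07"), by = "day")))
  expect_equal(unique(nv$indicator), "C4")
  expect_true(all(nv$code == 4L))

  # an episode on a non-differentiated indicator is rejected
  bad <- country_profile("CCC", "X", "Y",
    episodes = list(episode("2021-01-02", "2021-01-03", c(H7 = 1L))))
  expect_error(generate_panel(list(bad), win, cb), "non-differentiated")
})

test_that("deltas clamp at max_code consistently in panel and oracle", {
  cb <- default_codebook()
  win <- mini_window()
  p <- country_profile("AAA", "X", "Y", baseline = c(C6 = 3L),
    episodes = list(episode("2021-01-02", "2021-01-09", c(C6 = 2L), flag = 1)))
  obs <- generate_panel(list(p), win, cb)
  nv <- obs[obs$status_group == "non_vaccinated", ]
  expect_true(all(nv$code == 3L))  # clamped at C6 max
  day <- as.Date("2021-01-05")
  # NV equals V: both groups sit at the max, so recovered D reflects the clamp
  expect_equal(expected_index(p, day, "CHI", "non_vaccinated"),
               expected_index(p, day, "CHI", "vaccinated"))
})

test_that("panel generation is deterministic and jitter is seed-reproducible", {
  cb <- default_codebook()
  win <- mini_window()
  profs <- list(mini_profile())
  expect_identical(generate_panel(profs, win, cb), generate_panel(profs, win, cb))

  j1 <- generate_panel(profs, win, cb, jitter_days = 2, seed = 11)
  j2 <- generate_panel(profs, win, cb, jitter_days = 2, seed = 11)
  expect_identical(j1, j2)
  expect_error(generate_panel(profs, win, cb, jitter_days = 2), "seed")
})

test_that("pipeline discrimination equals the oracle exactly for every country-day", {
  cb <- default_codebook()
  # trimmed window keeps this cheap while covering onset, clamp and overlap
  win <- as.Date(c("2021-01-01", "2021-03-31"))
  profs <- list(
    mini_profile(), quiet_profile(),
    country_profile("CCC", "X", "Y", baseline = c(C2 = 1L, H6 = 2L),
      episodes = list(episode("2021-01-10", "2021-02-20", c(C2 = 2L, H6 = 2L)),
                      episode("2021-02-01", "2021-03-15", c(C2 = 1L, C5 = 1L))))
  )
  obs <- generate_panel(profs, win, cb)
  for (basis in c("CHI", "STRINGENCY")) {
    d <- discrimination_from_indices(build_index_series(obs, cb, basis))
    oracle <- dplyr::bind_rows(lapply(profs, expected_discrimination,
                                      window = win, index_name = basis,
                                      codebook = cb))
    merged <- dplyr::inner_join(d, oracle, by = c("country_code", "date"))
    expect_equal(nrow(merged), nrow(d))
    expect_equal(merged$d.x, merged$d.y, tolerance = 1e-12)
  }
})

test_that("recovery report shows zero error for deterministic profiles", {
  cb <- default_codebook()
  win <- as.Date(c("2021-01-01", "2021-02-28"))
  profs <- list(mini_profile(), quiet_profile())
  obs <- generate_panel(profs, win, cb)
  d <- discrimination_from_indices(build_index_series(obs, cb, "CHI"))
  s <- summarize_countries(d, build_index_series(obs, cb, "CHI"),
                           window = win)
  rep <- recovery_report(profs, s, window = win, index_name = "CHI")
  expect_equal(nrow(rep), 2)
  expect_equal(max(rep$abs_err_mean), 0, tolerance = 1e-12)
  expect_equal(max(rep$abs_err_max), 0, tolerance = 1e-12)
  expect_equal(nrow(recovery_report(list(), s, win)), 0)
})

test_that("profiles round-trip through a YAML config", {
  profs <- list(mini_profile(), quiet_profile())
  cfg <- lapply(profs, function(p) {
    list(country_code = p$country_code, country_name = p$country_name,
         continent = p$continent, sub_region = p$sub_region,
         baseline = as.list(p$baseline),
         episodes = lapply(p$episodes, function(e) {
           list(start = format(e$start), end = format(e$end),
                deltas = as.list(e$deltas), flag = e$flag)
         }))
  })
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  got <- read_profiles(path)
  win <- mini_window()
  expect_identical(generate_panel(got, win), generate_panel(profs, win))
})

test_that("default study profiles span the study design", {
  profs <- default_profiles()
  expect_gte(length(profs), 12)
  continents <- unique(vapply(profs, `[[`, "", "continent"))
  expect_gte(length(continents), 5)
  onsets <- as.Date(unlist(lapply(profs, function(p)
    vapply(p$episodes, function(e) format(e$start), "")), use.names = FALSE))
  expect_true(min(onsets) < as.Date("2021-02-01"))   # early adopters
  expect_true(max(onsets) > as.Date("2021-12-01"))   # late adopters
  # at least one zero-discrimination country with tight and one with lax policies
  no_ep <- Filter(function(p) length(p$episodes) == 0, profs)
  expect_gte(length(no_ep), 2)
  chis <- vapply(no_ep, expected_index, numeric(1), date = "2021-06-01",
                 index_name = "CHI", status_group = "non_vaccinated")
  expect_gt(max(chis), 60)
  expect_lt(min(chis), 20)
})
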