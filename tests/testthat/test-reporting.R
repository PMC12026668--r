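test_that("equal-interval classification places boundary and interior values", {
  # k = 5 over [0, 20]: widths of 4, first class closed at 0
  cls <- equal_interval_classes(
    c(a = 0, b = 3.99, c = 4, d = 4.01, e = 10.58, f = 8, g = 20),
    k = 5, domain_min = 0, domain_max = 20)
  expect_equal(cls$class_index, c(1L, 1L, 1L, 2L, 3L, 2L, 5L))
  expect_equal(cls$lower[cls$country_code == "e"], 8)
  expect_equal(cls$upper[cls$country_code == "e"], 12)

  # k = 5 over [0, 40]: widths of 8
  cls40 <- equal_interval_classes(c(x = 38.69, y = 32, z = 32.01),
                                  k = 5, domain_min = 0, domain_max = 40)
  expect_equal(cls40$class_index, c(5L, 4L, 5L))

  # widths exactly equal and classes partition the domain
  expect_equal(unique(cls$upper - cls$lower), 4)
  all_cls <- equal_interval_classes(seq(0, 20, by = 0.5), 5, 0, 20)
  expect_setequal(all_cls$class_index, 1:5)

  # idempotence: classifying class midpoints reproduces the class
  mids <- (cls$lower + cls$upper) / 2
  expect_equal(equal_interval_classes(mids, 5, 0, 20)$class_index,
               cls$class_index)
})

test_that("classification rejects out-of-domain values and bad domains", {
  expect_error(equal_interval_classes(c(1, 21), 5, 0, 20), "outside")
  expect_error(equal_interval_classes(c(-0.1), 5, 0, 20), "outside")
  expect_error(equal_interval_classes(1, 5, 10, 10), "domain_max")
  expect_error(equal_interval_classes(1, 1, 0, 20), "k must be")
})

test_that("timeline tables filter by region and sort by country and date", {
  cb <- default_codebook()
  win <- mini_window()
  obs <- generate_panel(list(mini_profile(), quiet_profile()), win, cb)
  d <- discrimination_from_indices(build_index_series(obs, cb, "CHI"))
  joined <- join_regions(unique(d$country_code), mini_regions())

  all_tl <- timeline_table(d, joined, "none")
  expect_setequal(unique(all_tl$country_code), c("AAA", "BBB"))
  expect_equal(nrow(all_tl), 20)

  sub <- timeline_table(d, joined, "sub_region", "Test Region")
  expect_setequal(unique(sub$country_code), "AAA")
  expect_equal(order(sub$country_code, sub$date), seq_len(nrow(sub)))

  expect_error(timeline_table(d, joined, "continent", "Atlantis"),
               "valid labels: Testland")

  # label valid in the lookup but absent from the data: empty with warning
  reg_plus <- rbind(mini_regions(),
                    tibble::tibble(country_name = "Gamma", iso3 = "GGG",
                                   sub_region = "Gamma Region",
                                   continent = "Gammaland"))
  joined2 <- join_regions(unique(d$country_code), reg_plus)
  expect_warning(empty <- timeline_table(d, reg_plus, "continent", "Gammaland"),
                 "no data")
  expect_equal(nrow(empty), 0)
})

test_that("pipeline bundles are deterministic with matching manifests", {
  win <- as.Date(c("2021-01-01", "2021-02-28"))
  cfg <- list(profiles = list(mini_profile(), quiet_profile()),
              regions = mini_regions(), window = win,
              mean_domain = c(0, 20), max_domain = c(0, 40))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  b1 <- run_pipeline(c(cfg, list(out_dir = out1)))
  b2 <- run_pipeline(c(cfg, list(out_dir = out2)))
  expect_equal(unname(unlist(b1$manifest$output_md5)),
               unname(unlist(b2$manifest$output_md5)))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "summaries.csv")))

  # recovery over the bundle is exact
  rep <- recovery_report(cfg$profiles, b1$summaries, window = win)
  expect_equal(max(rep$abs_err_mean, rep$abs_err_max), 0, tolerance = 1e-12)

  # summaries carry regions; the ranking is a permutation of the summaries
  expect_setequal(b1$rank_mean$country_code, b1$summaries$country_code)
  expect_equal(b1$by_continent$n_countries, 2)
})

test_that("pipeline reads panel files and supports the published-column path", {
  cb <- default_codebook()
  win <- as.Date(c("2021-01-01", "2021-01-31"))
  prof <- mini_profile()
  obs <- generate_panel(list(prof), win, cb)
  dates <- seq(win[1], win[2], by = "day")
  pub <- dplyr::bind_rows(lapply(c("non_vaccinated", "vaccinated"), function(g) {
    tibble::tibble(country_code = "AAA", date = dates, index_name = "CHI",
                   status_group = g,
                   value = vapply(dates, function(day)
                     expected_index(prof, day, "CHI", g, cb), numeric(1)))
  }))
  panel_path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(obs, panel_path, cb, indices = pub)

  reg <- tibble::tibble(country_name = "Alphaland", iso3 = "AAA",
                        sub_region = "Test Region", continent = "Testland")
  base_cfg <- list(panel_files = panel_path, regions = reg, window = win)
  b_rec <- run_pipeline(base_cfg)
  b_pub <- run_pipeline(c(base_cfg, list(source = "published")))
  # published columns are rounded to 2 decimals at export
  expect_equal(b_pub$summaries$mean_d, b_rec$summaries$mean_d, tolerance = 0.01)
  expect_equal(b_rec$summaries$country_code, "AAA")

  # Stringency basis gives higher values than CHI on the same differentiated data
  b_si <- run_pipeline(c(base_cfg, list(basis = "STRINGENCY")))
  expect_gt(b_si$summaries$max_d, b_rec$summaries$max_d)

  expect_error(run_pipeline(list(regions = reg)), "panel_files or profiles")
})
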