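# hand-built discrimination + index series over the full 730-day window
full_dates <- function() seq(study_window()[1], study_window()[2], by = "day")

flat_chi <- function(codes, value = 40) {
  dplyr::bind_rows(lapply(codes, function(cc) {
    dplyr::bind_rows(lapply(c("non_vaccinated", "vaccinated"), function(g) {
      make_series(cc, rep(value, 730), full_dates(), g)
    }))
  }))
}

d_series <- function(code, values) {
  tibble::tibble(country_code = code, country_name = code,
                 index_basis = "CHI", date = full_dates(), d = values)
}

test_that("per-country summaries follow mean/median/max arithmetic over all days", {
  # 73 of 730 days at D = 10: mean 1, median 0 (zeros dominate), max 10
  d <- dplyr::bind_rows(
    d_series("AAA", c(rep(10, 73), rep(0, 657))),
    d_series("BBB", rep(0, 730))
  )
  s <- summarize_countries(d, flat_chi(c("AAA", "BBB")), regions = mini_regions())
  a <- s[s$country_code == "AAA", ]
  expect_equal(a$mean_d, 1)
  expect_equal(a$median_d, 0)
  expect_equal(a$max_d, 10)
  expect_true(a$discriminated)
  b <- s[s$country_code == "BBB", ]
  expect_equal(c(b$mean_d, b$median_d, b$max_d), c(0, 0, 0))
  expect_false(b$discriminated)
  # region labels joined; mini_regions has no AAA/BBB names mismatch
  expect_equal(a$continent, "Testland")
  # mean dominance invariant
  expect_true(all(s$mean_d <= s$max_d & s$median_d <= s$max_d))

  # partial-window series are rejected unless permitted
  expect_error(summarize_countries(d[-1, ], flat_chi(c("AAA", "BBB"))),
               "window")
  expect_silent(summarize_countries(d[-1, ], flat_chi(c("AAA", "BBB")),
                                    partial = TRUE))
})

test_that("mean CHI basis options use the intended status groups", {
  d <- d_series("AAA", rep(0, 730))
  chi <- dplyr::bind_rows(
    make_series("AAA", rep(60, 730), full_dates(), "non_vaccinated"),
    make_series("AAA", rep(40, 730), full_dates(), "vaccinated")
  )
  expect_equal(summarize_countries(d, chi)$mean_chi, 60)
  expect_equal(summarize_countries(d, chi, mean_chi_basis = "average")$mean_chi, 50)
})

test_that("rankings are descending with stable code-ordered ties", {
  s <- tibble::tibble(
    country_code = c("CCC", "AAA", "BBB", "DDD"),
    country_name = c("C", "A", "B", "D"),
    continent = "X", sub_region = "Y",
    mean_d = c(5, 7, 5, 1), median_d = 0, max_d = c(20, 30, 10, 5),
    mean_chi = 40, discriminated = TRUE
  )
  r <- rank_countries(s, "mean_d", 3)
  expect_equal(r$country_code, c("AAA", "BBB", "CCC"))  # tie 5 vs 5 by code
  expect_equal(r$rank, 1:3)
  # re-ranking the output reproduces it
  expect_equal(rank_countries(r[-1], "mean_d", 3)$country_code,
               r$country_code)
  expect_equal(rank_countries(s, "max_d", 1)$country_code, "AAA")
  expect_error(rank_countries(s, "mean_d", 0), ">= 1")
})

test_that("zero partition is complete, disjoint, with per-set mean CHI", {
  d <- dplyr::bind_rows(
    d_series("AAA", c(rep(4, 365), rep(0, 365))),
    d_series("BBB", rep(0, 730)),
    d_series("CCC", rep(0, 730))
  )
  chi <- dplyr::bind_rows(flat_chi("AAA", 50), flat_chi("BBB", 30),
                          flat_chi("CCC", 40))
  s <- summarize_countries(d, chi)
  p <- zero_partition(s)
  expect_setequal(p$zero$country_code, c("BBB", "CCC"))
  expect_setequal(p$nonzero$country_code, "AAA")
  expect_equal(nrow(p$zero) + nrow(p$nonzero), nrow(s))
  expect_length(intersect(p$zero$country_code, p$nonzero$country_code), 0)
  expect_equal(p$mean_chi_zero, 35)     # unweighted mean of 30 and 40
  expect_equal(p$mean_chi_nonzero, 50)

  # all-discriminating input: empty zero set
  p2 <- zero_partition(s[s$discriminated, ])
  expect_equal(nrow(p2$zero), 0)
  expect_true(is.na(p2$mean_chi_zero))
})

test_that("regional grouping partitions countries and reports shares", {
  s <- tibble::tibble(
    country_code = c("A", "B", "C", "D"), country_name = c("A", "B", "C", "D"),
    continent = c("Africa", "Africa", "Asia", "Asia"),
    sub_region = c("East", "West", "South", "South"),
    mean_d = c(0, 2, 0, 4), median_d = 0, max_d = c(0, 8, 0, 9),
    mean_chi = 40, discriminated = c(FALSE, TRUE, FALSE, TRUE)
  )
  g <- group_by_region(s, "continent")
  expect_equal(nrow(g), 2)
  expect_equal(sum(g$n_countries), 4)
  expect_equal(g$n_zero[g$group == "Africa"], 1)
  expect_equal(g$share_discriminated, c(0.5, 0.5))
  expect_equal(nrow(group_by_region(s, "sub_region")), 3)
  s$continent <- NA_character_
  expect_error(group_by_region(s, "continent"), "not populated")
})

test_that("association reproduces textbook OLS behaviour", {
  s <- tibble::tibble(country_code = letters[1:5],
                      mean_d = c(1, 2, 3, 4, 5),
                      max_d = c(2, 4, 6, 8, 10),
                      mean_chi = c(7, 7, 7, 7, 7))
  # exactly collinear
  a <- association(s, "mean_d", "max_d")
  expect_equal(a$r_squared, 1)
  expect_equal(a$slope, 0.5)
  # self-association of a non-constant variable
  expect_equal(association(s, "mean_d", "mean_d")$r_squared, 1)
  # constant response
  expect_equal(association(s, "mean_chi", "max_d")$r_squared, 0)
  # zero-variance predictor is undefined
  expect_error(association(s, "mean_d", "mean_chi"), "zero-variance")
  expect_error(association(s[1:2, ], "mean_d", "max_d"), "at least 3")

  # cross-check r_squared and slope against closed-form OLS on noisy data
  set.seed(7)
  s2 <- tibble::tibble(country_code = as.character(1:40),
                       max_d = runif(40, 0, 40))
  s2$mean_d <- 0.4 * s2$max_d + rnorm(40, sd = 2)
  a2 <- association(s2, "mean_d", "max_d")
  expect_equal(a2$r_squared, cor(s2$mean_d, s2$max_d)^2)
  expect_equal(a2$slope, cov(s2$mean_d, s2$max_d) / var(s2$max_d))
  expect_lt(a2$p_value, 1e-4)
})
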