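#' Per-country discrimination summaries over the study window
#'
#' For every country, the mean, median and maximum of the daily
#' discrimination index over the full window — all days count, including
#' the zero-discrimination days before any differentiation, which is why
#' the mean (combining duration and magnitude) is the headline statistic
#' and many medians are zero. Also attaches the underlying mean composite
#' index and the region labels, and flags whether the country ever
#' discriminated (`max_d > 0`).
#'
#' @param d Discrimination-series tibble (see [discrimination_series()])
#'   spanning the full window for every country.
#' @param chi Index-series tibble providing the underlying composite
#'   index; by default its non-vaccinated status group is averaged (see
#'   `mean_chi_basis`).
#' @param regions Output of [join_regions()], or a region tibble with an
#'   `iso3` key; unmatched countries keep `NA` labels.
#' @param window Expected `c(start, end)` coverage; a country whose
#'   series does not span it is an error unless `partial = TRUE`.
#' @param mean_chi_basis `"non_vaccinated"` (default) or `"average"` (mean
#'   of the non-vaccinated and vaccinated series).
#' @param partial Allow partial-window series.
#' @return Tibble with one row per country: `country_code`,
#'   `country_name`, `continent`, `sub_region`, `mean_d`, `median_d`,
#'   `max_d`, `mean_chi`, `discriminated`.
#' @export
summarize_countries <- function(d, chi, regions = NULL,
                                window = study_window(),
                                mean_chi_basis = c("non_vaccinated", "average"),
                                partial = FALSE) {
  mean_chi_basis <- match.arg(mean_chi_basis)
  d <- dplyr::as_tibble(d)
  span <- d |>
    dplyr::group_by(.data$country_code) |>
    dplyr::summarise(start = min(.data$date), end = max(.data$date),
                     n = dplyr::n(), .groups = "drop")
  expected_n <- as.integer(as.Date(window[2]) - as.Date(window[1])) + 1L
  bad <- span[span$start != as.Date(window[1]) | span$end != as.Date(window[2]) |
              span$n != expected_n, ]
  if (nrow(bad) > 0 && !partial) {
    stop("series does not span the full study window for: ",
         paste(utils::head(bad$country_code, 5), collapse = ", "),
         call. = FALSE)
  }

  sums <- d |>
    dplyr::group_by(.data$country_code, .data$country_name) |>
    dplyr::summarise(mean_d = mean(.data$d), median_d = stats::median(.data$d),
                     max_d = max(.data$d), .groups = "drop") |>
    dplyr::mutate(discriminated = .data$max_d > 0)

  chi_groups <- if (mean_chi_basis == "non_vaccinated") "non_vaccinated" else
    c("non_vaccinated", "vaccinated")
  mean_chi <- chi[chi$status_group %in% chi_groups, ] |>
    dplyr::group_by(.data$country_code) |>
    dplyr::summarise(mean_chi = mean(.data$value), .groups = "drop")
  sums <- dplyr::left_join(sums, mean_chi, by = "country_code")

  reg <- if (is.null(regions)) NULL else if (is.data.frame(regions)) regions
    else regions$matched
  if (!is.null(reg)) {
    sums <- dplyr::left_join(
      sums, reg[, c("iso3", "sub_region", "continent")],
      by = c(country_code = "iso3"))
  } else {
    sums$sub_region <- NA_character_
    sums$continent <- NA_character_
  }
  sums[, c("country_code", "country_name", "continent", "sub_region",
           "mean_d", "median_d", "max_d", "mean_chi", "discriminated")]
}

#' Rank countries by average or maximum discrimination
#'
#' Descending order by the chosen statistic; ties broken by country code
#' so rankings are stable and reproducible.
#'
#' @param summaries Country-summary tibble.
#' @param by `"mean_d"` or `"max_d"`.
#' @param n Number of countries to keep (default all).
#' @return The top-`n` rows with a leading `rank` column.
#' @export
rank_countries <- function(summaries, by = c("mean_d", "max_d"), n = Inf) {
  by <- match.arg(by)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  out <- summaries[order(-summaries[[by]], summaries$country_code), ]
  out <- utils::head(out, n)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Partition countries by presence of any recorded discrimination
#'
#' Splits the summaries into the zero-discrimination set (no
#' discriminatory policy on any day, `max_d = 0`) and its complement, and
#' reports each set's unweighted mean of the per-country mean composite
#' index — contrasting how tightly the two groups restricted overall.
#'
#' @param summaries Country-summary tibble.
#' @return List with `zero` and `nonzero` tibbles plus `mean_chi_zero`
#'   and `mean_chi_nonzero`.
#' @export
zero_partition <- function(summaries) {
  zero <- summaries[!summaries$discriminated, ]
  nonzero <- summaries[summaries$discriminated, ]
  list(
    zero = zero, nonzero = nonzero,
    mean_chi_zero = if (nrow(zero)) mean(zero$mean_chi) else NA_real_,
    mean_chi_nonzero = if (nrow(nonzero)) mean(nonzero$mean_chi) else NA_real_
  )
}

#' Group country summaries by continent or sub-region
#'
#' @param summaries Country-summary tibble with region labels populated.
#' @param level `"continent"` or `"sub_region"`.
#' @return Tibble with one row per group: country count, discriminated
#'   count, share discriminated, and mean of the per-country mean
#'   discrimination.
#' @export
group_by_region <- function(summaries, level = c("continent", "sub_region")) {
  level <- match.arg(level)
  if (all(is.na(summaries[[level]]))) {
    stop("region labels are not populated; join regions first", call. = FALSE)
  }
  summaries |>
    dplyr::group_by(group = .data[[level]]) |>
    dplyr::summarise(
      n_countries = dplyr::n(),
      n_discriminated = sum(.data$discriminated),
      n_zero = sum(!.data$discriminated),
      share_discriminated = mean(.data$discriminated),
      mean_mean_d = mean(.data$mean_d),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
}

#' Cross-country linear association between two summary statistics
#'
#' Ordinary least-squares fit of one per-country statistic on another
#' (e.g. mean discrimination on maximum discrimination), reporting the
#' coefficient of determination and the two-sided p-value of the slope.
#'
#' @param summaries Country-summary tibble.
#' @param response,predictor Column names of the response and predictor.
#' @return One-row tibble: `response`, `predictor`, `r_squared`,
#'   `p_value`, `slope`, `intercept`, `n`.
#' @export
association <- function(summaries, response, predictor) {
  y <- summaries[[response]]
  x <- summaries[[predictor]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 countries with finite values",
                          call. = FALSE)
  if (stats::var(x) == 0) {
    stop("zero-variance predictor '", predictor, "': fit undefined",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exactly collinear input; the fit is still defined
  sm <- suppressWarnings(summary(fit))
  coefs <- sm$coefficients
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  p <- if (stats::var(y) == 0) 1 else coefs["x", "Pr(>|t|)"]
  tibble::tibble(
    response = response, predictor = predictor,
    r_squared = r2, p_value = p,
    slope = unname(coefs["x", "Estimate"]),
    intercept = unname(coefs["(Intercept)", "Estimate"]),
    n = length(x)
  )
}
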