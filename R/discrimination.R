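#' Daily discrimination index from paired status-group index series
#'
#' The discrimination index for a country-day is the composite policy
#' index for the non-vaccinated group minus the same index for the
#' vaccinated group: `D(t) = index_nv(t) - index_v(t)`. Positive values
#' mean tighter restrictions applied to non-vaccinated individuals. The
#' two inputs must cover the same countries, index basis and date axis.
#'
#' Negative values are possible in principle (a jurisdiction restricting
#' the vaccinated more) and are preserved, never clipped; they are
#' surfaced via a warning so anomalies are visible.
#'
#' @param nv,v Index-series tibbles as returned by [build_index_series()]
#'   (or the published-column equivalent), restricted to the
#'   non-vaccinated and vaccinated status group respectively.
#' @return Tibble with columns `country_code`, `country_name`,
#'   `index_basis`, `date`, `d` where `d` is the daily discrimination
#'   index in `[-100, 100]`.
#' @examples
#' cb <- default_codebook()
#' obs <- generate_panel(list(country_profile("AAA", "X", "Y")),
#'                       window = as.Date(c("2021-01-01", "2021-01-10")))
#' idx <- build_index_series(obs, cb, "CHI")
#' d <- discrimination_series(idx[idx$status_group == "non_vaccinated", ],
#'                            idx[idx$status_group == "vaccinated", ])
#' all(d$d == 0)  # no differentiation injected
#' @export
discrimination_series <- function(nv, v) {
  nv <- dplyr::as_tibble(nv)
  v <- dplyr::as_tibble(v)
  if (length(unique(nv$index_name)) != 1 ||
      !identical(unique(nv$index_name), unique(v$index_name))) {
    stop("nv and v must share a single common index basis", call. = FALSE)
  }
  nv <- nv[order(nv$country_code, nv$date), ]
  v <- v[order(v$country_code, v$date), ]
  if (!identical(nv$country_code, v$country_code) ||
      !identical(as.integer(nv$date), as.integer(v$date))) {
    stop("nv and v must share the same country and date axis", call. = FALSE)
  }
  out <- tibble::tibble(
    country_code = nv$country_code,
    country_name = nv$country_name,
    index_basis = nv$index_name,
    date = nv$date,
    d = nv$value - v$value
  )
  if (any(out$d < 0)) {
    warning(sum(out$d < 0), " country-day(s) with negative discrimination ",
            "values (vaccinated group more restricted); preserved as is",
            call. = FALSE)
  }
  out
}

#' Discrimination series straight from an index-series table
#'
#' Convenience wrapper splitting a combined index-series tibble into its
#' non-vaccinated and vaccinated halves and applying
#' [discrimination_series()].
#'
#' @param index_series Output of [build_index_series()] or
#'   [published_index_series()] containing both status groups.
#' @return See [discrimination_series()].
#' @export
discrimination_from_indices <- function(index_series) {
  discrimination_series(
    index_series[index_series$status_group == "non_vaccinated", ],
    index_series[index_series$status_group == "vaccinated", ]
  )
}

#' Stack two annual series onto one continuous time axis
#'
#' Concatenates per-country daily series from two consecutive calendar
#' years (e.g. the 2021 and 2022 panel files) into a single series with a
#' continuous date axis. For every country the second series must start
#' exactly one day after the first one ends; overlaps, gaps or a missing
#' year are hard errors because the study window requires both years.
#'
#' @param series_y1,series_y2 Tibbles with columns `country_code` and
#'   `date` (plus any value columns); typically discrimination series.
#' @return The row-bound tibble ordered by country and date.
#' @export
stack_years <- function(series_y1, series_y2) {
  s1 <- dplyr::as_tibble(series_y1)
  s2 <- dplyr::as_tibble(series_y2)
  if (nrow(s1) == 0 || nrow(s2) == 0) {
    stop("both annual series must be non-empty to span the study window",
         call. = FALSE)
  }
  keys <- intersect(c("country_code", "index_basis", "index_name",
                      "status_group"), names(s1))
  if (!setequal(unique(s1$country_code), unique(s2$country_code))) {
    stop("the two years cover different country sets", call. = FALSE)
  }
  joint <- dplyr::bind_rows(s1, s2)
  ends <- s1 |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(end1 = max(.data$date), .groups = "drop")
  starts <- s2 |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(start2 = min(.data$date), .groups = "drop")
  seam <- dplyr::inner_join(ends, starts, by = keys)
  bad <- seam[as.integer(seam$start2) != as.integer(seam$end1) + 1L, ]
  if (nrow(bad) > 0) {
    stop("overlapping or gapped date ranges at the year seam for: ",
         paste(utils::head(unique(bad$country_code), 5), collapse = ", "),
         call. = FALSE)
  }
  joint <- joint[do.call(order, joint[c(keys, "date")]), ]
  assert_contiguous_dates(joint, keys)
  joint
}

#' The 2021--2022 study window
#'
#' @return Date vector `c(start, end)` spanning 2021-01-01 to 2022-12-31
#'   (730 days; neither year has a leap day).
#' @export
study_window <- function() {
  as.Date(c("2021-01-01", "2022-12-31"))
}
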