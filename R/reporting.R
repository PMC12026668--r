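#' Equal-interval classification for choropleth export
#'
#' Partitions the value domain into `k` classes of identical width, as
#' used for the five-class map legends (domain `[0, 20]` for two-year
#' averages, `[0, 40]` for maxima). Intervals are left-open/right-closed
#' except the first class, which includes the lower domain bound; a value
#' exactly on a boundary belongs to the class below it. Values outside
#' the domain are a hard error, never clipped.
#'
#' @param values Numeric vector (typically per-country mean or max
#'   discrimination), optionally named by country code.
#' @param k Number of classes (>= 2), default 5.
#' @param domain_min,domain_max Classification domain bounds.
#' @return Tibble with one row per value: `country_code` (names of
#'   `values`, else index), `value`, `class_index` in `1..k`, `lower`,
#'   `upper`.
#' @examples
#' equal_interval_classes(c(AZE = 18.7, MAR = 10.58, TZA = 0),
#'                        k = 5, domain_min = 0, domain_max = 20)
#' @export
equal_interval_classes <- function(values, k = 5, domain_min = 0,
                                   domain_max = 20) {
  if (domain_max <= domain_min) stop("domain_max must exceed domain_min",
                                     call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (any(values < domain_min | values > domain_max)) {
    stop("value(s) outside classification domain [", domain_min, ", ",
         domain_max, "]: ",
         paste(utils::head(values[values < domain_min | values > domain_max], 3),
               collapse = ", "), call. = FALSE)
  }
  width <- (domain_max - domain_min) / k
  cls <- as.integer(ceiling((values - domain_min) / width))
  cls[values == domain_min] <- 1L
  cls <- pmin(cls, as.integer(k))  # guard float round-up at the top bound
  tibble::tibble(
    country_code = if (!is.null(names(values))) names(values)
                   else as.character(seq_along(values)),
    value = unname(values),
    class_index = cls,
    lower = domain_min + (cls - 1L) * width,
    upper = domain_min + cls * width
  )
}

#' Long timeline table for line-chart rendering
#'
#' Restricts a discrimination (or index) series to one continent or
#' sub-region and lays it out as one row per country-day, sorted by
#' country then date — the layout behind per-continent and per-sub-region
#' timeline charts.
#'
#' @param series Series tibble with `country_code`, `date` and a value
#'   column (`d` or `value`).
#' @param regions Output of [join_regions()] or a region tibble keyed by
#'   `iso3`.
#' @param filter_level `"continent"`, `"sub_region"` or `"none"`.
#' @param filter_value Group label to keep (required unless
#'   `filter_level = "none"`); an unknown label is an error listing the
#'   valid labels, a known label absent from the data yields an empty
#'   table with a warning.
#' @return Tibble `(date, country_code, country_name, value, group)`.
#' @export
timeline_table <- function(series, regions,
                           filter_level = c("none", "continent", "sub_region"),
                           filter_value = NULL) {
  filter_level <- match.arg(filter_level)
  reg <- if (is.data.frame(regions)) regions else regions$matched
  s <- dplyr::as_tibble(series)
  s$value <- if ("d" %in% names(s)) s$d else s$value
  s <- dplyr::left_join(
    s[, c("country_code", "country_name", "date", "value")],
    reg[, c("iso3", "continent", "sub_region")],
    by = c(country_code = "iso3"))
  if (filter_level == "none") {
    s$group <- "all"
  } else {
    if (is.null(filter_value)) stop("filter_value required", call. = FALSE)
    valid <- sort(unique(stats::na.omit(reg[[filter_level]])))
    if (!filter_value %in% valid) {
      stop("unknown ", filter_level, " '", filter_value, "'; valid labels: ",
           paste(valid, collapse = ", "), call. = FALSE)
    }
    s <- s[!is.na(s[[filter_level]]) & s[[filter_level]] == filter_value, ]
    if (nrow(s) == 0) {
      warning("no data for ", filter_level, " '", filter_value, "'",
              call. = FALSE)
    }
    s$group <- filter_value
  }
  s <- s[order(s$country_code, s$date),
         c("date", "country_code", "country_name", "value", "group")]
  tibble::as_tibble(s)
}

#' Run the full discrimination analysis pipeline
#'
#' One deterministic entry point from inputs to the analysis bundle:
#' reads (or generates) the policy panel, builds the per-group composite
#' index series, stacks the annual files, forms the discrimination
#' series, and produces summaries, the two rankings, the
#' zero-discrimination partition, regional groupings, equal-interval
#' classified tables for the mean and max maps, and per-continent
#' timelines. When `out_dir` is given every table is written as tidy CSV
#' together with a run manifest (input file hashes, options, output
#' hashes) so identical configs yield identical bundles.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `panel_files` (character vector of wide CSVs, one per year) or
#'   `profiles` (list of [country_profile()] / path to a profile config)
#'   for synthetic input; `regions` (path or tibble); `basis`
#'   (`"CHI"`/`"STRINGENCY"`); `window`; `source`
#'   (`"recomputed"`/`"published"`), `classes`, `mean_domain`,
#'   `max_domain`, `top_n`, `out_dir`.
#' @return List with `summaries`, `rank_mean`, `rank_max`, `partition`,
#'   `by_continent`, `by_sub_region`, `classified_mean`,
#'   `classified_max`, `discrimination`, `timelines`, `unmatched`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  basis <- toupper(config$basis %||% "CHI")
  window <- as.Date(config$window %||% study_window())
  source <- config$source %||% "recomputed"
  codebook <- if (!is.null(config$codebook)) read_codebook(config$codebook)
              else default_codebook()

  input_hashes <- character()
  if (!is.null(config$panel_files)) {
    input_hashes <- tools::md5sum(unlist(config$panel_files))
    parts <- lapply(config$panel_files, read_policy_panel, codebook = codebook)
    obs <- dplyr::bind_rows(lapply(parts, `[[`, "observations"))
    pub <- dplyr::bind_rows(lapply(parts, `[[`, "indices"))
  } else if (!is.null(config$profiles)) {
    profiles <- config$profiles
    if (is.character(profiles)) profiles <- read_profiles(profiles)
    obs <- generate_panel(profiles, window, codebook,
                          jitter_days = config$jitter_days %||% 0,
                          seed = config$seed)
    pub <- NULL
  } else {
    stop("config must name panel_files or profiles", call. = FALSE)
  }

  idx <- if (source == "published") {
    if (is.null(pub) || nrow(pub) == 0) {
      stop("published index columns requested but not present", call. = FALSE)
    }
    nm <- stats::setNames(obs$country_name, obs$country_code)
    published_index_series(pub, basis, country_names = nm)
  } else {
    build_index_series(obs, codebook, basis,
                       partial = isTRUE(config$partial))
  }

  # annual panel files are stacked at the series level onto one time axis
  years <- unique(format(idx$date, "%Y"))
  if (length(years) == 2) {
    idx <- stack_years(idx[format(idx$date, "%Y") == years[1], ],
                       idx[format(idx$date, "%Y") == years[2], ])
  }

  d <- discrimination_from_indices(idx)

  regions <- config$regions
  if (is.character(regions)) {
    input_hashes <- c(input_hashes, tools::md5sum(regions))
    regions <- read_country_regions(regions)
  }
  if (is.null(regions)) regions <- synthetic_regions()
  joined <- join_regions(unique(d$country_code), regions)

  summaries <- summarize_countries(
    d, idx, joined, window = window,
    mean_chi_basis = config$mean_chi_basis %||% "non_vaccinated",
    partial = isTRUE(config$partial))

  top_n <- config$top_n %||% 10
  k <- config$classes %||% 5
  mean_dom <- config$mean_domain %||% c(0, 20)
  max_dom <- config$max_domain %||% c(0, 40)

  bundle <- list(
    summaries = summaries,
    rank_mean = rank_countries(summaries, "mean_d", top_n),
    rank_max = rank_countries(summaries, "max_d", top_n),
    partition = zero_partition(summaries),
    by_continent = group_by_region(summaries, "continent"),
    by_sub_region = group_by_region(summaries, "sub_region"),
    classified_mean = equal_interval_classes(
      stats::setNames(summaries$mean_d, summaries$country_code),
      k, mean_dom[1], mean_dom[2]),
    classified_max = equal_interval_classes(
      stats::setNames(summaries$max_d, summaries$country_code),
      k, max_dom[1], max_dom[2]),
    discrimination = d,
    timelines = lapply(
      stats::setNames(nm = sort(unique(stats::na.omit(summaries$continent)))),
      function(ct) timeline_table(d, joined, "continent", ct)),
    unmatched = joined$unmatched
  )

  manifest <- list(
    basis = basis, source = source,
    window = as.character(window),
    options = list(classes = k, mean_domain = mean_dom, max_domain = max_dom,
                   top_n = top_n,
                   mean_chi_basis = config$mean_chi_basis %||% "non_vaccinated"),
    n_countries = nrow(summaries),
    input_md5 = as.list(input_hashes)
  )

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      summaries = bundle$summaries,
      rank_mean = bundle$rank_mean, rank_max = bundle$rank_max,
      by_continent = bundle$by_continent,
      by_sub_region = bundle$by_sub_region,
      classified_mean = bundle$classified_mean,
      classified_max = bundle$classified_max,
      discrimination = bundle$discrimination
    )
    paths <- vapply(names(files), function(nmf) {
      p <- file.path(out_dir, paste0(nmf, ".csv"))
      write_tidy(files[[nmf]], p)
      p
    }, character(1))
    manifest$output_md5 <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle$manifest <- manifest
  bundle
}
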