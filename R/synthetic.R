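#' Define a discrimination episode for a synthetic country profile
#'
#' During an episode the non-vaccinated group's codes for the listed
#' differentiated indicators are raised by `deltas` above the country's
#' baseline (clamped at each indicator's maximum code) while the
#' vaccinated group stays at baseline — the panel then carries explicit
#' per-group variants for those indicator-days.
#'
#' @param start,end Episode dates (inclusive), coercible to `Date`.
#' @param deltas Named non-negative integer vector of extra ordinal steps,
#'   keyed by differentiated indicator id (e.g. `c(C4 = 4, C6 = 2)`).
#' @param flag Flag value (0/1) applied to the episode indicators while
#'   the episode is active.
#' @return An `episode` list.
#' @export
episode <- function(start, end, deltas, flag = 1) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("episode start must not exceed end", call. = FALSE)
  if (is.null(names(deltas)) || any(!nzchar(names(deltas)))) {
    stop("deltas must be named by indicator id", call. = FALSE)
  }
  if (any(deltas < 0)) stop("deltas must be non-negative", call. = FALSE)
  structure(list(start = start, end = end,
                 deltas = deltas, flag = flag), class = "episode")
}

#' Define a synthetic country profile
#'
#' A profile fixes a country's constant baseline policy codes and flags
#' plus any discrimination episodes ([episode()]). Baseline codes apply to
#' both status groups; episodes raise the non-vaccinated group only.
#'
#' @param country_code ISO alpha-3 code.
#' @param continent,sub_region Region labels for grouping.
#' @param country_name Country name (defaults to the code).
#' @param baseline Named integer vector of baseline codes by indicator id;
#'   indicators not named default to 0.
#' @param baseline_flags Named 0/1 vector of baseline flags; default 1
#'   (nationwide) for every flagged indicator.
#' @param episodes List of [episode()] objects.
#' @return A `country_profile` list.
#' @export
country_profile <- function(country_code, continent, sub_region,
                            country_name = country_code,
                            baseline = integer(), baseline_flags = integer(),
                            episodes = list()) {
  structure(list(country_code = country_code, country_name = country_name,
                 continent = continent, sub_region = sub_region,
                 baseline = baseline, baseline_flags = baseline_flags,
                 episodes = episodes), class = "country_profile")
}

#' @keywords internal
profile_codes <- function(profile, codebook) {
  codes <- stats::setNames(rep(0L, nrow(codebook)), codebook$id)
  codes[names(profile$baseline)] <- as.integer(profile$baseline)
  flags <- stats::setNames(rep(1L, nrow(codebook)), codebook$id)
  flags[names(profile$baseline_flags)] <- as.integer(profile$baseline_flags)
  bad <- codes > codebook$max_code[match(names(codes), codebook$id)] | codes < 0L
  if (any(bad)) {
    stop("baseline code out of range for ", profile$country_code, ": ",
         paste(names(codes)[bad], collapse = ", "), call. = FALSE)
  }
  list(codes = codes, flags = flags)
}

#' @keywords internal
active_episodes <- function(profile, date) {
  Filter(function(e) date >= e$start && date <= e$end, profile$episodes)
}

#' @keywords internal
nv_codes_on <- function(profile, date, codebook) {
  base <- profile_codes(profile, codebook)
  codes <- base$codes; flags <- base$flags
  for (e in active_episodes(profile, date)) {
    ids <- names(e$deltas)
    if (!all(codebook$differentiated[match(ids, codebook$id)])) {
      stop("episode references a non-differentiated indicator for ",
           profile$country_code, call. = FALSE)
    }
    codes[ids] <- pmin(codes[ids] + as.integer(e$deltas),
                       codebook$max_code[match(ids, codebook$id)])
    flags[ids] <- as.integer(e$flag)
  }
  list(codes = codes, flags = flags)
}

#' Closed-form expected composite index for a synthetic profile
#'
#' Evaluates the composite index directly from a profile's codes and
#' flags without going through the panel/observation representation —
#' the analytic oracle against which the pipeline is checked.
#'
#' @param profile A [country_profile()].
#' @param date A single date.
#' @param index_name `"CHI"` or `"STRINGENCY"`.
#' @param status_group `"non_vaccinated"` or `"vaccinated"`.
#' @param codebook Codebook tibble.
#' @return The expected index value in `[0, 100]`.
#' @export
expected_index <- function(profile, date,
                           index_name = c("CHI", "STRINGENCY"),
                           status_group = c("non_vaccinated", "vaccinated"),
                           codebook = default_codebook()) {
  index_name <- match.arg(index_name)
  status_group <- match.arg(status_group)
  date <- as.Date(date)
  state <- if (status_group == "non_vaccinated") {
    nv_codes_on(profile, date, codebook)
  } else {
    profile_codes(profile, codebook)
  }
  members <- index_members(codebook, index_name)
  spec <- codebook[match(members, codebook$id), ]
  scores <- vapply(seq_along(members), function(i) {
    id <- members[i]
    subindex(state$codes[[id]],
             if (spec$has_flag[i]) state$flags[[id]] else NULL,
             max_code = spec$max_code[i], has_flag = spec$has_flag[i])
  }, numeric(1))
  mean(scores)
}

#' Closed-form expected discrimination series for a synthetic profile
#'
#' @param profile A [country_profile()].
#' @param window Date vector `c(start, end)`.
#' @param index_name Index basis.
#' @param codebook Codebook tibble.
#' @return Tibble `(country_code, date, d)` with the oracle discrimination
#'   value for every day of the window.
#' @export
expected_discrimination <- function(profile, window = study_window(),
                                    index_name = c("CHI", "STRINGENCY"),
                                    codebook = default_codebook()) {
  index_name <- match.arg(index_name)
  dates <- seq(as.Date(window[1]), as.Date(window[2]), by = "day")
  d <- vapply(dates, function(day) {
    expected_index(profile, day, index_name, "non_vaccinated", codebook) -
      expected_index(profile, day, index_name, "vaccinated", codebook)
  }, numeric(1))
  tibble::tibble(country_code = profile$country_code, date = dates, d = d)
}

#' Generate a synthetic policy panel from country profiles
#'
#' Produces a long observation table in the package's internal model: one
#' shared observation per country-day-indicator from the baseline, plus
#' explicit non-vaccinated and vaccinated variants for differentiated
#' indicators on days covered by an episode (the vaccinated variant
#' repeats the baseline). Flags are emitted only for flagged indicators
#' with positive codes. An optional uniform jitter (at most `jitter_days`
#' days, requires `seed`) shifts episode onsets to emulate uncertain
#' policy start dates; the default is fully deterministic.
#'
#' @param profiles List of [country_profile()] objects.
#' @param window Date vector `c(start, end)`.
#' @param codebook Codebook tibble.
#' @param jitter_days Maximum absolute onset shift in days (default 0).
#' @param seed Integer seed used when `jitter_days > 0`.
#' @return Observation tibble with columns `country_code`, `country_name`,
#'   `date`, `indicator`, `status_group`, `code`, `flag`.
#' @export
generate_panel <- function(profiles, window = study_window(),
                           codebook = default_codebook(),
                           jitter_days = 0, seed = NULL) {
  if (jitter_days > 0) {
    if (is.null(seed)) stop("jitter requires a seed", call. = FALSE)
    profiles <- withr_seed(seed, lapply(profiles, function(p) {
      p$episodes <- lapply(p$episodes, function(e) {
        shift <- sample.int(2L * jitter_days + 1L, 1L) - jitter_days - 1L
        e$start <- e$start + shift
        e
      })
      p
    }))
  }
  dates <- seq(as.Date(window[1]), as.Date(window[2]), by = "day")
  panels <- lapply(profiles, function(p) {
    base <- profile_codes(p, codebook)
    shared <- tidyr::expand_grid(date = dates, indicator = codebook$id)
    shared$code <- base$codes[shared$indicator]
    shared$flag <- base$flags[shared$indicator]
    shared$status_group <- "shared"

    for (e in p$episodes) {
      ids <- names(e$deltas)
      if (!all(codebook$differentiated[match(ids, codebook$id)])) {
        stop("episode references a non-differentiated indicator for ",
             p$country_code, call. = FALSE)
      }
    }
    active <- dates[vapply(dates, function(d) length(active_episodes(p, d)) > 0,
                           logical(1))]
    diff_rows <- lapply(active, function(day) {
      # same cumulative-clamp logic as the oracle, so overlaps agree exactly
      state <- nv_codes_on(p, day, codebook)
      ids <- unique(unlist(lapply(active_episodes(p, day),
                                  function(e) names(e$deltas))))
      dplyr::bind_rows(
        tibble::tibble(date = day, indicator = ids,
                       code = unname(state$codes[ids]),
                       flag = unname(state$flags[ids]),
                       status_group = "non_vaccinated"),
        tibble::tibble(date = day, indicator = ids,
                       code = unname(base$codes[ids]),
                       flag = unname(base$flags[ids]),
                       status_group = "vaccinated")
      )
    })
    out <- dplyr::bind_rows(c(list(shared), diff_rows))
    out$country_code <- p$country_code
    out$country_name <- p$country_name
    out
  })
  obs <- dplyr::bind_rows(panels)
  has_flag <- codebook$has_flag[match(obs$indicator, codebook$id)]
  obs$flag <- ifelse(has_flag & obs$code > 0L, obs$flag, NA_integer_)
  obs$code <- as.integer(obs$code)
  obs$flag <- as.integer(obs$flag)
  obs[order(obs$country_code, obs$date, obs$indicator, obs$status_group),
      c("country_code", "country_name", "date", "indicator",
        "status_group", "code", "flag")]
}

#' @keywords internal
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' The package's default synthetic study: twelve countries, six continents
#'
#' A deterministic fixture set emulating the qualitative global pattern of
#' vaccination-status-differentiated policies in 2021--2022: early
#' adopters (from January 2021), a mid-2021 bulk, late adopters (December
#' 2021 / January 2022 onsets), a high sustained discriminator holding to
#' year-end, low-discrimination Eastern Asia, and two zero-discrimination
#' countries — one with very tight undifferentiated policies and one with
#' lax policies throughout.
#'
#' @return A named list of [country_profile()] objects.
#' @export
default_profiles <- function() {
  w_end <- as.Date("2022-12-31")
  profiles <- list(
    # early adopters, moderate magnitude
    country_profile("EST", "Europe", "Northern Europe", "Estonia",
      baseline = c(C1 = 1L, C3 = 1L, H1 = 2L, H2 = 2L, H3 = 1L, H6 = 2L, H7 = 2L),
      episodes = list(episode("2021-01-25", "2022-02-28", c(C3 = 1L, C4 = 2L)))),
    country_profile("ISR", "Asia", "Western Asia", "Israel",
      baseline = c(C2 = 1L, C4 = 1L, H1 = 2L, H2 = 3L, H3 = 2L, H6 = 3L, H7 = 3L),
      episodes = list(episode("2021-02-15", "2022-04-30", c(C3 = 1L, C6 = 1L)))),
    country_profile("USA", "North America", "Northern America", "United States",
      baseline = c(C1 = 1L, C2 = 1L, H1 = 2L, H2 = 3L, H3 = 1L, H6 = 2L, H7 = 4L),
      episodes = list(episode("2021-04-12", "2022-03-31", c(C2 = 1L, C3 = 1L)))),
    # mid-2021 bulk, large maxima
    country_profile("FRA", "Europe", "Western Europe", "France",
      baseline = c(C1 = 1L, C2 = 1L, C3 = 1L, H1 = 2L, H2 = 3L, H3 = 2L,
                   H6 = 3L, H7 = 5L),
      episodes = list(
        episode("2021-08-09", "2022-02-15", c(C2 = 1L, C3 = 1L, C5 = 1L, C7 = 1L)),
        episode("2022-02-16", "2022-03-13",
                c(C2 = 2L, C3 = 1L, C5 = 2L, C6 = 2L, C7 = 2L, C8 = 2L)))),
    country_profile("AZE", "Asia", "Western Asia", "Azerbaijan",
      baseline = c(C2 = 1L, C4 = 1L, H1 = 1L, H2 = 2L, H6 = 3L, H7 = 3L),
      episodes = list(episode("2021-10-01", "2022-11-30",
                              c(C2 = 2L, C3 = 2L, C4 = 3L, C5 = 1L, C6 = 2L)))),
    country_profile("ARG", "South America", "South America", "Argentina",
      baseline = c(C1 = 1L, C3 = 1L, H1 = 2L, H2 = 2L, H3 = 1L, H6 = 3L, H7 = 3L),
      episodes = list(episode("2021-07-05", "2022-06-30", c(C3 = 1L, C4 = 2L, C5 = 1L)))),
    country_profile("MAR", "Africa", "Northern Africa", "Morocco",
      baseline = c(C2 = 1L, C4 = 1L, H1 = 2L, H2 = 2L, H3 = 1L, H6 = 3L, H7 = 3L),
      episodes = list(episode("2021-08-23", "2022-09-30",
                              c(C4 = 2L, C5 = 1L, C7 = 1L, H6 = 1L)))),
    # the worst and longest-lasting hold-out: very high into year-end
    country_profile("PAK", "Asia", "Southern Asia", "Pakistan",
      baseline = c(C4 = 1L, H1 = 2L, H2 = 1L, H6 = 2L, H7 = 3L),
      episodes = list(
        episode("2021-06-01", "2022-03-14", c(C2 = 1L, C4 = 2L, H6 = 1L)),
        episode("2022-03-15", "2022-12-31",
                c(C1 = 3L, C2 = 1L, C3 = 2L, C4 = 3L, C5 = 2L, C7 = 2L)))),
    # late adopters
    country_profile("RWA", "Africa", "Eastern Africa", "Rwanda",
      baseline = c(C4 = 1L, C6 = 1L, H1 = 2L, H2 = 1L, H6 = 3L, H7 = 2L),
      episodes = list(episode("2021-12-20", w_end,
                              c(C2 = 2L, C3 = 2L, C4 = 3L, C5 = 2L)))),
    country_profile("AUS", "Oceania", "Australia and New Zealand", "Australia",
      baseline = c(C1 = 1L, C2 = 1L, C8 = 3L, H1 = 2L, H2 = 3L, H3 = 2L,
                   H6 = 2L, H7 = 4L),
      episodes = list(episode("2021-12-01", "2022-04-30", c(C2 = 1L, C3 = 1L, C4 = 2L)))),
    # Eastern Asia: low-level differentiation, never above 5
    country_profile("JPN", "Asia", "Eastern Asia", "Japan",
      baseline = c(C3 = 1L, H1 = 2L, H2 = 2L, H3 = 2L, H6 = 2L, H7 = 4L),
      episodes = list(episode("2021-09-01", "2022-06-30", c(C4 = 2L)))),
    # zero discrimination: tight but undifferentiated, and lax throughout
    country_profile("CHN", "Asia", "Eastern Asia", "China",
      baseline = c(C1 = 2L, C2 = 2L, C3 = 2L, C4 = 3L, C5 = 1L, C6 = 2L,
                   C7 = 2L, C8 = 4L, H1 = 2L, H2 = 3L, H3 = 2L, H6 = 3L,
                   H7 = 4L, H8 = 2L)),
    country_profile("TZA", "Africa", "Eastern Africa", "Tanzania",
      baseline = c(H1 = 1L, H7 = 1L))
  )
  stats::setNames(profiles, vapply(profiles, `[[`, "", "country_code"))
}

#' Countries-by-continent lookup matching the default synthetic study
#'
#' @return Tibble `(country_name, iso3, sub_region, continent)` covering
#'   the [default_profiles()] countries plus a few extra entries, so the
#'   join has unmatched lookup rows like a real 249-country list would.
#' @export
synthetic_regions <- function() {
  profs <- default_profiles()
  main <- dplyr::bind_rows(lapply(profs, function(p) {
    tibble::tibble(country_name = p$country_name, iso3 = p$country_code,
                   sub_region = p$sub_region, continent = p$continent)
  }))
  extra <- tibble::tribble(
    ~country_name, ~iso3, ~sub_region, ~continent,
    "Germany", "DEU", "Western Europe", "Europe",
    "Brazil", "BRA", "South America", "South America",
    "Kenya", "KEN", "Eastern Africa", "Africa"
  )
  dplyr::bind_rows(main, extra)
}

#' Random profiles for property fuzzing
#'
#' Draws profiles with random baselines within codebook ranges and one
#' random episode over random differentiated indicators — used to fuzz
#' boundedness and antisymmetry of the discrimination metric.
#'
#' @param n Number of profiles.
#' @param codebook Codebook tibble.
#' @param window Date window the episodes must fall in.
#' @return List of [country_profile()] objects (caller controls the RNG
#'   seed).
#' @export
random_profiles <- function(n, codebook = default_codebook(),
                            window = study_window()) {
  dates <- seq(as.Date(window[1]), as.Date(window[2]), by = "day")
  diff_ids <- codebook$id[codebook$differentiated]
  lapply(seq_len(n), function(i) {
    baseline <- stats::setNames(
      vapply(codebook$max_code, function(m) sample.int(m + 1L, 1L) - 1L, 0L),
      codebook$id)
    ids <- sample(diff_ids, sample.int(length(diff_ids), 1L))
    deltas <- stats::setNames(
      vapply(ids, function(id) sample.int(
        codebook$max_code[codebook$id == id] + 1L, 1L) - 1L, 0L), ids)
    onset <- sample(seq_along(dates), 1L)
    country_profile(sprintf("Z%02d", i %% 100), "Fuzz", "Fuzz",
      baseline = baseline,
      baseline_flags = stats::setNames(
        sample(0:1, nrow(codebook), replace = TRUE), codebook$id),
      episodes = list(episode(dates[onset],
                              dates[min(length(dates), onset + sample.int(400, 1L))],
                              deltas, flag = sample(0:1, 1L))))
  })
}

#' Compare injected (oracle) and recovered discrimination summaries
#'
#' Runs the closed-form oracle for each profile over the window and
#' contrasts its mean/maximum discrimination with the values the pipeline
#' recovered, reporting absolute errors. For deterministic profiles the
#' errors are zero to at least two decimals.
#'
#' @param profiles List of [country_profile()] objects.
#' @param summaries Country-summary tibble from [summarize_countries()]
#'   computed on the panel generated from the same profiles.
#' @param window Date window the pipeline used.
#' @param index_name Index basis the pipeline used.
#' @param codebook Codebook tibble.
#' @return Tibble with per-country oracle and recovered mean/max values
#'   and their absolute errors.
#' @export
recovery_report <- function(profiles, summaries, window = study_window(),
                            index_name = c("CHI", "STRINGENCY"),
                            codebook = default_codebook()) {
  index_name <- match.arg(index_name)
  if (length(profiles) == 0) {
    return(tibble::tibble(country_code = character(), oracle_mean_d = numeric(),
                          oracle_max_d = numeric(), recovered_mean_d = numeric(),
                          recovered_max_d = numeric(), abs_err_mean = numeric(),
                          abs_err_max = numeric()))
  }
  oracle <- dplyr::bind_rows(lapply(profiles, function(p) {
    d <- expected_discrimination(p, window, index_name, codebook)
    tibble::tibble(country_code = p$country_code,
                   oracle_mean_d = mean(d$d), oracle_max_d = max(d$d))
  }))
  rec <- summaries[, c("country_code", "mean_d", "max_d")]
  names(rec) <- c("country_code", "recovered_mean_d", "recovered_max_d")
  out <- dplyr::inner_join(oracle, rec, by = "country_code")
  out$abs_err_mean <- abs(out$oracle_mean_d - out$recovered_mean_d)
  out$abs_err_max <- abs(out$oracle_max_d - out$recovered_max_d)
  out
}

#' Load synthetic country profiles from a YAML/JSON config
#'
#' The config is a list of profile records with fields `country_code`,
#' `country_name`, `continent`, `sub_region`, optional named `baseline`
#' and `baseline_flags` maps, and an `episodes` list of records with
#' `start`, `end`, named `deltas` and optional `flag`.
#'
#' @param path Path to the config file.
#' @return List of [country_profile()] objects.
#' @export
read_profiles <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(raw, function(r) {
    eps <- lapply(r$episodes %||% list(), function(e) {
      episode(e$start, e$end, unlist(e$deltas), flag = e$flag %||% 1)
    })
    country_profile(r$country_code, r$continent, r$sub_region,
                    country_name = r$country_name %||% r$country_code,
                    baseline = unlist(r$baseline %||% list()),
                    baseline_flags = unlist(r$baseline_flags %||% list()),
                    episodes = eps)
  })
}
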