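#' @importFrom rlang %||% .data
NULL

# Column-name dialect of the archived version-1 national files: indicator
# columns are "<id><variant>_<label>" where the variant suffix is empty or
# M (shared/merged), NV (non-vaccinated) or V (vaccinated); each has a
# companion "<id><variant>_Flag" where a flag exists. Pre-computed index
# columns are "<IndexName>_<Average|NonVaccinated|Vaccinated>". The dialect
# lives in these two regexes so an alternate naming scheme only needs a
# different pair.
v1_dialect <- function() {
  list(
    indicator = "^([A-Z][0-9]+)(NV|V|M)?_(.+)$",
    index = "^(ContainmentHealthIndex|StringencyIndex)_(Average|NonVaccinated|Vaccinated)$",
    index_names = c(ContainmentHealthIndex = "CHI", StringencyIndex = "STRINGENCY"),
    status = c("NV" = "non_vaccinated", "V" = "vaccinated", "M" = "shared"),
    index_status = c(Average = "average", NonVaccinated = "non_vaccinated",
                     Vaccinated = "vaccinated")
  )
}

#' Read an OxCGRT-dialect wide policy panel
#'
#' Parses a version-1 national wide CSV (one row per country-day, dates as
#' 8-digit year-month-day, indicator columns carrying status-variant
#' suffixes) into the long observation model, and captures any
#' pre-computed composite index columns that are present. Missing cells
#' are carried as absent observations, never imputed to zero. Unknown
#' non-structural columns are skipped with a warning; codes outside the
#' codebook's range and unparseable dates are hard errors.
#'
#' @param path CSV file path.
#' @param codebook Codebook tibble; columns for indicators absent from it
#'   are skipped (with a warning).
#' @param dialect Column-name dialect list; default the v1 archive dialect.
#' @return List with `observations` (tibble: `country_code`,
#'   `country_name`, `date`, `indicator`, `status_group`, `code`, `flag`)
#'   and `indices` (tibble: `country_code`, `date`, `index_name`,
#'   `status_group`, `value`).
#' @export
read_policy_panel <- function(path, codebook = default_codebook(),
                              dialect = v1_dialect()) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_guess()))
  structural <- c("CountryName", "CountryCode", "RegionName", "RegionCode",
                  "Jurisdiction", "Date")
  need <- c("CountryName", "CountryCode", "Date")
  if (!all(need %in% names(wide))) {
    stop("panel lacks required column(s): ",
         paste(setdiff(need, names(wide)), collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(as.character(wide$Date), format = "%Y%m%d")
  if (anyNA(dates)) {
    stop("unparseable date(s), e.g. row ", which(is.na(dates))[1], ": '",
         wide$Date[which(is.na(dates))[1]], "'", call. = FALSE)
  }

  value_cols <- setdiff(names(wide), structural)
  ind_match <- regmatches(value_cols, regexec(dialect$indicator, value_cols))
  idx_keep <- grepl(dialect$index, value_cols)

  parsed <- purrr::map_dfr(seq_along(value_cols), function(i) {
    m <- ind_match[[i]]
    if (length(m) == 0 || idx_keep[i]) return(NULL)
    tibble::tibble(column = value_cols[i], id = m[2],
                   variant = ifelse(m[3] == "", "M", m[3]), label = m[4])
  })
  known <- parsed[parsed$id %in% codebook$id, , drop = FALSE]
  unknown <- setdiff(value_cols[!idx_keep],
                     c(if (nrow(parsed)) known$column else character()))
  unknown <- setdiff(unknown, grep("ForDisplay|Notes$", value_cols, value = TRUE))
  if (length(unknown) > 0) {
    warning("skipping ", length(unknown), " unknown column(s): ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "", call. = FALSE)
  }

  code_cols <- known[known$label != "Flag", , drop = FALSE]
  flag_cols <- known[known$label == "Flag", , drop = FALSE]

  obs <- purrr::map_dfr(seq_len(nrow(code_cols)), function(i) {
    row <- code_cols[i, ]
    spec <- codebook[codebook$id == row$id, ]
    code <- suppressWarnings(as.integer(wide[[row$column]]))
    keep <- !is.na(code)
    if (!any(keep)) return(NULL)
    bad <- keep & (code < 0L | code > spec$max_code)
    if (any(bad)) {
      j <- which(bad)[1]
      stop("code ", code[j], " out of range for ", row$id, " (max ",
           spec$max_code, ") at ", wide$CountryCode[j], " ",
           format(dates[j]), call. = FALSE)
    }
    flag_col <- flag_cols$column[flag_cols$id == row$id &
                                 flag_cols$variant == row$variant]
    flag <- if (length(flag_col) == 1 && spec$has_flag) {
      suppressWarnings(as.integer(wide[[flag_col]]))
    } else {
      rep(NA_integer_, nrow(wide))
    }
    code_kept <- code[keep]
    flag_kept <- ifelse(spec$has_flag & code_kept > 0L, flag[keep], NA_integer_)
    tibble::tibble(
      country_code = wide$CountryCode[keep],
      country_name = wide$CountryName[keep],
      date = dates[keep],
      indicator = row$id,
      status_group = unname(dialect$status[row$variant]),
      code = code_kept,
      flag = as.integer(flag_kept)
    )
  })
  if (nrow(obs) > 0) {
    nd <- codebook$id[!codebook$differentiated]
    obs$status_group[obs$indicator %in% nd] <- "shared"
  }

  idx_cols <- value_cols[idx_keep]
  indices <- purrr::map_dfr(idx_cols, function(cn) {
    m <- regmatches(cn, regexec(dialect$index, cn))[[1]]
    val <- suppressWarnings(as.numeric(wide[[cn]]))
    keep <- !is.na(val)
    tibble::tibble(
      country_code = wide$CountryCode[keep], date = dates[keep],
      index_name = unname(dialect$index_names[m[2]]),
      status_group = unname(dialect$index_status[m[3]]),
      value = val[keep]
    )
  })
  if (nrow(indices) > 0 && any(indices$value < 0 | indices$value > 100)) {
    stop("published index value outside [0, 100]", call. = FALSE)
  }
  list(observations = obs, indices = indices)
}

#' Published composite index columns as an index-series table
#'
#' Reshapes the `indices` element of [read_policy_panel()] into the same
#' layout as [build_index_series()], so the discrimination metric can be
#' computed from the panel's pre-calculated index columns (the
#' reproduction path) instead of from recomputed indices.
#'
#' @param indices The `indices` tibble from [read_policy_panel()].
#' @param index_name `"CHI"` or `"STRINGENCY"`.
#' @param country_names Optional named vector mapping country codes to
#'   names.
#' @return Index-series tibble restricted to the non-vaccinated and
#'   vaccinated status groups.
#' @export
published_index_series <- function(indices, index_name = c("CHI", "STRINGENCY"),
                                   country_names = NULL) {
  index_name <- match.arg(index_name)
  out <- indices[indices$index_name == index_name &
                 indices$status_group %in% c("non_vaccinated", "vaccinated"), ]
  out$country_name <- if (is.null(country_names)) out$country_code else
    unname(country_names[out$country_code])
  out <- out[order(out$country_code, out$status_group, out$date),
             c("country_code", "country_name", "index_name", "status_group",
               "date", "value")]
  tibble::as_tibble(out)
}

#' Write a synthetic panel as a wide CSV in the v1 dialect
#'
#' Serialises a long observation table (plus optional pre-computed index
#' columns) into the wide one-row-per-country-day layout that
#' [read_policy_panel()] reads, with 8-digit dates, status-variant column
#' suffixes and blank cells for absent observations and for flags on
#' zero codes.
#'
#' @param observations Observation tibble (see [generate_panel()]).
#' @param path Output CSV path.
#' @param codebook Codebook tibble (provides column labels).
#' @param indices Optional `indices` tibble to embed as pre-computed index
#'   columns.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(observations, path, codebook = default_codebook(),
                            indices = NULL) {
  obs <- dplyr::as_tibble(observations)
  lab <- stats::setNames(gsub(" ", ".", codebook$label), codebook$id)
  variant <- c(shared = "M", non_vaccinated = "NV", vaccinated = "V")
  has_flag <- stats::setNames(codebook$has_flag, codebook$id)
  obs$colname <- paste0(obs$indicator, variant[obs$status_group], "_",
                        lab[obs$indicator])
  codes <- tidyr::pivot_wider(
    obs[, c("country_code", "country_name", "date", "colname", "code")],
    names_from = "colname", values_from = "code")
  fobs <- obs[has_flag[obs$indicator] & !is.na(obs$flag), ]
  if (nrow(fobs) > 0) {
    fobs$colname <- paste0(fobs$indicator, variant[fobs$status_group], "_Flag")
    flags <- tidyr::pivot_wider(
      fobs[, c("country_code", "date", "colname", "flag")],
      names_from = "colname", values_from = "flag")
    codes <- dplyr::left_join(codes, flags, by = c("country_code", "date"))
  }
  if (!is.null(indices) && nrow(indices) > 0) {
    idx <- indices
    nm <- c(CHI = "ContainmentHealthIndex", STRINGENCY = "StringencyIndex")
    st <- c(average = "Average", non_vaccinated = "NonVaccinated",
            vaccinated = "Vaccinated")
    idx$colname <- paste0(nm[idx$index_name], "_", st[idx$status_group])
    idx$value <- round(idx$value, 2)
    idxw <- tidyr::pivot_wider(
      idx[, c("country_code", "date", "colname", "value")],
      names_from = "colname", values_from = "value")
    codes <- dplyr::left_join(codes, idxw, by = c("country_code", "date"))
  }
  out <- dplyr::tibble(
    CountryName = codes$country_name, CountryCode = codes$country_code,
    RegionName = "", RegionCode = "", Jurisdiction = "NAT_TOTAL",
    Date = as.integer(format(codes$date, "%Y%m%d"))
  )
  out <- dplyr::bind_cols(
    out, codes[, setdiff(names(codes), c("country_code", "country_name", "date"))])
  out <- out[order(out$CountryCode, out$Date), ]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a countries-by-continent lookup table
#'
#' Accepts a delimited file carrying country name, ISO alpha-3 code,
#' sub-region and continent under the canonical names (`country_name`,
#' `iso3`, `sub_region`, `continent`) or common aliases as found in
#' UNSD-derived lists (`Country or Area`, `ISO-alpha3 Code`, `Region 1`,
#' `Continent`).
#'
#' @param path CSV path.
#' @return Tibble `(country_name, iso3, sub_region, continent)` with
#'   unique `iso3` keys; an empty file yields an empty tibble with a
#'   warning.
#' @export
read_country_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    warning("empty region list: ", path, call. = FALSE)
    return(tibble::tibble(country_name = character(), iso3 = character(),
                          sub_region = character(), continent = character()))
  }
  norm <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
  aliases <- list(
    country_name = c("country_name", "country", "country_or_area", "name"),
    iso3 = c("iso3", "iso_alpha3_code", "iso_alpha_3", "country_code", "iso"),
    sub_region = c("sub_region", "subregion", "region_1", "region", "world_region"),
    continent = c("continent")
  )
  nm <- norm(names(df))
  picked <- lapply(aliases, function(a) which(nm %in% a)[1])
  missing <- names(picked)[vapply(picked, is.na, logical(1))]
  if (length(missing) > 0) {
    stop("region list lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    country_name = as.character(df[[picked$country_name]]),
    iso3 = as.character(df[[picked$iso3]]),
    sub_region = as.character(df[[picked$sub_region]]),
    continent = as.character(df[[picked$continent]])
  )
  dups <- out$iso3[duplicated(out$iso3)]
  if (length(dups) > 0) {
    stop("duplicate iso3 code(s) in region list: ",
         paste(unique(dups), collapse = ", "), call. = FALSE)
  }
  out
}

#' Join panel countries to the region lookup
#'
#' Every panel country is either matched by ISO alpha-3 code or reported
#' in the unmatched list — countries absent from the lookup (e.g. Kosovo
#' in UNSD-derived lists) are surfaced, never silently dropped.
#'
#' @param panel_countries Character vector of panel country codes.
#' @param regions Region tibble from [read_country_regions()].
#' @return List with `matched` (tibble `iso3`, `country_name`,
#'   `sub_region`, `continent`) and `unmatched` (character vector).
#' @export
join_regions <- function(panel_countries, regions) {
  codes <- unique(panel_countries)
  hit <- codes %in% regions$iso3
  matched <- regions[match(codes[hit], regions$iso3),
                     c("iso3", "country_name", "sub_region", "continent")]
  list(matched = tibble::as_tibble(matched), unmatched = codes[!hit])
}

#' Write a series or summary table as tidy long CSV
#'
#' Numeric value columns are rounded to 2 decimals at this export
#' boundary (internal arithmetic stays at full precision), so a write /
#' re-read round-trip preserves values to 2 decimals.
#'
#' @param x A tibble (one row per country-day or per country).
#' @param path Output CSV path.
#' @param digits Decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_tidy <- function(x, path, digits = 2) {
  out <- dplyr::as_tibble(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a tidy CSV written by [write_tidy()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_tidy <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
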