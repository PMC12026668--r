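#' Flag-adjusted sub-index score for one indicator
#'
#' Maps an ordinal policy code onto a 0--100 scale. A code of 0 (no
#' measure) always scores 0. For flagged indicators a regionally targeted
#' measure (flag = 0) is penalised by half a code step before
#' normalisation:
#'
#' \deqn{s = 100 \, (v - 0.5\,(1 - f)) / N}
#'
#' where \eqn{v} is the code, \eqn{f} the flag and \eqn{N} the indicator's
#' maximum code. Unflagged indicators score \eqn{100 v / N}. Vectorised
#' over `code` and `flag`.
#'
#' @param code Integer code(s), `0 <= code <= max_code`.
#' @param flag Binary flag(s); required for positive codes of flagged
#'   indicators, must be `NULL`/`NA` for unflagged indicators.
#' @param max_code The indicator's maximum ordinal code.
#' @param has_flag Does the indicator carry a geographic-scope flag?
#' @return Numeric score(s) in `[0, 100]`.
#' @examples
#' subindex(3, 1, max_code = 3, has_flag = TRUE)   # 100
#' subindex(3, 0, max_code = 3, has_flag = TRUE)   # 83.33
#' subindex(4, NULL, max_code = 4, has_flag = FALSE)  # 100
#' @export
subindex <- function(code, flag = NULL, max_code, has_flag = TRUE) {
  if (is.null(flag)) flag <- rep(NA_real_, length(code))
  n <- max(length(code), length(flag))
  code <- rep_len(as.numeric(code), n)
  flag <- rep_len(as.numeric(flag), n)
  if (any(is.na(code))) stop("code must not be missing", call. = FALSE)
  if (any(code < 0 | code > max_code)) {
    stop("code out of range [0, ", max_code, "]", call. = FALSE)
  }
  if (any(code != floor(code))) stop("code must be integral", call. = FALSE)
  if (!has_flag && any(!is.na(flag))) {
    stop("flag supplied for an unflagged indicator", call. = FALSE)
  }
  if (has_flag && any(code > 0 & is.na(flag))) {
    stop("flag required for positive codes of a flagged indicator", call. = FALSE)
  }
  if (has_flag && any(!is.na(flag) & !flag %in% c(0, 1))) {
    stop("flag must be 0 or 1", call. = FALSE)
  }
  penalty <- if (has_flag) 0.5 * (1 - flag) else 0
  score <- 100 * (code - penalty) / max_code
  ifelse(code == 0, 0, score)
}

#' Composite index from one country-day's sub-index scores
#'
#' The composite index is the unweighted mean of the member indicators'
#' sub-index scores: 14 members for the Containment and Health Index,
#' 9 for the Stringency Index. In strict mode (default) every member must
#' be present; with `partial = TRUE` the mean is taken over the members
#' that are present (and the omission is the caller's responsibility to
#' log).
#'
#' @param scores Named numeric vector of sub-index scores keyed by
#'   indicator id.
#' @param index_name `"CHI"` or `"STRINGENCY"`.
#' @param codebook Codebook tibble, see [default_codebook()].
#' @param partial Average over present members instead of erroring when a
#'   member is absent.
#' @return A single score in `[0, 100]`.
#' @examples
#' cb <- default_codebook()
#' s <- stats::setNames(rep(0, 14), index_members(cb, "CHI"))
#' s["C1"] <- 100
#' composite_index(s, "CHI", cb)  # 100/14 = 7.142857
#' @export
composite_index <- function(scores, index_name = c("CHI", "STRINGENCY"),
                            codebook = default_codebook(), partial = FALSE) {
  index_name <- match.arg(index_name)
  members <- index_members(codebook, index_name)
  have <- intersect(members, names(scores))
  missing <- setdiff(members, have)
  if (length(missing) > 0 && !partial) {
    stop(index_name, " member indicator(s) absent: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(have) == 0) stop("no member scores available", call. = FALSE)
  vals <- scores[have]
  if (any(vals < 0 | vals > 100)) stop("scores must lie in [0, 100]", call. = FALSE)
  mean(vals)
}

#' Daily composite index series per country and vaccination-status group
#'
#' Builds the non-vaccinated and vaccinated variants of a composite index
#' from a long observation table. For each status group, a differentiated
#' indicator contributes its group-specific observation on days where one
#' exists and its shared (undifferentiated) observation otherwise;
#' non-differentiated indicators contribute their shared observation to
#' both groups identically. Days before any differentiation therefore
#' yield identical values for both groups.
#'
#' @param observations Tibble of policy observations with columns
#'   `country_code`, `country_name`, `date`, `indicator`, `status_group`
#'   (`"shared"`, `"non_vaccinated"` or `"vaccinated"`), `code`, `flag`.
#' @param codebook Codebook tibble.
#' @param index_name `"CHI"` or `"STRINGENCY"`.
#' @param partial Permissive mode: average over present members on
#'   country-days with gaps instead of erroring (gaps are reported via a
#'   warning naming the affected country-days).
#' @return Tibble with columns `country_code`, `country_name`,
#'   `index_name`, `status_group` (`"non_vaccinated"`/`"vaccinated"`),
#'   `date`, `value`; one row per country-day-group, dates contiguous per
#'   country.
#' @export
build_index_series <- function(observations, codebook = default_codebook(),
                               index_name = c("CHI", "STRINGENCY"),
                               partial = FALSE) {
  index_name <- match.arg(index_name)
  obs <- dplyr::as_tibble(observations)
  members <- index_members(codebook, index_name)
  obs <- obs[obs$indicator %in% members, , drop = FALSE]

  # identical repeats are harmless; only contradictory duplicates are fatal
  obs <- dplyr::distinct(obs)
  dup <- obs |>
    dplyr::count(.data$country_code, .data$date, .data$indicator,
                 .data$status_group) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("contradictory duplicate observations, e.g. ",
         dup$country_code[1], " ", format(dup$date[1]), " ",
         dup$indicator[1], " (", dup$status_group[1], ")", call. = FALSE)
  }

  spec <- codebook[match(obs$indicator, codebook$id), ]
  obs$score <- 100 * (obs$code -
    ifelse(spec$has_flag, 0.5 * (1 - dplyr::coalesce(obs$flag, 1)), 0)) /
    spec$max_code
  obs$score[obs$code == 0] <- 0

  shared <- obs[obs$status_group == "shared",
                c("country_code", "country_name", "date", "indicator", "score")]
  out <- lapply(c("non_vaccinated", "vaccinated"), function(g) {
    grp <- obs[obs$status_group == g,
               c("country_code", "date", "indicator", "score")]
    merged <- dplyr::left_join(
      shared, grp,
      by = c("country_code", "date", "indicator"),
      suffix = c("_shared", "_group")
    )
    merged$score <- dplyr::coalesce(merged$score_group, merged$score_shared)
    merged |>
      dplyr::group_by(.data$country_code, .data$country_name, .data$date) |>
      dplyr::summarise(value = mean(.data$score),
                       n_members = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(status_group = g)
  })
  out <- dplyr::bind_rows(out)

  gaps <- out[out$n_members < length(members), ]
  if (nrow(gaps) > 0) {
    if (!partial) {
      stop("missing ", index_name, " member(s) on ", nrow(gaps),
           " country-day(s), e.g. ", gaps$country_code[1], " ",
           format(gaps$date[1]), "; use partial = TRUE to average over ",
           "present members", call. = FALSE)
    }
    warning("averaged over present members on ", nrow(gaps),
            " country-day(s), e.g. ", gaps$country_code[1], " ",
            format(gaps$date[1]), call. = FALSE)
  }

  out$index_name <- index_name
  out <- out[order(out$country_code, out$status_group, out$date),
             c("country_code", "country_name", "index_name", "status_group",
               "date", "value")]
  assert_contiguous_dates(out, c("country_code", "status_group"))
  tibble::as_tibble(out)
}

#' @keywords internal
assert_contiguous_dates <- function(df, keys) {
  check <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      ok = all(diff(sort(as.integer(.data$date))) == 1L),
      .groups = "drop"
    )
  if (!all(check$ok)) {
    bad <- check[!check$ok, keys[1], drop = TRUE]
    stop("date axis has gaps or duplicates for: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
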