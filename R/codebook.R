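#' Indicator codebook for the Containment and Health Index
#'
#' The codebook lists the 14 ordinal policy indicators that make up the
#' Containment and Health Index (CHI): the eight containment-and-closure
#' indicators C1--C8 and the health-system indicators H1, H2, H3, H6, H7
#' and H8. Nine of them (C1--C8 plus H1) also form the Stringency Index.
#' Ten indicators (C1--C8, H6, H8) were recorded separately for vaccinated
#' and non-vaccinated individuals once a jurisdiction differentiated its
#' policies by vaccination status.
#'
#' Each indicator carries an ordinal code from 0 (no measure) up to an
#' indicator-specific maximum, and most carry a binary geographic-scope
#' flag (1 = nationwide, 0 = targeted to a specific region) that triggers
#' a 0.5-point deduction in the sub-index. C8, H2 and H3 have no flag.
#' H7's companion variable records cost to the individual rather than
#' geographic scope; by default it participates in the flag arithmetic the
#' same way, and `h7_flag = FALSE` turns that off.
#'
#' @param h7_flag Logical; treat H7's cost companion as a sub-index flag
#'   (default `TRUE`).
#' @return A tibble with one row per indicator and columns `id`, `label`,
#'   `max_code`, `has_flag`, `differentiated`, `in_chi`, `in_stringency`.
#' @examples
#' cb <- default_codebook()
#' sum(cb$in_chi)          # 14
#' sum(cb$in_stringency)   # 9
#' sum(cb$differentiated)  # 10
#' @export
default_codebook <- function(h7_flag = TRUE) {
  cb <- tibble::tribble(
    ~id,  ~label,                                ~max_code, ~has_flag, ~differentiated,
    "C1", "School closing",                       3L, TRUE,  TRUE,
    "C2", "Workplace closing",                    3L, TRUE,  TRUE,
    "C3", "Cancel public events",                 2L, TRUE,  TRUE,
    "C4", "Restrictions on gatherings",           4L, TRUE,  TRUE,
    "C5", "Close public transport",               2L, TRUE,  TRUE,
    "C6", "Stay at home requirements",            3L, TRUE,  TRUE,
    "C7", "Restrictions on internal movement",    2L, TRUE,  TRUE,
    "C8", "International travel controls",        4L, FALSE, TRUE,
    "H1", "Public information campaigns",         2L, TRUE,  FALSE,
    "H2", "Testing policy",                       3L, FALSE, FALSE,
    "H3", "Contact tracing",                      2L, FALSE, FALSE,
    "H6", "Facial coverings",                     4L, TRUE,  TRUE,
    "H7", "Vaccination policy",                   5L, TRUE,  FALSE,
    "H8", "Protection of elderly people",         3L, TRUE,  TRUE
  )
  if (!h7_flag) cb$has_flag[cb$id == "H7"] <- FALSE
  cb$in_chi <- TRUE
  cb$in_stringency <- cb$id %in% c(paste0("C", 1:8), "H1")
  validate_codebook(cb)
}

#' Load a codebook from a YAML or JSON config file
#'
#' The file holds a list of indicator records mirroring the columns of
#' [default_codebook()]: `id`, `label`, `max_code`, `has_flag`,
#' `differentiated`, `in_chi`, `in_stringency`. This allows extending the
#' schema (e.g. with V-series indicators) without code changes.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated codebook tibble.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  recs <- if (is.data.frame(raw)) raw else dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  needed <- c("id", "label", "max_code", "has_flag", "differentiated",
              "in_chi", "in_stringency")
  missing <- setdiff(needed, names(recs))
  if (length(missing) > 0) {
    stop("codebook config lacks fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cb <- tibble::as_tibble(recs[needed])
  cb$max_code <- as.integer(cb$max_code)
  for (f in c("has_flag", "differentiated", "in_chi", "in_stringency")) {
    cb[[f]] <- as.logical(cb[[f]])
  }
  validate_codebook(cb)
}

#' @keywords internal
validate_codebook <- function(cb) {
  stopifnot(is.data.frame(cb))
  if (anyDuplicated(cb$id)) stop("codebook ids must be unique", call. = FALSE)
  if (any(cb$max_code < 1L)) stop("max_code must be >= 1", call. = FALSE)
  if (any(cb$differentiated & !cb$in_chi)) {
    stop("every differentiated indicator must belong to the CHI", call. = FALSE)
  }
  cb
}

#' Member indicator ids of a composite index
#'
#' @param codebook A codebook tibble.
#' @param index_name `"CHI"` or `"STRINGENCY"`.
#' @return Character vector of indicator ids.
#' @export
index_members <- function(codebook, index_name = c("CHI", "STRINGENCY")) {
  index_name <- match.arg(index_name)
  col <- if (index_name == "CHI") "in_chi" else "in_stringency"
  codebook$id[codebook[[col]]]
}
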