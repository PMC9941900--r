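#' Round half away from zero
#'
#' Decimal rounding that sends exact halves up (2.5 -> 3, 0.345 -> 0.35 at two
#' digits), matching how percentages are conventionally printed in reports.
#' Base R's `round()` rounds halves to even, which would print 0.5 as 0.
#'
#' @param x numeric vector (non-negative values expected for report use).
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(c(18.999, 34.435, 84.829), 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Parse yes/no, TRUE/FALSE, 1/0 vote encodings to logical.
parse_binary_label <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x))) {
      abort("numeric labels must be 0 or 1")
    }
    return(x == 1)
  }
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("yes", "y", "true", "1", "misinformation")] <- TRUE
  out[lx %in% c("no", "n", "false", "0", "nonmisinformation")] <- FALSE
  bad <- !is.na(lx) & lx != "" & is.na(out)
  if (any(bad)) {
    abort(paste0("unrecognised label value(s): ",
                 paste(unique(lx[bad]), collapse = ", ")))
  }
  out
}

# ISO-8601 timestamps (date or finer) -> POSIXct UTC; NA allowed.
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, "UTC"))
  if (inherits(x, "Date")) return(lubridate::as_datetime(x, tz = "UTC"))
  x <- as.character(x)
  out <- lubridate::as_datetime(rep(NA_real_, length(x)), tz = "UTC")
  has <- !is.na(x) & trimws(x) != ""
  if (any(has)) {
    parsed <- suppressWarnings(lubridate::ymd_hms(x[has], tz = "UTC", quiet = TRUE))
    miss <- is.na(parsed)
    if (any(miss)) {
      parsed[miss] <- suppressWarnings(
        lubridate::as_datetime(lubridate::ymd(x[has][miss], quiet = TRUE), tz = "UTC"))
    }
    if (anyNA(parsed)) {
      abort(paste0("unparseable ISO-8601 timestamp(s): ",
                   paste(unique(x[has][is.na(parsed)]), collapse = ", ")))
    }
    out[has] <- parsed
  }
  out
}

# Extract a named logical label vector keyed by text id from the accepted
# label representations: a corpus tibble with id + label, or a named vector.
as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("id", "label") %in% names(labels))) {
      abort("a label data frame needs columns `id` and `label`")
    }
    out <- parse_binary_label(labels$label)
    names(out) <- labels$id
    return(out)
  }
  if (is.null(names(labels)) || any(names(labels) == "")) {
    abort("labels must be a named vector (names = text ids) or a data frame")
  }
  setNames(parse_binary_label(labels), names(labels))
}
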