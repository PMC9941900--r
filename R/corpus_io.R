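#' Read a short-text corpus from JSONL or CSV
#'
#' A corpus is a flat table of short texts (tweets, typically) with an opaque
#' unique `id`, the raw `text`, an optional ISO-8601 timestamp `created_at`,
#' and an optional annotation layer `votes`: one binary misinformation vote
#' ("yes"/"no") per annotator. In JSONL each line is one object with those
#' keys (`votes` an array); in CSV the same names head the columns and votes
#' are semicolon-joined (`"yes;no;yes"`). Masked tokens such as
#' `<MASKED-URL>` are ordinary text and round-trip unchanged.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"jsonl"`, or `"csv"`.
#' @param dedup_text drop records whose text duplicates an earlier record's
#'   (first occurrence kept). Default keeps exact duplicates.
#' @return a tibble with columns `id`, `text`, `created_at` (POSIXct, UTC,
#'   `NA` when absent), `votes` (list of logical vectors, `NULL` when
#'   unannotated) and `label` (majority vote, `NA` when unannotated or when
#'   the vote count is even).
#' @seealso [write_corpus()], [read_anchors()]
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"),
                        dedup_text = FALSE) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) abort(paste0("corpus file not found: ", path))
  recs <- if (format == "jsonl") read_corpus_jsonl(path) else read_corpus_csv(path)

  dup <- recs$id[duplicated(recs$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate record id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(trimws(recs$text)))) {
    abort("corpus records must have non-empty text")
  }
  if (dedup_text) recs <- recs[!duplicated(recs$text), ]
  recs$label <- map_lgl(recs$votes, function(v) {
    if (is.null(v) || length(v) == 0 || length(v) %% 2 == 0) return(NA)
    majority_label(v)
  })
  as_tibble(recs)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(id = character(), text = character(),
                  created_at = parse_timestamp(character()),
                  votes = list()))
  }
  rows <- map(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
      abort(paste0("line ", i, ": invalid JSON (", conditionMessage(e), ")"))
    })
    for (fld in c("id", "text")) {
      if (is.null(obj[[fld]]) || !nzchar(as.character(obj[[fld]])[1])) {
        abort(paste0("line ", i, ": missing required field `", fld, "`"))
      }
    }
    list(id = as.character(obj$id), text = as.character(obj$text),
         created_at = if (is.null(obj$created_at)) NA_character_
                      else as.character(obj$created_at),
         votes = if (is.null(obj$votes)) NULL
                 else parse_binary_label(unlist(obj$votes)))
  })
  tibble(
    id = map_chr(rows, "id"),
    text = map_chr(rows, "text"),
    created_at = parse_timestamp(map_chr(rows, "created_at")),
    votes = map(rows, "votes")
  )
}

read_corpus_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  for (fld in c("id", "text")) {
    if (!fld %in% names(df)) abort(paste0("corpus CSV lacks column `", fld, "`"))
    bad <- which(is.na(df[[fld]]) | !nzchar(df[[fld]]))
    if (length(bad) > 0) {
      abort(paste0("line ", bad[1] + 1, ": missing required field `", fld, "`"))
    }
  }
  tibble(
    id = df$id,
    text = df$text,
    created_at = parse_timestamp(if ("created_at" %in% names(df)) df$created_at
                                 else rep(NA_character_, nrow(df))),
    votes = if ("votes" %in% names(df)) {
      map(df$votes, function(v) {
        if (is.na(v) || !nzchar(v)) NULL
        else parse_binary_label(strsplit(v, ";", fixed = TRUE)[[1]])
      })
    } else rep(list(NULL), nrow(df))
  )
}

#' Write a corpus to JSONL or CSV
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p), p)` returns an
#' identical record collection (ids, texts, timestamps, votes).
#'
#' @param records corpus tibble as returned by [read_corpus()] (the `label`
#'   column, being derived, is not written).
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path, format = c("auto", "jsonl", "csv")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  ts <- ifelse(is.na(records$created_at), NA_character_,
               format(records$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  votes_chr <- map(records$votes %||% rep(list(NULL), nrow(records)),
                   function(v) if (is.null(v)) NULL else ifelse(v, "yes", "no"))
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      obj <- list(id = records$id[i], text = records$text[i])
      if (!is.na(ts[i])) obj$created_at <- ts[i]
      if (!is.null(votes_chr[[i]])) obj$votes <- votes_chr[[i]]
      jsonlite::toJSON(obj, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- tibble(id = records$id, text = records$text, created_at = ts,
                 votes = map_chr(votes_chr, function(v) {
                   if (is.null(v)) NA_character_ else paste(v, collapse = ";")
                 }))
    readr::write_csv(df, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Read an anchor-quote set
#'
#' Anchors are verbatim exemplars of known misinformation (for example the
#' misleading promotional statements quoted in FDA Warning Letters) used as
#' queries for semantic screening. Accepted as a JSON array of objects
#' `{anchor_id, source, text}` or as a CSV with those columns.
#'
#' @param path file to read (`.json` or `.csv`).
#' @return tibble with columns `anchor_id`, `source`, `text`, in file order.
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) abort(paste0("anchor file not found: ", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  } else {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  if (length(df) == 0 || NROW(df) == 0) abort("anchor set must be non-empty")
  df <- as_tibble(df)
  for (fld in c("anchor_id", "source", "text")) {
    if (!fld %in% names(df)) abort(paste0("anchor file lacks field `", fld, "`"))
  }
  df <- df[, c("anchor_id", "source", "text")]
  dup <- unique(df$anchor_id[duplicated(df$anchor_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate anchor_id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(trimws(df$text)))) abort("anchor texts must be non-empty")
  df
}

#' Write an anchor set as a JSON array
#'
#' @param anchors tibble with `anchor_id`, `source`, `text`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  jsonlite::write_json(anchors[, c("anchor_id", "source", "text")], path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Packaged anchor quotes from FDA Warning Letters
#'
#' The misleading CBD/COVID-19 promotional statements quoted verbatim in
#' public FDA Warning Letters, as packaged with anchorscreen. These are the
#' default anchor set for screening commercial CBD tweets for COVID-19
#' misinformation; supply your own file to [read_anchors()] to screen for
#' other claims.
#'
#' @return tibble with `anchor_id`, `source`, `text`.
#' @export
default_anchors <- function() {
  read_anchors(system.file("extdata", "fda_warning_letter_quotes.json",
                           package = "anchorscreen", mustWork = TRUE))
}

#' Keep only records passing a prefilter predicate
#'
#' Hook for an upstream relevance filter (in the motivating study, a
#' commercial-tweet classifier selected commercial CBD tweets before
#' screening). Order is preserved.
#'
#' @param records corpus tibble.
#' @param predicate function taking one record (a one-row list with `id`,
#'   `text`, ...) and returning `TRUE`/`FALSE`, or a function of the text
#'   vector returning a logical vector (detected by trying the vectorised
#'   form first).
#' @return the sub-tibble of records where the predicate holds.
#' @export
apply_prefilter <- function(records, predicate) {
  keep <- tryCatch({
    out <- predicate(records$text)
    if (is.logical(out) && length(out) == nrow(records)) out else NULL
  }, error = function(e) NULL)
  if (is.null(keep)) {
    keep <- map_lgl(seq_len(nrow(records)), function(i) {
      isTRUE(predicate(as.list(records[i, ])))
    })
  }
  records[keep, ]
}
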