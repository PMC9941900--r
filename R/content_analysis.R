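# Social-media-aware cleanup before n-gram tokenization: lower-case, strip
# URLs and @handles, drop the '#' so hashtag words survive as plain tokens.
clean_for_ngrams <- function(texts) {
  x <- tolower(texts)
  x <- stringr::str_replace_all(x, "(https?://|www\\.)\\S+", " ")
  x <- stringr::str_replace_all(x, "@[[:alnum:]_]+", " ")
  x <- stringr::str_replace_all(x, "#", "")
  x
}

#' n-gram frequency table
#'
#' Counts unigram and/or bigram occurrences across a corpus, the standard
#' first look at what a captured misinformation set talks about (for the
#' CBD/COVID-19 screen: "immune", "immune system", "boost", "sanitizer",
#' ...). Texts are lower-cased; URLs and user handles are stripped; the
#' `#` character is removed so hashtag words count as ordinary tokens;
#' tokens are split on non-alphanumerics; stopwords are removed before
#' n-grams are formed (so a bigram can bridge a removed stopword). Counts
#' are total occurrences, not document frequencies. Unigrams and bigrams
#' rank in one combined table.
#'
#' @param texts character vector, or a corpus tibble with a `text` column.
#' @param n_values n-gram orders, subset of `c(1, 2)`.
#' @param stopwords character vector; [default_stopwords()] by default.
#' @param top_k rows to return.
#' @return tibble `(term, frequency)`, frequency descending, ties broken
#'   lexicographically by term. Empty corpus (or all-stopword corpus) gives
#'   an empty table.
#' @export
ngram_frequencies <- function(texts, n_values = c(1, 2),
                              stopwords = default_stopwords(), top_k = 20) {
  if (top_k < 1) abort("top_k must be at least 1")
  if (!all(n_values %in% c(1, 2))) abort("n_values must be a subset of c(1, 2)")
  if (is.data.frame(texts)) texts <- texts$text
  empty <- tibble(term = character(), frequency = integer())
  if (length(texts) == 0) return(empty)

  toks <- tokenize(clean_for_ngrams(texts), case_folding = FALSE)
  toks <- map(toks, function(t) t[!t %in% stopwords])

  terms <- character(0)
  if (1 %in% n_values) terms <- c(terms, unlist(toks))
  if (2 %in% n_values) {
    bigrams <- unlist(map(toks, function(t) {
      if (length(t) < 2) return(character(0))
      paste(t[-length(t)], t[-1])
    }))
    terms <- c(terms, bigrams)
  }
  if (length(terms) == 0) return(empty)

  tab <- table(terms)
  out <- tibble(term = names(tab), frequency = as.integer(tab))
  out <- arrange(out, desc(.data$frequency), .data$term)
  head(out, top_k)
}

#' Monthly tweet volume
#'
#' Counts timestamped records per UTC calendar month, filling interior gaps
#' with zero so trend plots do not skip silent months. Records without a
#' timestamp are excluded (and an error is raised when none carry one).
#'
#' @param records corpus tibble with a `created_at` POSIXct column.
#' @return tibble `(month, n)`: `month` the first day of the month (Date),
#'   chronologically ordered; counts sum to the number of timestamped
#'   records.
#' @export
monthly_volume <- function(records) {
  ts <- records$created_at
  ts <- ts[!is.na(ts)]
  if (length(ts) == 0) abort("no timestamped records: monthly volume is undefined")
  m <- lubridate::floor_date(lubridate::as_date(ts), "month")
  months <- seq(min(m), max(m), by = "month")
  counts <- table(factor(as.character(m), levels = as.character(months)))
  tibble(month = months, n = as.integer(counts))
}

#' Plot a monthly volume series
#'
#' @param object output of [monthly_volume()].
#' @param ... unused.
#' @return a ggplot line chart of monthly counts.
#' @export
plot_monthly_volume <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$month, y = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Month", y = "Tweets", title = "Monthly tweet volume") +
    ggplot2::theme_minimal()
}

#' Plot an n-gram frequency table
#'
#' @param object output of [ngram_frequencies()].
#' @param ... unused.
#' @return a ggplot horizontal bar chart, most frequent term on top.
#' @export
plot_ngram_table <- function(object, ...) {
  object$term <- factor(object$term, levels = rev(object$term))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Occurrences", y = NULL, title = "Top n-grams") +
    ggplot2::theme_minimal()
}
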