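#' Majority vote over an odd number of binary annotations
#'
#' Resolves annotator discrepancies by majority vote, the standard way a
#' panel of 3 independent coders settles a yes/no misinformation label. An
#' even number of votes can tie and is rejected rather than tie-broken.
#'
#' @param votes binary labels: logical, 0/1, or "yes"/"no". Length must be odd.
#' @return single logical: the modal vote (`TRUE` = misinformation).
#' @examples
#' majority_label(c("yes", "yes", "no"))
#' @export
majority_label <- function(votes) {
  v <- parse_binary_label(votes)
  if (length(v) == 0 || anyNA(v)) abort("votes must be non-missing binary labels")
  if (length(v) %% 2 == 0) {
    abort("majority vote needs an odd number of votes (ties are undefined)")
  }
  sum(v) > length(v) / 2
}

#' Intercoder agreement: fraction of unanimously labeled records
#'
#' The proportion of annotated records on which ALL annotators assigned the
#' same label. Equals 1 exactly when every record is unanimous, and is
#' invariant to annotator order within records.
#'
#' @param annotations a corpus tibble with a `votes` list-column, or a bare
#'   list of per-record vote vectors. Every record must carry the same
#'   number of votes.
#' @return fraction in `[0, 1]`.
#' @examples
#' intercoder_agreement(list(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, TRUE)))
#' @export
intercoder_agreement <- function(annotations) {
  votes <- if (is.data.frame(annotations)) annotations$votes else annotations
  votes <- votes[!map_lgl(votes, is.null)]
  if (length(votes) == 0) abort("no annotated records: agreement is undefined")
  k <- unique(map_int(votes, length))
  if (length(k) != 1) abort("all records must have the same number of annotators")
  v <- map(votes, parse_binary_label)
  mean(map_lgl(v, function(x) all(x) || !any(x)))
}
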