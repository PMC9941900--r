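#' Cosine similarity and cosine distance between two vectors
#'
#' Cosine similarity is `dot(a, b) / (||a|| * ||b||)`, in `[-1, 1]`
#' (in `[0, 1]` for the non-negative count vectors of the reference
#' encoder); cosine distance is one minus that. A zero vector has no
#' direction: its similarity to anything is defined as 0 (distance 1), with
#' a warning, consistently with how zero-embedding texts are screened.
#'
#' @param a,b numeric vectors of equal length.
#' @return a single numeric score.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' cosine_distance(c(1, 0), c(1, 1))   # 1 - 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("vectors have different dimensions")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warn("zero vector in cosine similarity; returning similarity 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' @rdname cosine_similarity
#' @export
cosine_distance <- function(a, b) 1 - cosine_similarity(a, b)

#' Anchor-by-text cosine distance matrix
#'
#' Computes all pairwise cosine distances between an anchor embedding matrix
#' and a corpus embedding matrix. Entry `(i, j)` is the distance from anchor
#' `i` to text `j`, in `[0, 2]` generally and `[0, 1]` under the
#' non-negative reference encoder. Rows flagged as zero vectors get distance
#' exactly 1 to every counterpart.
#'
#' @param anchors,texts `text_embeddings` objects (see [encode_texts()]) of
#'   equal dimension.
#' @return an `anchor_distances` object: list with `anchor_ids`, `text_ids`,
#'   and `D`, the distances matrix (anchors in rows). `tidy()` converts it to
#'   a long tibble `(anchor_id, text_id, distance)`.
#' @export
distance_matrix <- function(anchors, texts) {
  stopifnot(inherits(anchors, "text_embeddings"), inherits(texts, "text_embeddings"))
  if (anchors$d != texts$d) {
    abort(paste0("dimension mismatch: anchors have d = ", anchors$d,
                 ", texts have d = ", texts$d))
  }
  A <- if (anchors$normalized) anchors$vectors else l2_normalize(anchors$vectors)
  B <- if (texts$normalized) texts$vectors else l2_normalize(texts$vectors)
  S <- A %*% t(B)
  if (any(anchors$zero_rows)) S[anchors$zero_rows, ] <- 0
  if (any(texts$zero_rows)) S[, texts$zero_rows] <- 0
  D <- 1 - S
  D[D < 0] <- 0
  D[D > 2] <- 2
  structure(
    list(anchor_ids = anchors$ids, text_ids = texts$ids, D = D),
    class = "anchor_distances"
  )
}

#' @export
print.anchor_distances <- function(x, ...) {
  cat("<anchor_distances> ", length(x$anchor_ids), " anchors x ",
      length(x$text_ids), " texts; range [",
      sprintf("%.4f", min(x$D)), ", ", sprintf("%.4f", max(x$D)), "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.anchor_distances <- function(x, ...) {
  tibble(
    anchor_id = rep(x$anchor_ids, times = length(x$text_ids)),
    text_id = rep(x$text_ids, each = length(x$anchor_ids)),
    distance = as.vector(x$D)
  )
}

# "Most similar", "Second most similar", ... labels for exemplar tables.
position_label <- function(i, side) {
  ord <- c("", "Second ", "Third ", "Fourth ", "Fifth ", "Sixth ", "Seventh ",
           "Eighth ", "Ninth ", "Tenth ")
  prefix <- if (i <= length(ord)) ord[i] else paste0(i, "th ")
  label <- paste0(prefix, "most ", side)
  if (i == 1) paste0(toupper(substr(label, 1, 1)), substr(label, 2, nchar(label)))
  else label
}

#' Nearest and farthest exemplars for one anchor
#'
#' Reports, for a single anchor, the `k` corpus texts at the smallest cosine
#' distance ("Most similar", "Second most similar", ...) and the `k` at the
#' largest ("... most distant", "Most distant") — the table one inspects to
#' confirm that near texts repeat the anchor's claim while far texts do not.
#' Ties are broken by text id, so reports are reproducible. Distances are
#' additionally rendered at 6 decimal places (round half-up).
#'
#' @param distances an `anchor_distances` object.
#' @param anchor_id the anchor to report on.
#' @param k how many exemplars on each side.
#' @param labels optional text labels (named logical / corpus tibble with
#'   `id` + `label`) to display alongside.
#' @param texts optional corpus tibble (`id`, `text`) to attach the text body.
#' @return tibble `(anchor_id, text_id, position, rank, distance, rendered)`
#'   plus `label`/`text` when supplied; most-similar block first, distances
#'   non-decreasing within it.
#' @export
exemplar_report <- function(distances, anchor_id, k = 2, labels = NULL,
                            texts = NULL) {
  stopifnot(inherits(distances, "anchor_distances"))
  if (!anchor_id %in% distances$anchor_ids) {
    abort(paste0("unknown anchor_id: ", anchor_id))
  }
  d <- distances$D[match(anchor_id, distances$anchor_ids), ]
  n <- length(d)
  if (k > n) abort("k exceeds the number of texts")
  ord <- order(d, distances$text_ids, method = "radix")
  ord_far <- order(-d, distances$text_ids, method = "radix")
  near <- ord[seq_len(k)]
  far <- rev(ord_far[seq_len(k)])  # display farthest last, as in report tables

  out <- tibble(
    anchor_id = anchor_id,
    text_id = distances$text_ids[c(near, far)],
    position = c(vapply(seq_len(k), position_label, "", side = "similar"),
                 vapply(rev(seq_len(k)), position_label, "", side = "distant")),
    rank = c(seq_len(k), n - rev(seq_len(k)) + 1L),
    distance = unname(d[c(near, far)]),
    rendered = sprintf("%.6f", round_half_up(unname(d[c(near, far)]), 6))
  )
  if (!is.null(labels)) {
    lv <- as_label_vector(labels)
    out$label <- unname(lv[out$text_id])
  }
  if (!is.null(texts)) {
    out$text <- texts$text[match(out$text_id, texts$id)]
  }
  out
}
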