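#' Encoder configuration
#'
#' The screening pipeline is encoder-agnostic: any sentence encoder mapping a
#' character vector to a fixed-dimension numeric matrix can supply the
#' vectors between which cosine distances are measured. Two backends are
#' provided:
#'
#' * `"reference"` — a deterministic bag-of-words count encoder over an
#'   explicit sorted vocabulary, L2-normalized. It is a pure function of its
#'   inputs (bit-reproducible), collision-free, and yields closed-form cosine
#'   values, which makes every downstream stage exactly testable.
#' * `"external"` — an adapter around a production sentence-embedding model
#'   (the documented default in the motivating study is Sentence-T5 with
#'   768-dimension vectors). Supply `encode_fn`, a function
#'   `character -> numeric matrix` with one row per input text; model weights
#'   are never bundled.
#'
#' @param backend `"reference"` or `"external"`.
#' @param case_folding lower-case text before tokenization (reference backend).
#' @param encode_fn for the external backend, the adapter function.
#' @return an `encoder_config` object.
#' @export
encoder_config <- function(backend = c("reference", "external"),
                           case_folding = TRUE, encode_fn = NULL) {
  backend <- arg_match(backend)
  if (backend == "external" && !is.function(encode_fn)) {
    abort("external backend requires `encode_fn`, a function(character) -> matrix")
  }
  structure(
    list(backend = backend, case_folding = case_folding,
         token_pattern = "split on non-alphanumeric", encode_fn = encode_fn),
    class = "encoder_config"
  )
}

# Tokenization rule shared by the reference encoder, the n-gram counter and
# the synthetic generator: (optionally) lower-case, split on runs of
# non-alphanumeric characters, drop empties.
tokenize <- function(texts, case_folding = TRUE) {
  if (case_folding) texts <- tolower(texts)
  toks <- stringr::str_split(texts, "[^[:alnum:]]+")
  map(toks, function(t) t[nzchar(t)])
}

#' Fit the reference encoder's vocabulary
#'
#' The vocabulary is the lexicographically sorted set of tokens in the given
#' texts; its size is the embedding dimension. Fit it on the union of corpus
#' and anchor texts so both live in the same space.
#'
#' @param texts character vector of texts.
#' @param config an [encoder_config()] (controls case folding).
#' @return sorted character vector of tokens.
#' @examples
#' fit_vocabulary("cbd cures covid")
#' @export
fit_vocabulary <- function(texts, config = encoder_config()) {
  toks <- unlist(tokenize(texts, config$case_folding))
  if (length(toks) == 0) abort("cannot fit a vocabulary: no tokens in input texts")
  sort(unique(toks), method = "radix")
}

#' Encode texts as sentence vectors
#'
#' Reference backend: token-count vectors over the fitted vocabulary,
#' L2-normalized; identical texts give identical rows; out-of-vocabulary
#' tokens are dropped. A text whose tokens are all out-of-vocabulary encodes
#' to a zero row, which is kept (screening must not silently lose records)
#' and flagged; downstream it is assigned similarity 0 / distance 1 to
#' everything. External backend: rows are whatever the adapter returns,
#' checked against the contract (one finite row per text, fixed dimension).
#'
#' @param texts character vector.
#' @param ids row ids; defaults to `text_1 ... text_n`.
#' @param config an [encoder_config()].
#' @param vocabulary for the reference backend, the output of
#'   [fit_vocabulary()]; required.
#' @param normalize L2-normalize rows (default `TRUE`).
#' @return a `text_embeddings` object: list with `ids`, `vectors` (matrix,
#'   rows named by id), `d`, `normalized`, `zero_rows` (named logical).
#' @export
encode_texts <- function(texts, ids = NULL, config = encoder_config(),
                         vocabulary = NULL, normalize = TRUE) {
  if (is.null(ids)) ids <- paste0("text_", seq_along(texts))
  if (length(ids) != length(texts)) abort("`ids` and `texts` lengths differ")
  if (anyDuplicated(ids)) abort("embedding ids must be unique")

  if (config$backend == "reference") {
    if (is.null(vocabulary)) {
      abort("reference backend requires a fitted `vocabulary` (see fit_vocabulary())")
    }
    toks <- tokenize(texts, config$case_folding)
    mat <- matrix(0, nrow = length(texts), ncol = length(vocabulary),
                  dimnames = list(ids, vocabulary))
    for (i in seq_along(toks)) {
      tt <- table(factor(toks[[i]], levels = vocabulary))
      mat[i, ] <- as.numeric(tt)
    }
  } else {
    mat <- tryCatch(config$encode_fn(texts), error = function(e) {
      abort(paste0("external encoder adapter failed: ", conditionMessage(e)))
    })
    if (!is.matrix(mat) || !is.numeric(mat) || nrow(mat) != length(texts)) {
      abort("external encoder must return a numeric matrix with one row per text")
    }
    if (!all(is.finite(mat))) abort("external encoder returned non-finite entries")
    rownames(mat) <- ids
  }

  emb <- structure(
    list(ids = ids, vectors = mat, d = ncol(mat), normalized = FALSE,
         zero_rows = setNames(rowSums(mat != 0) == 0, ids), config = config),
    class = "text_embeddings"
  )
  if (normalize) emb <- l2_normalize(emb) else emb
}

#' L2-normalize embedding rows
#'
#' Scales each non-zero row to unit Euclidean norm, so that cosine similarity
#' reduces to a plain dot product. Zero rows are left unchanged and flagged
#' with a warning; they later receive distance 1 to every anchor.
#'
#' @param x a `text_embeddings` object or a bare numeric matrix.
#' @return same type as the input, rows unit-norm (zero rows excepted).
#' @examples
#' l2_normalize(matrix(c(3, 4), nrow = 1))  # the 3-4-5 triangle -> (0.6, 0.8)
#' @export
l2_normalize <- function(x) {
  if (inherits(x, "text_embeddings")) {
    x$vectors <- l2_normalize(x$vectors)
    x$normalized <- TRUE
    if (any(x$zero_rows)) {
      warn(paste0(sum(x$zero_rows), " text(s) encoded to a zero vector ",
                  "(all tokens out of vocabulary); they will be assigned ",
                  "distance 1 to every anchor"))
    }
    return(x)
  }
  nrm <- sqrt(rowSums(x^2))
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x
}

#' @export
print.text_embeddings <- function(x, ...) {
  cat("<text_embeddings> ", length(x$ids), " texts x ", x$d, " dims (",
      x$config$backend, " backend", if (x$normalized) ", L2-normalized", ")\n",
      sep = "")
  if (any(x$zero_rows)) cat("  zero rows:", sum(x$zero_rows), "\n")
  invisible(x)
}
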