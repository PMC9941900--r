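# Small in-code fixtures shared across test files.

write_jsonl_fixture <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

toy_corpus_lines <- function() {
  c(
    '{"id": "a", "text": "cbd boosts immune system", "created_at": "2020-01-15T10:00:00Z", "votes": ["yes", "yes", "no"]}',
    '{"id": "b", "text": "cbd immune boost", "created_at": "2020-03-02", "votes": ["yes", "yes", "yes"]}',
    '{"id": "c", "text": "CBD is a natural way to do that... <MASKED-URL>", "created_at": "2020-03-20T23:59:59Z", "votes": ["no", "no", "no"]}'
  )
}

# Deterministic random embeddings for oracle comparisons: strictly positive
# entries so distances stay in [0, 1] like the reference encoder's.
random_embeddings <- function(n, d, prefix = "x") {
  mat <- matrix(runif(n * d, min = 0.05, max = 1), nrow = n)
  ids <- paste0(prefix, seq_len(n))
  rownames(mat) <- ids
  structure(
    list(ids = ids, vectors = mat / sqrt(rowSums(mat^2)), d = d,
         normalized = TRUE, zero_rows = stats::setNames(rep(FALSE, n), ids),
         config = encoder_config()),
    class = "text_embeddings"
  )
}

# Brute-force oracle: per-pair cosine distance loop, no shared code with
# distance_matrix().
naive_distance_matrix <- function(A, B) {
  D <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      D[i, j] <- 1 - sum(A[i, ] * B[j, ]) /
        (sqrt(sum(A[i, ]^2)) * sqrt(sum(B[j, ]^2)))
    }
  }
  D
}

# Brute-force oracle for capture metrics from raw lists.
naive_capture <- function(d, lab, t) {
  cap <- which(d <= t)
  n_cap <- length(cap)
  tp <- sum(lab[cap])
  list(n_captured = n_cap, tp = tp,
       precision = if (n_cap == 0) NA_real_ else tp / n_cap,
       recall = tp / sum(lab))
}
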