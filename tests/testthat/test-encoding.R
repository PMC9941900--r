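test_that("vocabulary fitting lower-cases, splits on non-alphanumerics, sorts", {
  expect_equal(fit_vocabulary("cbd cures covid"), c("cbd", "covid", "cures"))
  expect_equal(fit_vocabulary("A a A"), "a")
  expect_equal(fit_vocabulary("boost! your #immune-system"),
               c("boost", "immune", "system", "your"))
  expect_error(fit_vocabulary(c("", "   ")), "no tokens")
})

test_that("reference encoding is deterministic and respects token geometry", {
  texts <- c("cbd boosts immune system", "cbd immune boost",
             "cbd boosts immune system", "totally unrelated words")
  vocab <- fit_vocabulary(texts)
  emb <- encode_texts(texts, config = encoder_config(), vocabulary = vocab)

  # identical texts -> identical rows, distance 0
  expect_identical(emb$vectors[1, ], emb$vectors[3, ])
  expect_equal(cosine_distance(emb$vectors[1, ], emb$vectors[3, ]), 0)

  # disjoint vocabularies -> orthogonal rows, similarity exactly 0
  expect_identical(cosine_similarity(emb$vectors[1, ], emb$vectors[4, ]), 0)

  # hand-computed overlap: |{cbd, immune}| / (sqrt(4) * sqrt(3))
  expect_equal(cosine_similarity(emb$vectors[1, ], emb$vectors[2, ]),
               2 / (sqrt(4) * sqrt(3)), tolerance = 1e-12)

  # bit-reproducibility across calls
  again <- encode_texts(texts, config = encoder_config(), vocabulary = vocab)
  expect_identical(emb$vectors, again$vectors)
})

test_that("cosine similarity is invariant to token order within a text", {
  withr::with_seed(21, {
    words <- c("cbd", "immune", "boost", "virus", "oil", "covid", "cure")
    for (i in 1:10) {
      t1 <- paste(sample(words, 5, replace = TRUE), collapse = " ")
      t2 <- paste(sample(strsplit(t1, " ")[[1]]), collapse = " ")
      probe <- "cbd covid immune"
      vocab <- fit_vocabulary(c(t1, probe))
      e <- encode_texts(c(t1, t2, probe), vocabulary = vocab)
      expect_equal(cosine_similarity(e$vectors[1, ], e$vectors[3, ]),
                   cosine_similarity(e$vectors[2, ], e$vectors[3, ]))
    }
  })
})

test_that("l2_normalize scales non-zero rows to unit norm and flags zero rows", {
  expect_equal(l2_normalize(matrix(c(3, 4), nrow = 1))[1, ], c(0.6, 0.8))
  unit <- matrix(c(0.6, 0.8), nrow = 1)
  expect_equal(l2_normalize(unit), unit)
  withzero <- matrix(c(1, 1, 0, 0), nrow = 2, byrow = TRUE)
  expect_equal(l2_normalize(withzero)[2, ], c(0, 0))

  vocab <- fit_vocabulary("known words only")
  expect_warning(
    emb <- encode_texts(c("known words", "completely absent"), vocabulary = vocab),
    "zero vector")
  expect_equal(unname(emb$zero_rows), c(FALSE, TRUE))
  expect_equal(sqrt(sum(emb$vectors[1, ]^2)), 1, tolerance = 1e-9)
})

test_that("out-of-vocabulary tokens are dropped from the encoding", {
  vocab <- fit_vocabulary("cbd immune")
  emb <- suppressWarnings(
    encode_texts("cbd helps immune defence", vocabulary = vocab))
  expect_equal(ncol(emb$vectors), 2)
  expect_equal(unname(emb$vectors[1, ]), c(1, 1) / sqrt(2))
})

test_that("an external adapter must honour the output contract", {
  mock <- function(texts) {
    m <- matrix(seq_len(length(texts) * 4) / 10, nrow = length(texts))
    m
  }
  emb <- encode_texts(c("a b", "c d"), config = encoder_config("external", encode_fn = mock))
  expect_equal(emb$d, 4)
  expect_equal(emb$ids, c("text_1", "text_2"))
  expect_true(all(abs(sqrt(rowSums(emb$vectors^2)) - 1) < 1e-9))

  bad_shape <- function(texts) matrix(1, nrow = 1, ncol = 3)
  expect_error(encode_texts(c("a", "b"),
                            config = encoder_config("external", encode_fn = bad_shape)),
               "one row per text")
  non_finite <- function(texts) matrix(c(1, NaN), nrow = length(texts), ncol = 1)
  expect_error(encode_texts(c("a", "b"),
                            config = encoder_config("external", encode_fn = non_finite)),
               "non-finite")
  unreachable <- function(texts) stop("model server down")
  expect_error(encode_texts("a",
                            config = encoder_config("external", encode_fn = unreachable)),
               "adapter failed.*model server down")
  expect_error(encoder_config("external"), "encode_fn")
})
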