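test_that("config validation enforces parameter ranges", {
  expect_error(synthetic_config(theta = 1.2), "theta")
  expect_error(synthetic_config(annotator_error = 0.5), "annotator_error")
  expect_error(synthetic_config(n_pos = -1), "non-negative")
  expect_error(synthetic_config(n_annotators = 4), "odd")
  expect_error(synthetic_config(n_pos = 10, n_anchors = 0), "anchor")
})

test_that("identical config and seed give byte-identical corpora", {
  cfg <- synthetic_config(n_pos = 20, n_neg = 60, seed = 9)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$anchors, g2$anchors)

  g3 <- generate_corpus(synthetic_config(n_pos = 20, n_neg = 60, seed = 10))
  expect_false(identical(g1$records$text, g3$records$text))
})

test_that("prevalence is exact and votes behave as configured", {
  cfg <- synthetic_config(n_pos = 19, n_neg = 81, annotator_error = 0, seed = 3)
  gen <- generate_corpus(cfg)
  expect_equal(mean(gen$records$truth), 0.19)
  expect_equal(nrow(gen$records), 100)
  # noiseless annotators are unanimous and agree with the ground truth
  expect_equal(intercoder_agreement(gen$records), 1.0)
  expect_identical(gen$records$label, gen$records$truth)
  expect_true(all(lengths(gen$records$votes) == 3))
  # timestamps inside the configured window
  expect_true(all(gen$records$created_at >=
                    lubridate::as_datetime("2020-01-01", tz = "UTC")))
  expect_true(all(gen$records$created_at <=
                    lubridate::as_datetime("2021-04-28", tz = "UTC")))
})

test_that("full anchor overlap reproduces the anchor token multiset", {
  cfg <- synthetic_config(n_pos = 8, n_neg = 0, n_anchors = 4, theta = 1,
                          fixed_text_length = 12, anchor_length = 12, seed = 5)
  gen <- generate_corpus(cfg)
  D <- anchorscreen:::corpus_distances(gen$records, gen$anchors)
  for (i in seq_len(nrow(gen$records))) {
    own <- gen$records$anchor_id[i]
    expect_equal(D$D[own, gen$records$id[i]], 0, tolerance = 1e-12)
  }
})

test_that("positives sit closer to anchors as theta rises; theta 0 erases the gap", {
  gaps <- vapply(c(0.2, 0.5, 0.8), function(th) {
    mean(vapply(1:3, function(s) {
      distance_separation(synthetic_config(n_pos = 40, n_neg = 160, theta = th,
                                           seed = 100 + s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))

  zero_gaps <- vapply(1:10, function(s) {
    distance_separation(synthetic_config(n_pos = 40, n_neg = 160, theta = 0,
                                         seed = 200 + s))
  }, numeric(1))
  expect_lt(max(abs(zero_gaps)), 0.02)
})

test_that("synthetic output round-trips through the standard file formats", {
  gen <- generate_corpus(synthetic_config(n_pos = 5, n_neg = 15, seed = 2))
  corpus_path <- tempfile(fileext = ".jsonl")
  anchor_path <- tempfile(fileext = ".json")
  write_corpus(gen$records, corpus_path)
  write_anchors(gen$anchors, anchor_path)
  back <- read_corpus(corpus_path)
  expect_equal(back$id, gen$records$id)
  expect_equal(back$text, gen$records$text)
  expect_equal(back$label, gen$records$label)
  expect_equal(read_anchors(anchor_path)$text, gen$anchors$text)
})

test_that("recovery summaries report feasibility and held-out metrics", {
  cfg <- synthetic_config(n_pos = 30, n_neg = 120, theta = 0.9,
                          annotator_error = 0, seed = 4)
  rec <- recovery_experiment(cfg, precision_floor = 0.8,
                             grid = seq(0, 1, by = 0.01),
                             n_train_seeds = 3, n_test_seeds = 1)
  expect_equal(nrow(rec), 3)
  g <- glance(rec)
  expect_equal(g$n_seeds, 3)
  expect_true(g$mean_heldout_recall > 0)

  # a floor of 0 keeps the whole corpus: held-out recall 1
  rec0 <- recovery_experiment(cfg, precision_floor = 0,
                              grid = seq(0, 1, by = 0.01),
                              n_train_seeds = 2, n_test_seeds = 1)
  expect_true(all(rec0$heldout_recall == 1))

  # test-free runs carry training metrics only
  rec_nt <- recovery_experiment(cfg, precision_floor = 0.8,
                                grid = seq(0, 1, by = 0.01),
                                n_train_seeds = 2, n_test_seeds = 0)
  expect_true(all(is.na(rec_nt$heldout_precision)))
  expect_true(all(!is.na(rec_nt$train_precision)))
})
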