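toy_distances <- function() {
  ids <- paste0("t", 1:5)
  structure(list(anchor_ids = c("A", "B"), text_ids = ids,
                 D = matrix(c(0.1, 0.2, 0.3, 0.4, 0.5,
                              0.5, 0.4, 0.3, 0.2, 0.1),
                            nrow = 2, byrow = TRUE,
                            dimnames = list(c("A", "B"), ids))),
            class = "anchor_distances")
}
toy_labels <- function() {
  stats::setNames(c(TRUE, TRUE, FALSE, TRUE, FALSE), paste0("t", 1:5))
}

test_that("capture_summary reproduces the worked-example percentages", {
  s <- capture_summary(n_captured = 323, tp = 274, n_pos = 938, n_total = 4937)
  expect_equal(s$prevalence_pct, 19.0)
  expect_equal(s$capture_rate_pct, 34.4)
  expect_equal(s$precision_pct, 84.8)
  expect_equal(s$recall_pct, 29.2)
  expect_error(capture_summary(10, 11, 20), "exceed")
})

test_that("capture at a threshold is inclusive and hand-countable", {
  cap <- capture_at_threshold(toy_distances(), toy_labels(), 0.3,
                              anchor_scope = "A")
  expect_equal(cap$n_captured, 3)
  expect_equal(cap$tp, 2)
  expect_equal(cap$precision, 2 / 3)
  expect_equal(cap$recall, 2 / 3)
  expect_setequal(cap$captured_ids[[1]], c("t1", "t2", "t3"))

  below_min <- capture_at_threshold(toy_distances(), toy_labels(), 0.05, "A")
  expect_equal(below_min$n_captured, 0)
  expect_true(is.na(below_min$precision))
  expect_equal(below_min$recall, 0)
})

test_that("sweeps match hand counts and are monotone", {
  curves <- sweep_thresholds(toy_distances(), toy_labels(),
                             grid = c(0.1, 0.3, 0.5))
  a <- curves[curves$anchor_id == "A", ]
  expect_equal(a$n_captured, c(1L, 3L, 5L))
  expect_equal(a$tp, c(1L, 2L, 3L))
  expect_equal(a$recall, c(1, 2, 3) / 3)
  # endpoint >= max distance captures everything
  expect_equal(a$recall[3], 1)
  expect_equal(a$n_captured[3], 5L)
  for (scope in c("A", "B")) {
    cv <- curves[curves$anchor_id == scope, ]
    expect_true(all(diff(cv$n_captured) >= 0))
    expect_true(all(diff(cv$recall) >= 0))
  }
  expect_error(sweep_thresholds(toy_distances(), toy_labels(), numeric(0)),
               "non-empty")
  expect_error(sweep_thresholds(toy_distances(), toy_labels(), c(0.2, 0.2)),
               "strictly increasing")
})

test_that("optimal_threshold picks the largest feasible grid point", {
  curves <- sweep_thresholds(toy_distances(), toy_labels(),
                             grid = c(0.1, 0.3, 0.5))
  # precisions along anchor A: 1.0, 0.667, 0.6
  expect_equal(optimal_threshold(curves, 0.8, anchor_id = "A"), 0.1)
  # floor 0: the last grid threshold with a non-empty capture
  expect_equal(optimal_threshold(curves, 0, anchor_id = "A"), 0.5)
  # an unreachable floor yields NA
  expect_true(is.na(optimal_threshold(curves, 1.0, anchor_id = "B")))
  expect_error(optimal_threshold(curves, 1.5), "\\[0, 1\\]")
})

test_that("rank_anchors orders by recall, then precision, then id", {
  curves <- sweep_thresholds(toy_distances(), toy_labels(),
                             grid = c(0.1, 0.3, 0.5))
  ranked <- rank_anchors(curves, precision_floor = 0.8)
  # A reaches precision 1 at t = 0.1 (recall 1/3); B never clears the floor
  expect_equal(ranked$anchor_id, "A")
  expect_equal(ranked$recall, 1 / 3)
  expect_equal(nrow(rank_anchors(curves, 0.8, k = 0)), 0)

  # identical curves tie-break by anchor id
  ids <- paste0("t", 1:5)
  same <- structure(list(anchor_ids = c("zz", "aa"), text_ids = ids,
                         D = matrix(rep(c(0.1, 0.2, 0.3, 0.4, 0.5), each = 2),
                                    nrow = 2,
                                    dimnames = list(c("zz", "aa"), ids))),
                    class = "anchor_distances")
  r2 <- rank_anchors(sweep_thresholds(same, toy_labels(), c(0.1, 0.3, 0.5)), 0.8)
  expect_equal(r2$anchor_id, c("aa", "zz"))

  # infeasible everywhere -> empty with warning (nearest text is a negative,
  # so no grid point ever reaches precision 1)
  hard_labels <- stats::setNames(c(FALSE, TRUE, TRUE, TRUE, FALSE), ids)
  expect_warning(
    empty <- rank_anchors(sweep_thresholds(same, hard_labels, c(0.1, 0.3, 0.5)),
                          precision_floor = 1, k = 5),
    "no anchor")
  expect_equal(nrow(empty), 0)
})

test_that("pooled capture is the union of per-anchor captures", {
  D <- toy_distances()
  lab <- toy_labels()
  # at t = 0.1, anchor A captures t1 and anchor B captures t5
  pooled <- pooled_capture(D, c("A", "B"), lab, 0.1)
  expect_setequal(pooled$captured_ids[[1]], c("t1", "t5"))
  # singleton subset reduces to capture_at_threshold
  single <- pooled_capture(D, "A", lab, 0.3)
  direct <- capture_at_threshold(D, lab, 0.3, "A")
  expect_equal(single$n_captured, direct$n_captured)
  expect_equal(single$tp, direct$tp)
  # full subset at a threshold past every per-text minimum captures all
  expect_equal(pooled_capture(D, c("A", "B"), lab, 0.5)$n_captured, 5)
  expect_error(pooled_capture(D, character(0), lab, 0.1), "non-empty")
  expect_error(pooled_capture(D, "missing", lab, 0.1), "unknown anchor")
})

test_that("capture metrics agree with brute-force recounts on random toys", {
  withr::with_seed(41, {
    for (rep in 1:30) {
      n_t <- sample(5:50, 1); n_a <- sample(1:5, 1)
      ids <- paste0("t", seq_len(n_t))
      D <- structure(list(anchor_ids = paste0("a", seq_len(n_a)), text_ids = ids,
                          D = matrix(runif(n_a * n_t), nrow = n_a,
                                     dimnames = list(paste0("a", seq_len(n_a)), ids))),
                     class = "anchor_distances")
      lab <- stats::setNames(runif(n_t) < 0.4, ids)
      if (!any(lab)) lab[1] <- TRUE
      t <- runif(1)
      a <- sample(D$anchor_ids, 1)
      got <- capture_at_threshold(D, lab, t, a)
      want <- naive_capture(D$D[a, ], unname(lab), t)
      expect_equal(got$n_captured, want$n_captured)
      expect_equal(got$tp, want$tp)
      expect_equal(got$precision, want$precision, tolerance = 1e-12)
      expect_equal(got$recall, want$recall, tolerance = 1e-12)
    }
  })
})

test_that("captured sets nest as the threshold grows; counts conserve", {
  withr::with_seed(42, {
    ids <- paste0("t", 1:30)
    D <- structure(list(anchor_ids = "a1", text_ids = ids,
                        D = matrix(runif(30), nrow = 1,
                                   dimnames = list("a1", ids))),
                   class = "anchor_distances")
    lab <- stats::setNames(runif(30) < 0.3, ids)
    lab[1] <- TRUE
    ts <- sort(runif(5))
    caps <- lapply(ts, function(t) capture_at_threshold(D, lab, t, "a1"))
    for (i in 2:5) {
      expect_true(all(caps[[i - 1]]$captured_ids[[1]] %in%
                        caps[[i]]$captured_ids[[1]]))
      expect_true(caps[[i]]$recall >= caps[[i - 1]]$recall)
    }
    for (cap in caps) {
      expect_equal(cap$n_captured + (30 - cap$n_captured), 30)
    }
  })
})
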