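#' Configuration for the synthetic labeled-corpus generator
#'
#' Describes a corpus with a minority positive class planted near an anchor
#' set: positives draw each token from their assigned anchor's token
#' multiset with probability `theta` and otherwise from a shared background
#' vocabulary; negatives draw purely from the background. Three simulated
#' annotators then vote on each record, each flipping the ground truth
#' independently with probability `annotator_error`. The defaults mirror
#' the study design this package emulates: 27 anchors, 3 annotators, and a
#' positive prevalence of 0.19.
#'
#' @param n_pos,n_neg counts of planted misinformation and background texts.
#' @param n_anchors how many anchors to auto-generate when `anchor_texts`
#'   is not supplied.
#' @param anchor_texts optional character vector of anchor texts to use
#'   verbatim instead of auto-generated ones.
#' @param theta per-token probability, in `[0, 1]`, that a positive text
#'   copies from its anchor rather than the background.
#' @param background_vocab_size number of background token types.
#' @param anchor_vocab_size distinctive token types per auto-generated anchor.
#' @param anchor_length tokens per auto-generated anchor.
#' @param anchor_bg_mix fraction of an auto-generated anchor's tokens drawn
#'   from the background vocabulary. The default 0 plants clean separation:
#'   background texts share no vocabulary with the anchors' claim tokens,
#'   so a calibrated threshold has a real margin and transfers across
#'   corpora. Raising it blurs anchors into the background chatter and
#'   makes calibration progressively harder to transfer — useful for
#'   studying the failure mode, not for testing recovery.
#' @param text_length_mean Poisson mean of the per-text token count.
#' @param min_text_length lower truncation of the token count.
#' @param fixed_text_length if set, every text has exactly this many tokens
#'   (overrides the Poisson draw).
#' @param annotator_error per-annotator label-flip probability, in
#'   `[0, 0.5)`.
#' @param n_annotators number of simulated annotators (odd).
#' @param date_range two dates bounding the uniform timestamp draw.
#' @param seed integer RNG seed; identical config + seed gives a
#'   byte-identical corpus.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_pos = 190, n_neg = 810, n_anchors = 27,
                             anchor_texts = NULL, theta = 0.9,
                             background_vocab_size = 500,
                             anchor_vocab_size = 15, anchor_length = 12,
                             anchor_bg_mix = 0, text_length_mean = 12,
                             min_text_length = 3, fixed_text_length = NULL,
                             annotator_error = 0.02, n_annotators = 3,
                             date_range = c("2020-01-01", "2021-04-28"),
                             seed = 1L) {
  if (theta < 0 || theta > 1) abort("theta must be in [0, 1]")
  if (annotator_error < 0 || annotator_error >= 0.5) {
    abort("annotator_error must be in [0, 0.5)")
  }
  if (n_pos < 0 || n_neg < 0) abort("n_pos and n_neg must be non-negative")
  if (n_annotators %% 2 == 0) abort("n_annotators must be odd")
  if (n_pos > 0 && is.null(anchor_texts) && n_anchors < 1) {
    abort("positives require a non-empty anchor set")
  }
  structure(
    list(n_pos = n_pos, n_neg = n_neg, n_anchors = n_anchors,
         anchor_texts = anchor_texts, theta = theta,
         background_vocab_size = background_vocab_size,
         anchor_vocab_size = anchor_vocab_size, anchor_length = anchor_length,
         anchor_bg_mix = anchor_bg_mix, text_length_mean = text_length_mean,
         min_text_length = min_text_length,
         fixed_text_length = fixed_text_length,
         annotator_error = annotator_error, n_annotators = n_annotators,
         date_range = as.character(date_range), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Run fn under a fixed, fully specified RNG state, restoring the caller's.
with_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  fn()
}

# m tokens from an anchor's token multiset: a without-replacement draw when
# m fits inside the multiset (so theta = 1 with matching length reproduces
# the multiset exactly), recycling the multiset when m exceeds it.
draw_from_multiset <- function(tokens, m) {
  if (m == 0) return(character(0))
  pool <- rep(tokens, ceiling(m / length(tokens)))
  sample(pool, m)
}

#' Generate a synthetic labeled corpus, annotations and anchor set
#'
#' Deterministically expands a [synthetic_config()] into (a) corpus records
#' with ground-truth labels, simulated annotator votes and uniform
#' timestamps, (b) the anchor set, written in the same shapes as
#' [read_corpus()] / [read_anchors()] produce, so synthetic data is
#' indistinguishable from file input to every downstream stage.
#'
#' Positives are assigned to anchors round-robin; record order is a random
#' interleaving of positives and negatives. The generated positive fraction
#' equals `n_pos / (n_pos + n_neg)` exactly.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (corpus tibble plus `truth` and `anchor_id`
#'   columns), `anchors` (anchor tibble), and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng(config$seed, function() {
    bg_vocab <- sprintf("bg%03d", seq_len(config$background_vocab_size))

    if (!is.null(config$anchor_texts)) {
      anchor_texts <- config$anchor_texts
    } else {
      anchor_texts <- vapply(seq_len(config$n_anchors), function(k) {
        vocab_k <- sprintf("a%02dw%02d", k, seq_len(config$anchor_vocab_size))
        from_bg <- runif(config$anchor_length) < config$anchor_bg_mix
        toks <- ifelse(from_bg,
                       sample(bg_vocab, config$anchor_length, replace = TRUE),
                       sample(vocab_k, config$anchor_length, replace = TRUE))
        paste(toks, collapse = " ")
      }, character(1))
    }
    n_anchors <- length(anchor_texts)
    anchors <- tibble(
      anchor_id = sprintf("anchor_%02d", seq_len(n_anchors)),
      source = "synthetic",
      text = anchor_texts
    )
    anchor_tokens <- tokenize(anchor_texts)

    n <- config$n_pos + config$n_neg
    truth <- c(rep(TRUE, config$n_pos), rep(FALSE, config$n_neg))
    assigned <- c(if (config$n_pos > 0)
                    rep_len(seq_len(n_anchors), config$n_pos)
                  else integer(0),
                  rep(NA_integer_, config$n_neg))

    lengths <- if (!is.null(config$fixed_text_length)) {
      rep(config$fixed_text_length, n)
    } else {
      pmax(config$min_text_length, rpois(n, config$text_length_mean))
    }

    texts <- vapply(seq_len(n), function(i) {
      L <- lengths[i]
      if (truth[i]) {
        from_anchor <- runif(L) < config$theta
        toks <- character(L)
        toks[from_anchor] <- draw_from_multiset(anchor_tokens[[assigned[i]]],
                                                sum(from_anchor))
        toks[!from_anchor] <- sample(bg_vocab, sum(!from_anchor), replace = TRUE)
      } else {
        toks <- sample(bg_vocab, L, replace = TRUE)
      }
      paste(toks, collapse = " ")
    }, character(1))

    ord <- sample.int(n)
    truth <- truth[ord]; texts <- texts[ord]; assigned <- assigned[ord]

    t0 <- lubridate::as_datetime(config$date_range[1], tz = "UTC")
    t1 <- lubridate::as_datetime(config$date_range[2], tz = "UTC")
    ts <- t0 + lubridate::dseconds(floor(runif(n) * as.numeric(t1 - t0, "secs")))

    votes <- map(truth, function(tr) {
      flips <- runif(config$n_annotators) < config$annotator_error
      xor(rep(tr, config$n_annotators), flips)
    })

    records <- tibble(
      id = sprintf("t%05d", seq_len(n)),
      text = texts,
      created_at = ts,
      votes = votes,
      label = map_lgl(votes, majority_label),
      truth = truth,
      anchor_id = ifelse(is.na(assigned), NA_character_,
                         sprintf("anchor_%02d", assigned))
    )
    list(records = records, anchors = anchors, config = config)
  })
}

# Encode a corpus and anchor set with the reference encoder (shared
# vocabulary) and return the anchor-by-text distance matrix.
corpus_distances <- function(records, anchors, config = encoder_config()) {
  vocab <- fit_vocabulary(c(records$text, anchors$text), config)
  emb_t <- suppressWarnings(
    encode_texts(records$text, records$id, config, vocab))
  emb_a <- suppressWarnings(
    encode_texts(anchors$text, anchors$anchor_id, config, vocab))
  distance_matrix(emb_a, emb_t)
}

#' Threshold-recovery experiment on synthetic corpora
#'
#' The end-to-end check that calibrated thresholds generalize: for each
#' train seed, generate a corpus, calibrate the pooled (minimum-distance
#' over all anchors) threshold under the precision floor, then evaluate
#' that threshold on freshly generated corpora from the same configuration.
#' The anchor set is generated once and held fixed across all corpora, as a
#' real screening deployment would hold its quote set fixed.
#'
#' @param config a [synthetic_config()]; its `seed` seeds the whole
#'   experiment.
#' @param precision_floor see [optimal_threshold()].
#' @param grid threshold grid.
#' @param n_train_seeds number of independent calibration corpora.
#' @param n_test_seeds held-out corpora evaluated per calibration (0 for
#'   training metrics only).
#' @return a `recovery_experiment` tibble, one row per train seed:
#'   `train_seed`, `threshold` (`NA` when calibration is infeasible at the
#'   floor), `train_precision`, `train_recall`, `heldout_precision`,
#'   `heldout_recall` (means over the test corpora). `glance()` summarises:
#'   mean held-out metrics and the fraction of feasible calibrations whose
#'   held-out precision meets the floor.
#' @export
recovery_experiment <- function(config, precision_floor = 0.8,
                                grid = default_grid(), n_train_seeds = 20,
                                n_test_seeds = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  anchors <- generate_corpus(config)$anchors

  rows <- map(seq_len(n_train_seeds), function(i) {
    cfg_i <- config
    cfg_i$anchor_texts <- anchors$text
    cfg_i$seed <- config$seed + 1000L * i
    train <- generate_corpus(cfg_i)
    D <- corpus_distances(train$records, train$anchors)
    labels <- setNames(train$records$truth, train$records$id)
    curves <- sweep_thresholds(D, labels, grid, pooled = TRUE)
    pooled_curve <- curves[curves$anchor_id == "pooled", ]
    t_opt <- optimal_threshold(pooled_curve, precision_floor)

    row <- tibble(train_seed = cfg_i$seed, threshold = t_opt,
                  train_precision = NA_real_, train_recall = NA_real_,
                  heldout_precision = NA_real_, heldout_recall = NA_real_)
    if (is.na(t_opt)) return(row)

    at <- pooled_curve[pooled_curve$threshold == t_opt, ]
    row$train_precision <- at$precision
    row$train_recall <- at$recall

    if (n_test_seeds > 0) {
      held <- map(seq_len(n_test_seeds), function(j) {
        cfg_j <- cfg_i
        cfg_j$seed <- cfg_i$seed + j
        test <- generate_corpus(cfg_j)
        Dt <- corpus_distances(test$records, test$anchors)
        lab_t <- setNames(test$records$truth, test$records$id)
        capture_at_threshold(Dt, lab_t, t_opt)
      })
      held <- bind_rows(held)
      row$heldout_precision <- mean(held$precision)
      row$heldout_recall <- mean(held$recall)
    }
    row
  })
  out <- bind_rows(rows)
  class(out) <- c("recovery_experiment", class(out))
  attr(out, "precision_floor") <- precision_floor
  out
}

#' @exportS3Method generics::glance
glance.recovery_experiment <- function(x, ...) {
  floor_ <- attr(x, "precision_floor")
  feasible <- !is.na(x$threshold)
  tibble(
    n_seeds = nrow(x),
    n_feasible = sum(feasible),
    mean_threshold = mean(x$threshold[feasible]),
    mean_heldout_precision = mean(x$heldout_precision[feasible]),
    mean_heldout_recall = mean(x$heldout_recall[feasible]),
    success_rate = mean(feasible & !is.na(x$heldout_precision) &
                          x$heldout_precision >= floor_)
  )
}

#' Positive/negative anchor-distance separation of a synthetic corpus
#'
#' Mean of the per-text minimum anchor distance among negatives minus the
#' same mean among positives. Positive when planted positives sit closer to
#' the anchor set than background texts; near zero when `theta = 0` (both
#' classes then draw from the same distribution).
#'
#' @param config a [synthetic_config()].
#' @return single numeric gap.
#' @export
distance_separation <- function(config) {
  gen <- generate_corpus(config)
  D <- corpus_distances(gen$records, gen$anchors)
  dmin <- scope_distances(D)
  mean(dmin[gen$records$id[!gen$records$truth]]) -
    mean(dmin[gen$records$id[gen$records$truth]])
}
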