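#' Run configuration for the end-to-end screening pipeline
#'
#' Bundles everything one scan needs: input locations (or in-memory
#' tibbles), encoder choice, threshold grid, precision floor, and report
#' sizes. The configuration is serialized verbatim into the output
#' directory so a run is reproducible from its artifacts alone.
#'
#' @param corpus corpus file path, or a corpus tibble.
#' @param anchors anchor file path, or an anchor tibble; `NULL` uses the
#'   packaged FDA Warning Letter quotes ([default_anchors()]).
#' @param output_dir directory for run artifacts (created if absent).
#' @param encoder an [encoder_config()].
#' @param grid threshold grid for sweeps.
#' @param precision_floor operating precision floor.
#' @param top_k how many top-ranked anchors to report.
#' @param exemplar_k exemplars per side in each anchor's report.
#' @param stopwords stopword list for the n-gram table.
#' @param ngram_top_k rows in the n-gram table.
#' @param calibrate run labeled calibration (sweeps, optimal thresholds,
#'   anchor ranking); requires labels. `FALSE` = scan-only mode: distances
#'   and exemplar reports only.
#' @param dedup_text drop exact duplicate texts on load.
#' @param prefilter optional predicate passed to [apply_prefilter()].
#' @param seed integer seed recorded with the run.
#' @return a `run_config` list.
#' @export
run_config <- function(corpus, anchors = NULL, output_dir = tempfile("scan_"),
                       encoder = encoder_config(), grid = default_grid(),
                       precision_floor = 0.8, top_k = 5, exemplar_k = 2,
                       stopwords = default_stopwords(), ngram_top_k = 20,
                       calibrate = TRUE, dedup_text = FALSE,
                       prefilter = NULL, seed = 1L) {
  if (is.character(corpus) && !file.exists(corpus)) {
    abort(paste0("corpus path does not exist: ", corpus))
  }
  if (is.character(anchors) && !file.exists(anchors)) {
    abort(paste0("anchor path does not exist: ", anchors))
  }
  structure(
    list(corpus = corpus, anchors = anchors, output_dir = output_dir,
         encoder = encoder, grid = grid, precision_floor = precision_floor,
         top_k = top_k, exemplar_k = exemplar_k, stopwords = stopwords,
         ngram_top_k = ngram_top_k, calibrate = calibrate,
         dedup_text = dedup_text, prefilter = prefilter,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# Serializable view of a run_config (drops functions, keeps their fingerprints).
config_fingerprint <- function(config) {
  list(
    corpus = if (is.character(config$corpus)) config$corpus else "<in-memory>",
    anchors = if (is.null(config$anchors)) "<packaged default>"
              else if (is.character(config$anchors)) config$anchors
              else "<in-memory>",
    encoder_backend = config$encoder$backend,
    encoder_case_folding = config$encoder$case_folding,
    grid = list(min = min(config$grid), max = max(config$grid),
                n = length(config$grid)),
    precision_floor = config$precision_floor,
    top_k = config$top_k, exemplar_k = config$exemplar_k,
    ngram_top_k = config$ngram_top_k, calibrate = config$calibrate,
    dedup_text = config$dedup_text,
    prefilter = !is.null(config$prefilter),
    seed = config$seed
  )
}

#' Run the full anchor-screening pipeline
#'
#' Composes the whole flow — load, optional prefilter, encode, distance
#' matrix, per-anchor exemplar reports, and (when labels are present and
#' calibration is requested) threshold sweeps, optimal thresholds and
#' anchor ranking — plus the corpus content summaries (n-gram table,
#' monthly volume), writing every artifact to the run directory:
#'
#' * `distances.csv` — long-form anchor x text cosine distances
#' * `exemplars.csv` — nearest/farthest texts per anchor
#' * `sweep.csv` — per-anchor (plus pooled) threshold sweep
#' * `calibration.json` — per-anchor optimal thresholds and the ranked table
#' * `ngrams.csv` — top n-grams
#' * `monthly.csv` — monthly tweet volume (when timestamps exist)
#' * `run_config.json`, `run.log`
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`records`,
#'   `anchors`, `distances`, `exemplars`, `sweep`, `ranked`, `ngrams`,
#'   `monthly`, `paths`).
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  records <- if (is.character(config$corpus)) {
    read_corpus(config$corpus, dedup_text = config$dedup_text)
  } else if (config$dedup_text) {
    config$corpus[!duplicated(config$corpus$text), ]
  } else config$corpus
  anchors <- if (is.null(config$anchors)) default_anchors()
             else if (is.character(config$anchors)) read_anchors(config$anchors)
             else config$anchors
  say("loaded ", nrow(records), " records, ", nrow(anchors), " anchors")

  if (!is.null(config$prefilter)) {
    records <- apply_prefilter(records, config$prefilter)
    say("prefilter kept ", nrow(records), " records")
  }
  if (nrow(records) == 0) abort("no records to scan after loading/prefiltering")

  has_labels <- "label" %in% names(records) && !anyNA(records$label)
  if (config$calibrate && !has_labels) {
    abort(paste0("calibration requires a fully labeled corpus; ",
                 "rerun with calibrate = FALSE (scan-only mode) or supply labels"))
  }

  vocab <- fit_vocabulary(c(records$text, anchors$text), config$encoder)
  emb_t <- withCallingHandlers(
    encode_texts(records$text, records$id, config$encoder, vocab),
    warning = function(w) {
      say("warning: ", conditionMessage(w)); invokeRestart("muffleWarning")
    })
  emb_a <- suppressWarnings(
    encode_texts(anchors$text, anchors$anchor_id, config$encoder, vocab))
  D <- distance_matrix(emb_a, emb_t)
  say("encoded at d = ", emb_t$d, "; distance matrix ",
      length(D$anchor_ids), " x ", length(D$text_ids))

  paths <- list(
    distances = file.path(config$output_dir, "distances.csv"),
    exemplars = file.path(config$output_dir, "exemplars.csv"),
    sweep = file.path(config$output_dir, "sweep.csv"),
    calibration = file.path(config$output_dir, "calibration.json"),
    ngrams = file.path(config$output_dir, "ngrams.csv"),
    monthly = file.path(config$output_dir, "monthly.csv"),
    config = file.path(config$output_dir, "run_config.json"),
    log = log_path
  )
  readr::write_csv(tidy(D), paths$distances, progress = FALSE)

  labels <- if (has_labels) setNames(records$label, records$id) else NULL
  k <- min(config$exemplar_k, nrow(records))
  exemplars <- bind_rows(map(anchors$anchor_id, function(a) {
    exemplar_report(D, a, k = k, labels = labels, texts = records)
  }))
  readr::write_csv(exemplars, paths$exemplars, progress = FALSE)

  sweep_tbl <- NULL; ranked <- NULL
  if (config$calibrate) {
    sweep_tbl <- sweep_thresholds(D, labels, config$grid, pooled = TRUE)
    readr::write_csv(as_tibble(sweep_tbl), paths$sweep, progress = FALSE)
    ranked <- withCallingHandlers(
      rank_anchors(sweep_tbl, config$precision_floor, config$top_k),
      warning = function(w) {
        say("warning: ", conditionMessage(w)); invokeRestart("muffleWarning")
      })
    per_anchor <- map(setdiff(unique(sweep_tbl$anchor_id), "pooled"), function(a) {
      t_opt <- optimal_threshold(sweep_tbl, config$precision_floor, anchor_id = a)
      list(anchor_id = a,
           optimal_threshold = if (is.na(t_opt)) NULL else t_opt)
    })
    jsonlite::write_json(
      list(precision_floor = config$precision_floor,
           n_pos = attr(sweep_tbl, "n_pos"), n_texts = attr(sweep_tbl, "n_texts"),
           per_anchor = per_anchor, top_anchors = ranked),
      paths$calibration, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("calibrated at floor ", config$precision_floor, "; ",
        nrow(ranked), " anchor(s) feasible in top table")
  }

  ngrams <- ngram_frequencies(records$text, stopwords = config$stopwords,
                              top_k = config$ngram_top_k)
  readr::write_csv(ngrams, paths$ngrams, progress = FALSE)

  monthly <- NULL
  if (any(!is.na(records$created_at))) {
    monthly <- monthly_volume(records)
    readr::write_csv(monthly, paths$monthly, progress = FALSE)
  } else {
    say("no timestamps: monthly series skipped")
  }

  jsonlite::write_json(config_fingerprint(config), paths$config,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)

  invisible(list(records = records, anchors = anchors, distances = D,
                 exemplars = exemplars, sweep = sweep_tbl, ranked = ranked,
                 ngrams = ngrams, monthly = monthly, paths = paths,
                 config = config))
}

#' Demonstration run on a bundled synthetic corpus
#'
#' Generates a default synthetic corpus ([synthetic_config()]), runs the
#' full pipeline on it, and prints the top-anchor calibration table.
#'
#' @param seed integer seed for the synthetic corpus.
#' @param output_dir run directory (a temporary directory by default).
#' @return invisibly, the [run_scan()] result list.
#' @export
make_demo <- function(seed = 1L, output_dir = tempfile("demo_")) {
  gen <- generate_corpus(synthetic_config(seed = seed))
  cfg <- run_config(corpus = gen$records, anchors = gen$anchors,
                    output_dir = output_dir, seed = seed)
  res <- run_scan(cfg)
  cat("\nTop anchors at precision floor ", cfg$precision_floor, ":\n", sep = "")
  print(as.data.frame(res$ranked), row.names = FALSE)
  invisible(res)
}
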