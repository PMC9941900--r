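#' Default threshold grid
#'
#' Cosine-distance thresholds from 0 to 1 in steps of 0.001. Under the
#' reference encoder all distances lie in `[0, 1]`, so the grid endpoint
#' always captures the full corpus; informative operating points typically
#' sit in the lower third of the range.
#'
#' @return strictly increasing numeric vector.
#' @export
default_grid <- function() seq(0, 1, by = 0.001)

#' Capture metrics from raw counts
#'
#' The arithmetic behind every screening report: given how many texts a
#' threshold captured (`n_captured`), how many of those are labeled
#' misinformation (`tp`), the total labeled misinformation in the corpus
#' (`n_pos`), and optionally the corpus size (`n_total`), computes
#' prevalence (`n_pos / n_total`), capture rate (`n_captured / n_pos`, the
#' share of the positive class the capture set amounts to), precision
#' (`tp / n_captured`, undefined as `NA` when nothing is captured) and
#' recall (`tp / n_pos`). Percent columns are rounded half-up to 1 decimal,
#' the convention used in printed screening reports.
#'
#' @param n_captured,tp,n_pos,n_total non-negative counts; `tp <= n_captured`
#'   and `tp <= n_pos`.
#' @return one-row tibble with the counts, the proportions, and `*_pct`
#'   columns.
#' @examples
#' capture_summary(n_captured = 323, tp = 274, n_pos = 938, n_total = 4937)
#' @export
capture_summary <- function(n_captured, tp, n_pos, n_total = NA_integer_) {
  if (tp > n_captured || tp > n_pos) abort("tp cannot exceed n_captured or n_pos")
  prevalence <- if (is.na(n_total)) NA_real_ else n_pos / n_total
  precision <- if (n_captured == 0) NA_real_ else tp / n_captured
  recall <- if (n_pos == 0) NA_real_ else tp / n_pos
  capture_rate <- if (n_pos == 0) NA_real_ else n_captured / n_pos
  tibble(
    n_captured = n_captured, tp = tp, n_pos = n_pos, n_total = n_total,
    prevalence = prevalence, capture_rate = capture_rate,
    precision = precision, recall = recall,
    prevalence_pct = round_half_up(100 * prevalence, 1),
    capture_rate_pct = round_half_up(100 * capture_rate, 1),
    precision_pct = round_half_up(100 * precision, 1),
    recall_pct = round_half_up(100 * recall, 1)
  )
}

# Resolve one anchor scope of an anchor_distances object to a named distance
# vector: a single anchor row, or the per-text minimum over an anchor subset.
scope_distances <- function(distances, anchor_scope = NULL) {
  if (is.numeric(distances)) {
    if (is.null(names(distances))) abort("bare distance vectors must be named by text id")
    return(distances)
  }
  stopifnot(inherits(distances, "anchor_distances"))
  if (is.null(anchor_scope)) anchor_scope <- distances$anchor_ids
  missing <- setdiff(anchor_scope, distances$anchor_ids)
  if (length(missing) > 0) {
    abort(paste0("unknown anchor id(s): ", paste(missing, collapse = ", ")))
  }
  rows <- distances$D[match(anchor_scope, distances$anchor_ids), , drop = FALSE]
  setNames(apply(rows, 2, min), distances$text_ids)
}

# Align a label vector to a set of text ids, insisting on full coverage.
aligned_labels <- function(labels, text_ids) {
  lv <- as_label_vector(labels)
  lab <- lv[text_ids]
  if (anyNA(lab)) {
    abort(paste0("labels missing for ", sum(is.na(lab)), " text id(s)"))
  }
  unname(lab)
}

#' Capture set and metrics at one distance threshold
#'
#' A text is captured when its cosine distance to the anchor scope is at or
#' below `threshold` (inclusive, so grid endpoints are exact). The anchor
#' scope is one anchor's distance row, or — for a multi-anchor scope — the
#' per-text minimum distance over the anchors, so a text is captured when
#' ANY anchor in the scope is close enough.
#'
#' @param distances an `anchor_distances` object (see [distance_matrix()]),
#'   or a named distance vector for a single scope.
#' @param labels misinformation labels covering every text id: a named
#'   logical vector or a tibble with `id` and `label`.
#' @param threshold cosine distance cutoff, `>= 0`.
#' @param anchor_scope anchor id(s) defining the scope; default all anchors
#'   of `distances`.
#' @return one-row tibble: `anchor_scope`, `threshold`, `n_captured`, `tp`,
#'   `precision` (`NA` when nothing is captured), `recall`, and
#'   `captured_ids` (list-column).
#' @examples
#' d <- c(a = 0.1, b = 0.2, c = 0.3, d = 0.4, e = 0.5)
#' lab <- c(a = TRUE, b = TRUE, c = FALSE, d = TRUE, e = FALSE)
#' capture_at_threshold(d, lab, threshold = 0.3)
#' @export
capture_at_threshold <- function(distances, labels, threshold,
                                 anchor_scope = NULL) {
  if (threshold < 0) abort("threshold must be non-negative")
  d <- scope_distances(distances, anchor_scope)
  lab <- aligned_labels(labels, names(d))
  captured <- d <= threshold
  n_cap <- sum(captured)
  tp <- sum(captured & lab)
  P <- sum(lab)
  scope_label <- if (is.numeric(distances)) "scope"
                 else paste(anchor_scope %||% "all", collapse = "+")
  tibble(
    anchor_scope = scope_label,
    threshold = threshold,
    n_captured = n_cap,
    tp = tp,
    precision = if (n_cap == 0) NA_real_ else tp / n_cap,
    recall = if (P == 0) NA_real_ else tp / P,
    captured_ids = list(names(d)[captured])
  )
}

#' Pooled multi-anchor capture
#'
#' Captures a text when its minimum distance over an anchor subset is at or
#' below the threshold — the union of the per-anchor capture sets. Pooled
#' recall therefore always dominates each member anchor's recall at the same
#' threshold.
#'
#' @inheritParams capture_at_threshold
#' @param anchor_subset non-empty character vector of anchor ids present in
#'   `distances`.
#' @return as [capture_at_threshold()].
#' @export
pooled_capture <- function(distances, anchor_subset, labels, threshold) {
  if (length(anchor_subset) == 0) abort("anchor_subset must be non-empty")
  capture_at_threshold(distances, labels, threshold, anchor_scope = anchor_subset)
}

# Step-function sweep of one distance row over a threshold grid.
sweep_row <- function(d, lab, grid) {
  ord <- order(d, method = "radix")
  ds <- d[ord]
  cum_tp <- cumsum(lab[ord])
  idx <- findInterval(grid, ds)
  n_captured <- idx
  tp <- ifelse(idx == 0, 0L, cum_tp[pmax(idx, 1L)])
  P <- sum(lab)
  tibble(
    threshold = grid,
    n_captured = as.integer(n_captured),
    tp = as.integer(tp),
    precision = ifelse(n_captured == 0, NA_real_, tp / n_captured),
    recall = if (P == 0) NA_real_ else tp / P
  )
}

#' Threshold sweep: capture metrics across a distance grid
#'
#' Evaluates capture count, true positives, precision and recall at every
#' grid threshold, per anchor (and optionally for the pooled
#' minimum-distance scope). This is the curve family from which an operating
#' threshold is chosen: as the distance threshold grows, capture and recall
#' rise monotonically while precision typically decays toward the corpus
#' prevalence.
#'
#' @inheritParams capture_at_threshold
#' @param grid strictly increasing thresholds; [default_grid()] by default.
#' @param anchors anchor ids to sweep; default all in `distances`.
#' @param pooled also include a `"pooled"` scope using the per-text minimum
#'   distance over `anchors`.
#' @return a `sweep_curves` tibble: `anchor_id`, `threshold`, `n_captured`,
#'   `tp`, `precision`, `recall`; one row per anchor x grid point.
#' @export
sweep_thresholds <- function(distances, labels, grid = default_grid(),
                             anchors = NULL, pooled = FALSE) {
  if (length(grid) == 0) abort("threshold grid must be non-empty")
  if (any(diff(grid) <= 0)) abort("threshold grid must be strictly increasing")
  stopifnot(inherits(distances, "anchor_distances"))
  anchors <- anchors %||% distances$anchor_ids
  lab <- aligned_labels(labels, distances$text_ids)

  curves <- map(anchors, function(a) {
    d <- distances$D[match(a, distances$anchor_ids), ]
    mutate(sweep_row(d, lab, grid), anchor_id = a, .before = 1)
  })
  if (pooled) {
    dmin <- scope_distances(distances, anchors)
    curves <- c(curves, list(
      mutate(sweep_row(unname(dmin), lab, grid), anchor_id = "pooled", .before = 1)))
  }
  out <- bind_rows(curves)
  class(out) <- c("sweep_curves", class(out))
  attr(out, "n_pos") <- sum(lab)
  attr(out, "n_texts") <- length(lab)
  out
}

#' Optimal threshold under a precision floor
#'
#' The operating point sought in anchor screening: capture as many
#' misinformation texts as possible while keeping false positives rare.
#' Because capture grows monotonically with the threshold, that is the
#' LARGEST grid threshold whose precision is defined (something was
#' captured) and at or above the floor.
#'
#' @param curve a `sweep_curves` tibble restricted to one scope, or a sweep
#'   of several anchors together with `anchor_id` naming which to use.
#' @param precision_floor minimum acceptable precision, in `[0, 1]`;
#'   default 0.80, a standard operating floor for this kind of screen.
#' @param anchor_id scope to select when `curve` holds several.
#' @return the threshold, or `NA_real_` when no grid point qualifies.
#' @export
optimal_threshold <- function(curve, precision_floor = 0.8, anchor_id = NULL) {
  if (precision_floor < 0 || precision_floor > 1) {
    abort("precision_floor must be in [0, 1]")
  }
  if (!is.null(anchor_id)) curve <- curve[curve$anchor_id == anchor_id, ]
  if ("anchor_id" %in% names(curve) && length(unique(curve$anchor_id)) > 1) {
    abort("curve spans several anchors; pass `anchor_id` to select one")
  }
  ok <- !is.na(curve$precision) & curve$precision >= precision_floor
  if (!any(ok)) return(NA_real_)
  max(curve$threshold[ok])
}

#' Rank anchors by misinformation recall at their optimal thresholds
#'
#' For each anchor, finds the optimal threshold under the precision floor
#' and ranks anchors by the recall achieved there (descending), breaking
#' ties by precision then anchor id. This reproduces the "top performing
#' anchors" analysis: which exemplar statements capture the most labeled
#' misinformation at high precision.
#'
#' @param curves a `sweep_curves` tibble from [sweep_thresholds()].
#' @param precision_floor see [optimal_threshold()].
#' @param k how many top anchors to return (default all feasible).
#' @return tibble `(anchor_id, threshold, n_captured, tp, precision,
#'   recall)`, best first; empty (with a warning) when no anchor is feasible
#'   at the floor.
#' @export
rank_anchors <- function(curves, precision_floor = 0.8, k = Inf) {
  scopes <- setdiff(unique(curves$anchor_id), "pooled")
  rows <- map(scopes, function(a) {
    cv <- curves[curves$anchor_id == a, ]
    t_opt <- optimal_threshold(cv, precision_floor)
    if (is.na(t_opt)) return(NULL)
    cv[cv$threshold == t_opt, ]
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    warn("no anchor reaches the precision floor at any grid threshold")
    return(tibble(anchor_id = character(), threshold = numeric(),
                  n_captured = integer(), tp = integer(),
                  precision = numeric(), recall = numeric()))
  }
  out <- arrange(out, desc(recall), desc(precision), anchor_id)
  head(as_tibble(out), k)
}

#' @exportS3Method generics::glance
#' @rdname rank_anchors
#' @param x a `sweep_curves` object.
#' @param ... passed on (`precision_floor`, `k`).
glance.sweep_curves <- function(x, ...) rank_anchors(x, ...)

#' @exportS3Method generics::tidy
tidy.sweep_curves <- function(x, ...) as_tibble(x)
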