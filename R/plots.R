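#' Plot threshold sweep curves
#'
#' Draws one of the three standard screening diagnostics as a function of
#' the cosine-distance threshold, one line per anchor scope: recall (share
#' of labeled misinformation captured), capture count, or precision.
#'
#' @param object a `sweep_curves` tibble from [sweep_thresholds()].
#' @param metric which curve family to draw.
#' @param anchors optional subset of anchor ids to display.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_curves <- function(object,
                                  metric = c("recall", "n_captured", "precision"),
                                  anchors = NULL, ...) {
  metric <- arg_match(metric)
  df <- as_tibble(object)
  if (!is.null(anchors)) df <- df[df$anchor_id %in% anchors, ]
  ylab <- switch(metric,
                 recall = "Proportion of misinformation captured",
                 n_captured = "Texts captured",
                 precision = "Precision of capture set")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data[[metric]],
                                   colour = .data$anchor_id)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Cosine distance threshold", y = ylab,
                  colour = "Anchor") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.recovery_experiment <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$threshold), ]
  floor_ <- attr(object, "precision_floor")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = .data$heldout_precision)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = floor_, linetype = "dashed") +
    ggplot2::labs(x = "Calibrated threshold",
                  y = "Held-out precision",
                  title = "Threshold recovery across seeds") +
    ggplot2::theme_minimal()
}
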