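## ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_rect
#'   geom_point geom_abline geom_step labs facet_wrap theme_bw
#'   scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Bar chart of fragment-class proportions
#'
#' @param object `snc_proportions` from [compute_class_proportions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snc_proportions <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$class, -.data$proportion),
                     y = .data$proportion)) +
    geom_col(fill = "steelblue") +
    scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    labs(x = NULL, y = "share of annotated reads") +
    theme_bw()
}

#' Read-length distribution plot
#'
#' @param object `snc_lengthdist` from [length_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snc_lengthdist <- function(object, ...) {
  ggplot(object, aes(.data$length, .data$rpm)) +
    geom_col(fill = "grey30") +
    labs(x = "read length (nt)", y = "RPM",
         title = attr(object, "fragment_class")) +
    theme_bw()
}

#' Coverage profile with optional peak shading
#'
#' @param object `snc_profile` from [coverage_profile()].
#' @param peaks Optional `snc_peaks` for the same parent.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snc_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot(object, aes(.data$pos, .data$depth))
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + geom_rect(
      data = as_tibble(peaks),
      aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.3
    )
  }
  p + geom_line(color = "grey20") +
    labs(x = paste(attr(object, "parent_id"), "position (nt)"), y = "depth") +
    theme_bw()
}

#' Volcano plot of differential-expression results
#'
#' @param object `snc_de` from [run_de()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snc_de <- function(object, ...) {
  ggplot(object, aes(.data$log2fc, -log10(.data$p), color = .data$direction)) +
    geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_color_manual(values = c(up = "firebrick", down = "navy", ns = "grey70")) +
    labs(x = "log2 fold change (AML / control)", y = "-log10 p") +
    theme_bw()
}

#' Validation ROC curves of evaluated marker panels
#'
#' @param object `snc_panel_report` from [evaluate_panels()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snc_panel_report <- function(object, ...) {
  pts <- map_dfr(object, function(r) {
    if (is.null(r$validation_scores)) return(NULL)
    mutate(roc_points(r$validation_scores, r$validation_labels),
           class = sprintf("%s (AUC %.2f)", r$class, r$auc_validation))
  })
  ggplot(pts, aes(.data$fpr, .data$tpr, color = .data$class)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    labs(x = "false positive rate", y = "true positive rate", color = NULL) +
    theme_bw()
}
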