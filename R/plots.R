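#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a calibration fit
#'
#' Log of the mean per-sequence exceedance count against segment score,
#' with the fitted Karlin-Altschul regression line.
#'
#' @param object A `ka_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ka_calibration <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$log_exceedance)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(
      x = "segment score (nats)",
      y = "ln(mean segments per sequence exceeding score)",
      title = sprintf("Null calibration: k = %.3g, a = %.3g (r² = %.3f)",
                      object$k, object$a, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot nucleotide-level ROC points
#'
#' @param roc A tibble from [roc_points()].
#' @param fpr_column Which false positive rate to use on the x axis:
#'   `"fpr"` (the `FP / (TP + FN)` form) or `"fpr_std"` (`FP / (FP + TN)`,
#'   available when `roc_points()` was given a total length).
#' @return A ggplot object.
#' @export
plot_roc <- function(roc, fpr_column = c("fpr", "fpr_std")) {
  fpr_column <- match.arg(fpr_column)
  stopifnot(fpr_column %in% names(roc))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data[[fpr_column]], y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("false positive rate (", fpr_column, ")"),
                  y = "true positive rate (nucleotide level)",
                  title = "Filter ROC across P-value thresholds") +
    ggplot2::theme_minimal()
}

#' Plot PPV by exon length before and after filtering
#'
#' @param binned A tibble from [bin_ppv_by_exon_length()].
#' @return A ggplot object.
#' @export
plot_ppv_by_length <- function(binned) {
  long <- tidyr::pivot_longer(binned, cols = c("ppv_before", "ppv_after"),
                              names_to = "phase", names_prefix = "ppv_",
                              values_to = "ppv")
  long$phase <- factor(long$phase, levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$length_bin, y = .data$ppv,
                                     fill = .data$phase)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "exon length (codons)",
                  y = "positive predictive value",
                  fill = NULL,
                  title = "PPV by exon length, before vs after filtering") +
    ggplot2::theme_minimal()
}
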