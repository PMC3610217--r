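#' Plot a discovery run: n-gram counts and DR distributions per class
#'
#' Bar panel of discriminative n-grams per class beside the per-class DR
#' distribution on a log scale — the quick visual check that signal classes
#' dominate and DRs sit well above the threshold.
#'
#' @param object A `motif_discovery` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_discovery <- function(object, ...) {
  d <- object$ngrams
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no discriminative n-grams") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$dr)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::geom_hline(yintercept = object$config$threshold,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "class", y = "discriminative ratio (log scale)",
                  title = "Discriminative n-grams by class",
                  subtitle = paste0("dashed line: selection threshold T = ",
                                    object$config$threshold))
}

#' Plot a ROC curve
#'
#' @param object A `roc_curve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC curve (trapezoidal AUC = %.3f)",
                                  object$auc))
}
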