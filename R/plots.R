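# ggplot2 figure helpers ------------------------------------------------------

#' @importFrom ggplot2 ggplot aes geom_tile geom_histogram geom_line
#'   geom_abline geom_point labs scale_fill_viridis_c coord_equal autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a (median) edge-weight matrix
#'
#' @param weight_matrix Symmetric node-by-node matrix.
#' @param node_labels Optional per-node network labels used to order nodes
#'   by network.
#' @return A ggplot.
#' @export
plot_weight_matrix <- function(weight_matrix, node_labels = NULL) {
  W <- as.matrix(weight_matrix)
  n <- nrow(W)
  ord <- seq_len(n)
  if (!is.null(node_labels)) ord <- order(as.character(node_labels))
  W <- W[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$weight <- as.numeric(W)[(df$j - 1) * n + df$i]
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$weight)) +
    geom_tile() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "node", y = "node", fill = "weight")
}

#' Distribution of per-redraw CV correlations
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot (histogram of per-redraw r, or pooled
#'   predicted-vs-actual scatter for LOOCV).
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  if (object$scheme == "loocv") {
    ggplot(object$predictions,
           aes(x = .data$actual, y = .data$predicted)) +
      geom_point() +
      geom_abline(linetype = 2) +
      labs(title = sprintf("LOOCV pooled r = %.2f", object$r_pooled),
           x = "actual score change", y = "predicted score change")
  } else {
    ggplot(object$per_redraw, aes(x = .data$r)) +
      geom_histogram(bins = 40) +
      labs(title = sprintf("3-fold CV, median r = %.2f", object$r_median),
           x = "per-redraw r", y = "count")
  }
}

#' ROC curve plot
#'
#' @param curve A [roc_curve_points()] tibble.
#' @param auc Optional AUC shown in the title.
#' @return A ggplot.
#' @export
plot_roc <- function(curve, auc = NULL) {
  ggplot(curve, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_line() +
    geom_abline(linetype = 2) +
    labs(title = if (!is.null(auc)) sprintf("AUC = %.2f", auc) else NULL,
         x = "1 - specificity", y = "sensitivity")
}

#' @importFrom rlang .data
NULL
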