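#' Heatmap of a glycan kernel or similarity matrix
#'
#' @param object A `glycan_kernel` or any labeled symmetric matrix.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot glycan_kernel
#' @export
autoplot.glycan_kernel <- function(object, ...) {
  df <- tibble(
    row = factor(rep(rownames(object) %||% as.character(seq_len(nrow(object))),
                     times = ncol(object)),
                 levels = rownames(object) %||% as.character(seq_len(nrow(object)))),
    col = factor(rep(colnames(object) %||% as.character(seq_len(ncol(object))),
                     each = nrow(object)),
                 levels = colnames(object) %||% as.character(seq_len(ncol(object)))),
    value = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "K") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Kernel (", attr(object, "method") %||% "", ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Distribution of per-repeat cross-validated AUCs
#'
#' @param object A `glycan_cv` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot glycan_cv
#' @export
autoplot.glycan_cv <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = object$auc, linetype = 2) +
    ggplot2::labs(x = "per-repeat mean AUC", y = "repeats",
                  title = sprintf("CV AUC: mean %.4f (sd %.4f)",
                                  object$auc, object$sd)) +
    ggplot2::theme_minimal()
}

#' Bar chart of multiple-kernel weights
#'
#' @param weights A tibble from [mkl_weights()].
#' @return A ggplot object.
#' @export
plot_mkl_weights <- function(weights) {
  ggplot2::ggplot(weights, ggplot2::aes(x = .data$kernel, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "alignment weight") +
    ggplot2::theme_minimal()
}
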