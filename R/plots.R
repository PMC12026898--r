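#' Plot the optimization trace of a fitted model
#'
#' Best training cost per epoch, one line per restart.
#'
#' @param object A `"fic_fit"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fic_fit <- function(object, ...) {
  d <- object$candidates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$train_total,
                                  colour = factor(.data$restart))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "CMA-ES epoch", y = "best child total cost",
                  colour = "restart") +
    ggplot2::theme_minimal()
}

#' Heatmap of an FC matrix
#'
#' @param object An `"fc_matrix"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  m <- unclass(object)
  d <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  d$fc <- as.vector(m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$j, y = .data$i,
                                  fill = .data$fc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Bar chart of realism-cost components
#'
#' @param object A `"realism_cost"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.realism_cost <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$component != "total", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "cost component") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
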