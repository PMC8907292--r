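#' Plot the GA fitness trace
#'
#' Best-so-far pooled CV R-squared per generation, one panel line per
#' feature-count stage.
#'
#' @param object an `ibcga_run`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ibcga_run <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(
    x = .data$generation, y = .data$best_fitness,
    group = .data$r, colour = factor(.data$r))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = expression("best 10-CV" ~ R^2),
                  colour = "features (r)") +
    ggplot2::theme_minimal()
}

#' Plot per-run appearance scores
#'
#' @param object an `asc_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.asc_report <- function(object, ...) {
  sc <- object$scores
  sc$selected <- sc$run == object$selected_run
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$run, y = .data$score,
                                   fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "run", y = "appearance score") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- object$points
  df <- tibble(fpr = c(1, 1 - pts$specificity, 0),
               tpr = c(1, pts$sensitivity, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' @param object a `km_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (years)", y = "survival probability") +
    ggplot2::theme_minimal()
}
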