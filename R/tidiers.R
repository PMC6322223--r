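#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report into per-class metrics
#'
#' @param x A `weaktext_eval` from [prf()].
#' @param ... Unused.
#' @return A tibble with one row per class: `label`, `support`, `precision`,
#'   `recall`, `f1`, `zero_denominator`.
#' @method tidy weaktext_eval
#' @export
tidy.weaktext_eval <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x A `weaktext_eval`.
#' @param ... Unused.
#' @return A one-row tibble: aggregate `precision`, `recall`, `f1`,
#'   `average`, `n`.
#' @method glance weaktext_eval
#' @export
glance.weaktext_eval <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall, f1 = x$f1,
                 average = x$average, n = x$n)
}

#' @method glance weaktext_model
#' @export
glance.weaktext_model <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind,
                 classes = paste(x$classes, collapse = ";"),
                 n_train = x$n_train, seed = x$seed %||% NA_integer_)
}

#' @method tidy weaktext_paradigm
#' @export
tidy.weaktext_paradigm <- function(x, ...) x$predictions

#' @method glance weaktext_paradigm
#' @export
glance.weaktext_paradigm <- function(x, ...) {
  tibble::tibble(model = x$model$spec$kind,
                 model_f1 = x$model_eval$f1, rule_f1 = x$rule_eval$f1,
                 model_precision = x$model_eval$precision,
                 model_recall = x$model_eval$recall,
                 disagreements = unname(x$disagreements$tally["disagreements"]),
                 n_test = x$model_eval$n, n_train = x$model$n_train)
}

#' Summarize bound-verification replicates per data size
#'
#' @param x A `weaktext_bound` tibble from [verify_bound()].
#' @param ... Unused.
#' @return A tibble with one row per data size: median and maximum observed
#'   loss gap, median implied constant, fraction of fits satisfying the
#'   norm condition, and convergence rate.
#' @method tidy weaktext_bound
#' @export
tidy.weaktext_bound <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$size),
                   eps = 1 / sqrt(.data$size[1]),
                   median_gap = stats::median(.data$gap),
                   max_gap = max(.data$gap),
                   median_c_hat = stats::median(.data$c_hat),
                   norm_bound_rate = mean(.data$norm_bound_ok),
                   converged_rate = mean(.data$converged),
                   .groups = "drop")
}

#' @method tidy weaktext_disagreement
#' @export
tidy.weaktext_disagreement <- function(x, ...) x$cases

#' Plot per-class precision/recall/F1
#'
#' @param object A `weaktext_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weaktext_eval
#' @export
autoplot.weaktext_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_class,
                              c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Per-class metrics (n = %d)", object$n)) +
    ggplot2::theme_minimal()
}

#' Plot the observed loss gap against the data size
#'
#' Shows the replicate |L - L_phi| values at the fitted weights per data
#' size on log-log axes, with the eps = |D|^(-1/2) reference slope anchored
#' at the smallest size's median; if the gap follows the bound's scaling,
#' the medians track the guide line.
#'
#' @param object A `weaktext_bound` from [verify_bound()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weaktext_bound
#' @export
autoplot.weaktext_bound <- function(object, ...) {
  s <- tidy.weaktext_bound(object)
  guide <- tibble::tibble(
    size = s$size,
    gap = s$median_gap[1] * sqrt(s$size[1]) / sqrt(s$size))
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$size, y = .data$gap)) +
    ggplot2::geom_jitter(width = 0.03, height = 0, alpha = 0.5) +
    ggplot2::geom_line(data = s, ggplot2::aes(y = .data$median_gap),
                       color = "steelblue") +
    ggplot2::geom_line(data = guide, linetype = 2, color = "grey40") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "|D|", y = "|L - L_phi| at fitted w",
                  title = "Weak-supervision loss gap vs data size") +
    ggplot2::theme_minimal()
}

#' Plot a training-size study
#'
#' @param object A `weaktext_curve` from [learning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weaktext_curve
#' @export
autoplot.weaktext_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("model_f1", "rule_f1"),
                              names_to = "system", values_to = "f1")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$f1,
                                     color = .data$system)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training documents", y = "F1") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data %||%
NULL
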