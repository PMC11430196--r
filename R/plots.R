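# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a trend-factor table as per-state propensity profiles
#'
#' @param object A [fit_trend_table()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_table <- function(object, ...) {
  df <- tidy(object)
  df$aa <- factor(df$aa, levels = aa_alphabet())
  df$state <- factor(df$state, levels = object$states)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$normalized,
                                   group = .data$state)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$state), ncol = 1) +
    ggplot2::labs(x = "amino acid", y = "normalized propensity",
                  title = "Secondary-structure propensity profiles") +
    ggplot2::theme_minimal()
}

#' Plot grouped factor-importance shares
#'
#' @param object An [grouped_importance()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_report <- function(object, ...) {
  df <- object$per_factor
  df$factor <- factor(df$factor, levels = df$factor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 100 / nrow(df), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "importance share (%)",
                  title = paste0("Grouped permutation importance (",
                                 object$family, ")"),
                  subtitle = sprintf("baseline Q = %.1f%%, %d repeats",
                                     object$baseline_q, object$repeats)) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation confusion matrix
#'
#' @param object An [evaluate_ss()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ss_evaluation <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("observed", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey70", high = "firebrick") +
    ggplot2::labs(title = sprintf("Q = %.1f%%, Sov = %.1f%%",
                                  object$q, object$sov_overall)) +
    ggplot2::theme_minimal()
}

#' Plot ablation results as paired bars
#'
#' @param object An [run_ablation()] result.
#' @param metric `"q"` or `"sov"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ss_ablation <- function(object, metric = c("q", "sov"), ...) {
  metric <- match.arg(metric)
  df <- object$results
  df$arm <- factor(df$arm, levels = c("without", "with"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data[[metric]],
                                   fill = .data$arm)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(without = "grey60",
                                          with = "steelblue")) +
    ggplot2::labs(x = NULL, y = paste(toupper(metric), "(%)"),
                  fill = NULL,
                  title = "Effect of adding property + trend factors") +
    ggplot2::theme_minimal()
}
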