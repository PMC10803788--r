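#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decision report
#'
#' @param x An `ff_decision` from [ff_decide()].
#' @param ... Unused.
#' @return One row per alternative with its overall pair, score, accuracy,
#'   rank and tie group, best first.
#' @method tidy ff_decision
#' @export
tidy.ff_decision <- function(x, ...) {
  x$ranking
}

#' @rdname tidy.ff_decision
#' @return For `glance()`: a one-row summary (dimensions, variant, family,
#'   best alternative and its score, violation count).
#' @method glance ff_decision
#' @export
glance.ff_decision <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    family = x$family,
    n_alternatives = length(x$alternatives),
    n_attributes = length(x$attributes),
    n_periods = length(x$periods),
    best = x$ranking$alternative[1],
    best_score = x$ranking$score[1],
    n_violations = nrow(x$violations)
  )
}

#' Plot alternative scores
#'
#' Bar chart of the per-alternative scores in ranking order; the optimal
#' alternative is highlighted.
#'
#' @param object An `ff_decision`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ff_decision
#' @export
autoplot.ff_decision <- function(object, ...) {
  d <- object$ranking
  d$alternative <- factor(d$alternative, levels = rev(d$alternative))
  d$best <- d$rank == 1
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$alternative,
                                  fill = .data$best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(
      x = if (object$family == "fermatean") {
        expression(score ~ g == mu^3 - nu^3)
      } else {
        expression(score ~ g == mu - nu)
      },
      y = NULL,
      title = sprintf("%s %s ranking", object$family, object$variant),
      subtitle = ranking_chain(object)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ff_decision
#' @param x An `ff_decision`.
#' @export
plot_scores <- function(x, ...) autoplot(x, ...)
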