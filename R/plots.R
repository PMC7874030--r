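#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: motor modules and
#' mean motor primitives for a `synergy_nmf` fit, the R^2-vs-rank curve
#' for a `rank_selection`, and the mean overlap curve for the output of
#' [primitive_overlaps()].
#'
#' @param object the fitted object.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot-lungesyn
NULL

#' @rdname autoplot-lungesyn
#' @method autoplot synergy_nmf
#' @export
autoplot.synergy_nmf <- function(object, ...) {
  pm <- primitive_mean_cycle(object)
  dd <- tibble(
    synergy = factor(rep(seq_len(object$rank), each = CYCLE_POINTS)),
    point = rep(seq_len(CYCLE_POINTS), times = object$rank),
    activation = as.vector(t(pm))
  )
  ggplot2::ggplot(dd, ggplot2::aes(.data$point, .data$activation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = SWING_POINTS + 0.5, linetype = 2) +
    ggplot2::facet_wrap(~synergy, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "normalized cycle point (touchdown at 50/51)",
      y = "activation (unit max)",
      title = sprintf("Motor primitives (rank %d, R² = %.3f)",
                      object$rank, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-lungesyn
#' @export
plot_modules <- function(object, ...) {
  stopifnot(inherits(object, "synergy_nmf"))
  dd <- tidy(object, "w") %>%
    mutate(muscle = factor(.data$muscle, levels = lunge_muscles()))
  ggplot2::ggplot(dd, ggplot2::aes(.data$muscle, .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~synergy, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "muscle weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot-lungesyn
#' @method autoplot rank_selection
#' @export
autoplot.rank_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$rank, .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$rank, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = object$curve$rank) +
    ggplot2::labs(x = "number of synergies", y = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' @param overlaps output of [primitive_overlaps()].
#' @rdname autoplot-lungesyn
#' @export
plot_overlaps <- function(overlaps, ...) {
  ggplot2::ggplot(overlaps$mean, ggplot2::aes(.data$point, .data$overlap)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = SWING_POINTS + 0.5, linetype = 2) +
    ggplot2::labs(
      x = "normalized cycle point (touchdown at 50/51)",
      y = "mean number of primitive overlaps"
    ) +
    ggplot2::theme_minimal()
}
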