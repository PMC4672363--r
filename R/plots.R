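# ggplot2 autoplot methods for the main result types.

#' Plot a two-channel recording
#'
#' @param object An [eog_recording()].
#' @param ... Unused.
#' @return A ggplot: both channels over time, with labeled event blocks
#'   shaded when labels are present.
#' @method autoplot eog_recording
#' @export
autoplot.eog_recording <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("left_uV", "right_uV"),
                              names_to = "channel", values_to = "uV")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$uV,
                                          colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "amplitude [µV]", colour = NULL) +
    ggplot2::theme_minimal()
  if ("label" %in% names(object)) {
    ev <- dplyr::filter(
      dplyr::summarise(dplyr::group_by(as_tibble(object), .data$label),
                       t0 = min(.data$time_s), t1 = max(.data$time_s),
                       .groups = "drop"),
      .data$label != "center")
    if (nrow(ev))
      p <- p + ggplot2::geom_rect(
        data = ev, inherit.aes = FALSE, alpha = 0.15,
        ggplot2::aes(xmin = .data$t0, xmax = .data$t1,
                     ymin = -Inf, ymax = Inf, fill = .data$label))
  }
  p
}

#' Plot a Haar scalogram
#'
#' @param object An [cwt_haar()] result.
#' @param energy If `TRUE` (default) plot squared coefficients, else signed
#'   coefficients.
#' @param ... Unused.
#' @return A ggplot tile map over shift (time) and scale.
#' @method autoplot eog_scalogram
#' @export
autoplot.eog_scalogram <- function(object, energy = TRUE, ...) {
  m <- if (energy) object$S else object$coefs
  df <- as_tibble(as.data.frame.table(m, responseName = "value"))
  names(df) <- c("scale", "shift", "value")
  df$shift <- as.integer(df$shift)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift, y = .data$scale,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "shift [samples]", y = "scale [samples]",
                  fill = if (energy) "S" else "C") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param object An [confusion()] object.
#' @param percent Row-normalize to percent (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot tile map with count/percent annotations.
#' @method autoplot eog_confusion
#' @export
autoplot.eog_confusion <- function(object, percent = TRUE, ...) {
  df <- tidy(object, percent = percent)
  val <- if (percent) "percent" else "n"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data[[val]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data[[val]]))) +
    ggplot2::scale_y_discrete(limits = rev(object$classes)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = val) +
    ggplot2::theme_minimal()
}

#' Plot a decision stream
#'
#' @param object An `eog_decisions` tibble from [classify_stream()].
#' @param ... Unused.
#' @return A ggplot step chart of decisions per block, with ground truth
#'   overlaid when available.
#' @method autoplot eog_decisions
#' @export
autoplot.eog_decisions <- function(object, ...) {
  lv <- eye_classes()
  df <- as_tibble(object)
  df$decision <- factor(df$decision, levels = lv)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$block_index,
                                        y = .data$decision)) +
    ggplot2::geom_point(shape = 15, size = 2, colour = "steelblue") +
    ggplot2::labs(x = "block", y = NULL) +
    ggplot2::theme_minimal()
  if ("label" %in% names(df)) {
    df$label <- factor(df$label, levels = lv)
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$label),
                                 shape = 1, size = 3, colour = "black")
  }
  p
}
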