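#' Plot a truth table as an NFI bar chart
#'
#' One bar per input state with the decision threshold drawn as a dashed
#' line, mirroring the fluorescence read-out of the gates.
#'
#' @param object A `prism_truth_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prism_truth_table <- function(object, ...) {
  incols <- names(object)[startsWith(names(object), "in")]
  lab <- apply(as.data.frame(object)[, incols, drop = FALSE], 1,
               paste, collapse = "/")
  df <- tibble::tibble(
    state = factor(lab, levels = lab),
    nfi = object$nfi,
    output = factor(object$output)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$nfi,
                                   fill = .data$output)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "input state", y = "NFI",
                  title = paste0(attr(object, "gate"), " gate"),
                  fill = "output") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an open/erase cycling trace
#'
#' @param object A `prism_cycle` from [run_cycle()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prism_cycle <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$nfi)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$action), size = 3) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$step) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "half-cycle", y = "NFI",
                  title = "Reversible ON-OFF switching") +
    ggplot2::theme_minimal()
}

#' Plot the even/odd identification table
#'
#' @param object A `prism_parity_table` from [parity_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prism_parity_table <- function(object, ...) {
  df <- tibble::tibble(digit = factor(object$digit), nfi = object$nfi,
                       output = factor(object$output))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$digit, y = .data$nfi,
                                   fill = .data$output)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "decimal digit", y = "NFI",
                  title = "Even/odd identification", fill = "output") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the prism geometry
#'
#' A simple 2-D projection (x against y, point size encoding z) of the
#' vertex and nick coordinates.
#'
#' @param p A [geometry_params()] object.
#' @return A ggplot object.
#' @export
plot_prism_geometry <- function(p = geometry_params()) {
  geom <- build_geometry(p)
  ggplot2::ggplot(geom, ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$z,
                                     label = .data$point)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(size = 3, vjust = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", size = "z (nm)") +
    ggplot2::theme_minimal()
}
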