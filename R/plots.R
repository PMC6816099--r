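# ggplot2 visualization: free-energy surfaces (heatmap / profile) and
# string-method profiles with confidence intervals.

#' Plot a free-energy surface
#'
#' 1-D surfaces become a free-energy profile; 2-D surfaces a heatmap with
#' masked cells left blank.
#'
#' @param object a [fe_surface]
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.fe_surface <- function(object, ...) {
  centers <- fes_centers(object)
  if (object$ndim == 1) {
    d <- data.frame(cv = centers[, 1], F = object$values)
    ggplot2::ggplot(d[!is.na(d$F), ], ggplot2::aes(x = .data$cv, y = .data$F)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "collective variable", y = "free energy (kJ/mol)")
  } else {
    d <- data.frame(cv1 = centers[, 1], cv2 = centers[, 2], F = object$values)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$cv1, y = .data$cv2,
                                    fill = .data$F)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "white",
                                    name = "F (kJ/mol)") +
      ggplot2::labs(x = "xi1", y = "xi2")
  }
}

#' Plot a string-method result
#'
#' Mean free-energy profile with 95% confidence-interval error bars over
#' the given iteration window (default: the detected oscillatory phase).
#'
#' @param object a `string_result`
#' @param window iteration window (default: oscillatory phase to end)
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.string_result <- function(object, window = NULL, ...) {
  if (is.null(window)) {
    s <- object$oscillatory_start
    if (is.na(s)) s <- max(1, object$n_iterations - 9)
    window <- s:object$n_iterations
  }
  st <- profile_stats(object, window)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$image, y = .data$mean)) +
    ggplot2::geom_line(color = "purple") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.3) +
    ggplot2::labs(x = "image", y = "free energy (kJ/mol)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
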